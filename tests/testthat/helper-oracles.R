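# Independent oracles used by the test suite. Everything here is built on
# base R Bessel library functions and direct formula evaluation, sharing no
# code with the compiled implementation under test.

# Riccati-Bessel functions via half-integer-order library Bessel functions
rb_psi <- function(n, x) sqrt(pi * x / 2) * besselJ(x, n + 0.5)
rb_chi <- function(n, x) -sqrt(pi * x / 2) * besselY(x, n + 0.5)
rb_dpsi <- function(n, x) rb_psi(n - 1, x) - n * rb_psi(n, x) / x
rb_dchi <- function(n, x) rb_chi(n - 1, x) - n * rb_chi(n, x) / x
rb_zeta <- function(n, x) complex(real = rb_psi(n, x),
                                  imaginary = -rb_chi(n, x))
rb_dzeta <- function(n, x) complex(real = rb_dpsi(n, x),
                                   imaginary = -rb_dchi(n, x))

# homogeneous Mie coefficients, vectorised over order
oracle_mie_homog <- function(x, m, nmax) {
  n <- seq_len(nmax)
  a <- (m * rb_psi(n, m * x) * rb_dpsi(n, x) -
          rb_psi(n, x) * rb_dpsi(n, m * x)) /
    (m * rb_psi(n, m * x) * rb_dzeta(n, x) -
       rb_zeta(n, x) * rb_dpsi(n, m * x))
  b <- (rb_psi(n, m * x) * rb_dpsi(n, x) -
          m * rb_psi(n, x) * rb_dpsi(n, m * x)) /
    (rb_psi(n, m * x) * rb_dzeta(n, x) -
       m * rb_zeta(n, x) * rb_dpsi(n, m * x))
  list(a = a, b = b)
}

# coated-sphere coefficients by direct evaluation of the boundary-condition
# solution (library Bessel functions, no recurrences)
oracle_mie_coated <- function(x, y, m1, m2, nmax) {
  n <- seq_len(nmax)
  An <- (m2 * rb_psi(n, m2 * x) * rb_dpsi(n, m1 * x) -
           m1 * rb_dpsi(n, m2 * x) * rb_psi(n, m1 * x)) /
    (m2 * rb_chi(n, m2 * x) * rb_dpsi(n, m1 * x) -
       m1 * rb_dchi(n, m2 * x) * rb_psi(n, m1 * x))
  Bn <- (m2 * rb_dpsi(n, m2 * x) * rb_psi(n, m1 * x) -
           m1 * rb_psi(n, m2 * x) * rb_dpsi(n, m1 * x)) /
    (m2 * rb_dchi(n, m2 * x) * rb_psi(n, m1 * x) -
       m1 * rb_chi(n, m2 * x) * rb_dpsi(n, m1 * x))
  Q <- rb_psi(n, m2 * y) - An * rb_chi(n, m2 * y)
  dQ <- rb_dpsi(n, m2 * y) - An * rb_dchi(n, m2 * y)
  Rn <- rb_psi(n, m2 * y) - Bn * rb_chi(n, m2 * y)
  dRn <- rb_dpsi(n, m2 * y) - Bn * rb_dchi(n, m2 * y)
  a <- (rb_psi(n, y) * dQ - m2 * rb_dpsi(n, y) * Q) /
    (rb_zeta(n, y) * dQ - m2 * rb_dzeta(n, y) * Q)
  b <- (m2 * rb_psi(n, y) * dRn - rb_dpsi(n, y) * Rn) /
    (m2 * rb_zeta(n, y) * dRn - rb_dzeta(n, y) * Rn)
  list(a = a, b = b)
}

# brute-force unpolarized LSP from oracle coefficients with a direct
# Legendre-recurrence evaluation of the angular functions
oracle_lsp <- function(cell, optics) {
  sp <- size_parameters(cell, optics)
  nmax <- ceiling(sp$y_total + 4 * sp$y_total^(1 / 3) + 2)
  cf <- if (abs(sp$m_core - sp$m_shell) < 1e-12)
    oracle_mie_homog(sp$y_total, sp$m_shell, nmax)
  else oracle_mie_coated(sp$x_core, sp$y_total, sp$m_core, sp$m_shell, nmax)
  ang <- lsp_angles(optics)
  ints <- vapply(ang, function(th) {
    mu <- cos(th * pi / 180)
    p <- numeric(nmax); t <- numeric(nmax)
    p[1] <- 1; t[1] <- mu
    if (nmax >= 2) {
      p[2] <- 3 * mu
      t[2] <- 2 * mu * p[2] - 3 * p[1]
      for (n in 3:nmax) {
        p[n] <- ((2 * n - 1) * mu * p[n - 1] - n * p[n - 2]) / (n - 1)
        t[n] <- n * mu * p[n] - (n + 1) * p[n - 1]
      }
    }
    f <- (2 * seq_len(nmax) + 1) / (seq_len(nmax) * (seq_len(nmax) + 1))
    s1 <- sum(f * (cf$a * p + cf$b * t))
    s2 <- sum(f * (cf$a * t + cf$b * p))
    (Mod(s1)^2 + Mod(s2)^2) / 2
  }, numeric(1))
  ints
}

# dipole polarizability of a coated sphere (quasi-static closed form);
# f = core/total diameter ratio
rayleigh_coated_alpha <- function(m1, m2, f) {
  e1 <- m1^2; e2 <- m2^2
  ((e2 - 1) * (e1 + 2 * e2) + f^3 * (e1 - e2) * (1 + 2 * e2)) /
    ((e2 + 2) * (e1 + 2 * e2) + 2 * f^3 * (e2 - 1) * (e1 - e2))
}

# shared coarse fixtures ---------------------------------------------------

toy_grid <- function() {
  grid_spec(diameter = c(8, 18, 1), nc_ratio = c(0.75, 0.90, 0.05),
            ri_nucleus = c(1.38, 1.44, 0.02),
            ri_cytoplasm = c(1.35, 1.41, 0.02))
}

toy_optics <- function() optical_config(angle_step = 0.5)

.toy_cache <- new.env(parent = emptyenv())
toy_table <- function() {
  if (is.null(.toy_cache$tab))
    .toy_cache$tab <- build_lookup(toy_grid(), toy_optics(), quiet = TRUE)
  .toy_cache$tab
}

# exhaustive matcher used as the inversion oracle
brute_force_match <- function(curve_norm, table) {
  mse <- apply(table$curves, 1, function(r) mean((r - curve_norm)^2))
  list(index = which.min(mse), residual = min(mse), all = mse)
}
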