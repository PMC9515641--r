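test_that("angular grid and size parameters follow their definitions", {
  opt <- optical_config()
  ang <- lsp_angles(opt)
  expect_length(ang, 281)
  expect_equal(ang[1], 2.0)
  expect_equal(ang[281], 30.0)
  expect_true(all(diff(ang) > 0))

  sp <- size_parameters(core_shell_cell(10, 0.5, 1.42, 1.39), opt)
  expect_equal(sp$y_total, pi * 10 * 1.334 / 0.6328, tolerance = 1e-12)
  expect_equal(sp$x_core, sp$y_total / 2, tolerance = 1e-12)
  expect_equal(sp$y_total, 66.24, tolerance = 1e-3)

  sp1 <- size_parameters(core_shell_cell(10, 1, 1.42, 1.39), opt)
  expect_identical(sp1$x_core, sp1$y_total)

  spm <- size_parameters(core_shell_cell(10, 0.5, 1.334 + 1e-15, 1.334 + 1e-15),
                         opt)
  expect_equal(spm$m_core, 1, tolerance = 1e-12)
  expect_equal(spm$m_shell, 1, tolerance = 1e-12)

  expect_error(core_shell_cell(-1, 0.5, 1.4, 1.38), "diameter")
  expect_error(core_shell_cell(10, 1.2, 1.4, 1.38), "nc_ratio")
})

test_that("coated coefficients reduce to the homogeneous solution", {
  # index-matched particle scatters nothing
  cf0 <- coated_sphere_coefficients(10, 20, 1, 1)
  expect_lt(max(Mod(cf0$a)), 1e-12)
  expect_lt(max(Mod(cf0$b)), 1e-12)

  # equal core/shell index: equals a homogeneous sphere of the full diameter
  m <- 1.40 / 1.334
  cf <- coated_sphere_coefficients(33.12, 66.24, m, m)
  or <- oracle_mie_homog(66.24, m, cf$order_count)
  rel <- function(u, v) Mod(u - v) / pmax(Mod(v), 1e-300)
  expect_lt(max(rel(cf$a, or$a)), 1e-8)
  expect_lt(max(rel(cf$b, or$b)), 1e-8)

  # vanishing core: homogeneous sphere of the shell index
  cfs <- coated_sphere_coefficients(1e-6, 20, 1.2, 1.06)
  ors <- oracle_mie_homog(20, 1.06, cfs$order_count)
  expect_lt(max(rel(cfs$a, ors$a)), 1e-8)

  expect_error(coated_sphere_coefficients(5, 3, 1.1, 1.05), "x_core")
})

test_that("coated coefficients match the quasi-static closed form", {
  # a genuinely layered particle in the dipole limit: the ratio of its a_1
  # to the homogeneous-shell a_1 equals the ratio of polarizabilities
  y <- 0.05; f <- 0.6
  m1 <- 1.10; m2 <- 1.05
  cfc <- coated_sphere_coefficients(f * y, y, m1, m2)
  cfh <- oracle_mie_homog(y, m2, length(cfc$a))
  ratio <- Mod(cfc$a[1] / cfh$a[1])
  expected <- rayleigh_coated_alpha(m1, m2, f) /
    ((m2^2 - 1) / (m2^2 + 2))
  expect_equal(ratio, expected, tolerance = 1e-3)
})

test_that("scattering amplitudes obey forward-limit and Rayleigh behaviour", {
  cf <- coated_sphere_coefficients(5, 10, 1.05, 1.03)
  zero <- cf
  zero$a[] <- 0 + 0i; zero$b[] <- 0 + 0i
  amp0 <- scattering_amplitudes(zero, c(2, 10, 30))
  expect_true(all(Mod(amp0$S1) == 0 & Mod(amp0$S2) == 0))

  amp <- scattering_amplitudes(cf, c(0.001, 15))
  expect_equal(amp$S1[1], amp$S2[1], tolerance = 1e-6)

  # small homogeneous particle: |S1| flat, |S2| ~ |cos(theta)| (dipole
  # limit; magnetic-dipole corrections scale with y^2 and stay below 1%)
  cfr <- coated_sphere_coefficients(0.1, 0.15, 1.04, 1.04)
  th <- c(10, 45, 80, 100, 170)
  ampr <- scattering_amplitudes(cfr, th)
  expect_lt(diff(range(Mod(ampr$S1))) / mean(Mod(ampr$S1)), 0.01)
  expect_equal(Mod(ampr$S2) / Mod(ampr$S1[1]), abs(cos(th * pi / 180)),
               tolerance = 0.01)

  expect_error(scattering_amplitudes(cf, c(0, 10)), "angles")
})

test_that("forward LSP agrees with the brute-force reference", {
  opt <- optical_config(angle_step = 1)  # 29 angles keeps the oracle cheap
  cell <- core_shell_cell(15, 0.85, 1.42, 1.39)
  got <- lsp_intensity(cell, opt)
  ref <- oracle_lsp(cell, opt)
  expect_lt(max(abs(got$intensities - ref) / ref), 1e-6)

  # reduction identity: equal-index cell == homogeneous sphere
  a <- lsp_intensity(core_shell_cell(12, 0.8, 1.40, 1.40), opt)
  b <- lsp_intensity(core_shell_cell(12, 0.3, 1.40, 1.40), opt)
  expect_equal(a$intensities, b$intensities, tolerance = 1e-10)

  # index-matched cell produces a null profile
  zero <- lsp_intensity(core_shell_cell(10, 0.5, 1.334 + 1e-15, 1.334 + 1e-15),
                        opt)
  expect_lt(max(zero$intensities), 1e-16)
})

test_that("coated/homogeneous equivalence holds across random parameters", {
  set.seed(7)
  opt <- optical_config(angle_step = 2)
  for (i in 1:100) {
    d <- runif(1, 2, 8)
    m <- runif(1, 1.35, 1.45)
    nc <- runif(1, 0.1, 0.99)
    cc <- lsp_intensity(core_shell_cell(d, nc, m, m), opt)
    or <- oracle_lsp(core_shell_cell(d, 0.5, m, m), opt)
    expect_lt(max(abs(cc$intensities - or) / or), 1e-8)
  }
})

test_that("integrated window intensity tracks diameter", {
  # bigger cells scatter more into the window overall, but the trend is not
  # strictly monotone at the extremes: below ~8 um Mie ripple dominates and
  # above ~18 um the forward lobe migrates below the 2 degree cut-on
  opt <- optical_config()
  d <- seq(6, 20, by = 0.5)
  cells <- data.frame(diameter_um = d, nc_ratio = 0.85, ri_nucleus = 1.42,
                      ri_cytoplasm = 1.39)
  tot <- rowSums(lsp_intensity(cells, opt))
  expect_gt(cor(d, tot, method = "spearman"), 0.9)
  core <- d >= 9 & d <= 17
  expect_true(all(diff(tot[core]) > 0))
})

test_that("detector pattern and radial average round-trip", {
  opt <- optical_config()   # 0.1 deg bins resolve the fringe structure
  det <- detector_config()
  cell <- core_shell_cell(15.66, 0.85, 1.42, 1.39)
  prof <- lsp_intensity(cell, opt)
  img <- detector_pattern(prof, det)
  back <- radial_average(img, det, opt)
  # reference = the same profile averaged over each 0.1 deg annular bin
  # (binned radial averaging reports bin means, not point samples)
  mid <- which(back$angles >= 3 & back$angles <= 29)
  ref <- vapply(back$angles[mid], function(a) {
    xs <- seq(a - 0.05, a + 0.05, length.out = 21)
    mean(approx(prof$angles, prof$intensities, xout = xs)$y)
  }, numeric(1))
  expect_lt(max(abs(back$intensities[mid] - ref) / ref), 0.02)

  # constant profile -> constant image annulus -> constant recovery
  # (the two boundary bins have partial pixel support and are skipped)
  flat <- lsp(prof$angles, rep(2, length(prof$angles)))
  imgf <- detector_pattern(flat, det)
  backf <- radial_average(imgf, det, opt)
  inner <- seq(2, length(backf$angles) - 1)
  expect_true(all(abs(backf$intensities[inner] - 2) < 1e-9))

  # zero in, zero out
  z <- lsp(prof$angles, rep(0, length(prof$angles)))
  expect_true(all(detector_pattern(z, det) == 0))

  # angular range beyond the sensor is refused
  far <- detector_config(pixel_count = 64, pixel_pitch_um = 10,
                         propagation_distance_mm = 50)
  expect_error(detector_pattern(prof, far), "detector extent")
})
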