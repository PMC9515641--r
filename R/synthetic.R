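#' Default phenotype distributions
#'
#' Per-phenotype Gaussian descriptions of the four biophysical properties
#' for naive monocytes and M0 (unpolarized), M1 (pro-inflammatory) and M2
#' (anti-inflammatory) macrophages, with default sample sizes
#' n = 148/149/167/215. Diameter means and SDs follow the reported
#' population measurements; N/C-ratio and refractive-index dispersions are
#' not reported for these populations and default to SD(N/C) = 0.02 and
#' SD(RI) = 0.006 (see the methods vignette for this calibration).
#'
#' @return Named list of four `phenotype_spec` objects
#'   (`Mono`, `M0`, `M1`, `M2`).
#' @examples
#' default_phenotype_specs()$M0$diameter
#' @export
default_phenotype_specs <- function() {
  mk <- function(label, d_mean, d_sd, nc_mean, rin_mean, ric_mean, n) {
    structure(list(label = label,
                   diameter = c(mean = d_mean, sd = d_sd),
                   nc_ratio = c(mean = nc_mean, sd = 0.02),
                   ri_nucleus = c(mean = rin_mean, sd = 0.006),
                   ri_cytoplasm = c(mean = ric_mean, sd = 0.006),
                   n = n),
              class = "phenotype_spec")
  }
  list(Mono = mk("Mono", 9.82, 1.59, 0.80, 1.39, 1.36, 148L),
       M0   = mk("M0",  15.66, 2.84, 0.85, 1.42, 1.39, 149L),
       M1   = mk("M1",  11.76, 1.72, 0.85, 1.42, 1.38, 167L),
       M2   = mk("M2",  14.25, 2.29, 0.85, 1.43, 1.39, 215L))
}

#' @export
print.phenotype_spec <- function(x, ...) {
  cat(sprintf(paste0("Phenotype %s (n = %d): D %.2f+/-%.2f um, ",
                     "N/C %.2f+/-%.2f, RI_N %.3f+/-%.3f, ",
                     "RI_C %.3f+/-%.3f\n"),
              x$label, x$n, x$diameter[1], x$diameter[2], x$nc_ratio[1],
              x$nc_ratio[2], x$ri_nucleus[1], x$ri_nucleus[2],
              x$ri_cytoplasm[1], x$ri_cytoplasm[2]))
  invisible(x)
}

#' Multiplicative intensity noise model
#'
#' @param multiplicative_sigma Relative standard deviation of the pointwise
#'   lognormal intensity factors (default 0.05 = 5 percent).
#' @param angle_jitter_deg Standard deviation of a per-cell rigid shift of
#'   the angular axis, degrees (default 0).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_sigma = 0.05, angle_jitter_deg = 0) {
  stopifnot(multiplicative_sigma >= 0, angle_jitter_deg >= 0)
  structure(list(multiplicative_sigma = multiplicative_sigma,
                 angle_jitter_deg = angle_jitter_deg),
            class = "noise_model")
}

# truncated-normal draws by rejection (bounds sit far in the tails here)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  guard <- 0L
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal rejection failed to converge")
  }
  out
}

#' Sample cells from a phenotype distribution
#'
#' Independent truncated-Gaussian draws per property, truncated at the
#' lookup-grid bounds so that every sampled cell is invertible.
#'
#' @param spec A `phenotype_spec` (see [default_phenotype_specs()]).
#' @param n Number of cells (defaults to the spec's `n`).
#' @param seed Integer seed; required for reproducibility.
#' @param grid A [grid_spec()] giving the truncation bounds.
#' @return Data frame of cells (`diameter_um`, `nc_ratio`, `ri_nucleus`,
#'   `ri_cytoplasm`, `label`).
#' @export
sample_cells <- function(spec, n = spec$n, seed = NULL,
                         grid = grid_spec()) {
  stopifnot(inherits(spec, "phenotype_spec"), n >= 1,
            inherits(grid, "grid_spec"))
  means <- c(spec$diameter[1], spec$nc_ratio[1], spec$ri_nucleus[1],
             spec$ri_cytoplasm[1])
  lo <- vapply(grid, `[`, numeric(1), 1)
  hi <- vapply(grid, `[`, numeric(1), 2)
  if (any(means < lo | means > hi))
    stop("phenotype means lie outside the lookup grid bounds")
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    diameter_um = .rtruncnorm(n, spec$diameter[1], spec$diameter[2],
                              lo[1], hi[1]),
    nc_ratio = .rtruncnorm(n, spec$nc_ratio[1], spec$nc_ratio[2],
                           lo[2], hi[2]),
    ri_nucleus = .rtruncnorm(n, spec$ri_nucleus[1], spec$ri_nucleus[2],
                             lo[3], hi[3]),
    ri_cytoplasm = .rtruncnorm(n, spec$ri_cytoplasm[1], spec$ri_cytoplasm[2],
                               lo[4], hi[4]),
    label = rep(spec$label, n), stringsAsFactors = FALSE)
}

#' Apply instrument noise to an LSP
#'
#' Multiplies the intensities pointwise by lognormal factors (median 1,
#' log-sd equal to `multiplicative_sigma`), optionally after a rigid jitter
#' of the angular axis. Nonnegativity is preserved; a zero profile stays
#' zero.
#'
#' @param x An [lsp()] or a numeric intensity matrix (cells x angles).
#' @param model A [noise_model()].
#' @param seed Optional integer seed.
#' @param angles Angle grid for matrix input with jitter.
#' @return Same shape as the input.
#' @export
add_noise <- function(x, model = noise_model(), seed = NULL, angles = NULL) {
  stopifnot(inherits(model, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  jitter1 <- function(ang, ints) {
    if (model$angle_jitter_deg == 0) return(ints)
    sh <- rnorm(1, 0, model$angle_jitter_deg)
    approx(ang + sh, ints, xout = ang, rule = 2)$y
  }
  if (inherits(x, "lsp")) {
    ints <- jitter1(x$angles, x$intensities)
    if (model$multiplicative_sigma > 0)
      ints <- ints * rlnorm(length(ints), 0, model$multiplicative_sigma)
    return(lsp(x$angles, ints, meta = c(x$meta, list(noise = unclass(model)))))
  }
  stopifnot(is.matrix(x))
  out <- x
  for (i in seq_len(nrow(out))) {
    v <- if (is.null(angles)) out[i, ] else jitter1(angles, out[i, ])
    if (model$multiplicative_sigma > 0)
      v <- v * rlnorm(length(v), 0, model$multiplicative_sigma)
    out[i, ] <- v
  }
  out
}

#' Simulate a labelled LSP dataset
#'
#' Full generative stand-in for the scattering instrument: per phenotype,
#' sample cells from the property distributions, forward-model their LSPs
#' on the configured angular grid, then apply multiplicative noise. All
#' randomness derives from the single `seed`.
#'
#' @param specs List of `phenotype_spec`s (default all four populations).
#' @param optics An [optical_config()].
#' @param noise A [noise_model()].
#' @param seed Integer root seed (required).
#' @param n_override Optional named integer vector overriding per-spec
#'   sample sizes, e.g. `c(Mono = 107)`.
#' @return Object of class `lsp_set`: `angles`, `intensities` (cells x
#'   angles), `labels`, `truth` (sampled cell parameters) and `meta`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(default_phenotype_specs()["M1"], seed = 1,
#'                        n_override = c(M1 = 5))
#' dim(ds$intensities)
#' }
#' @export
simulate_dataset <- function(specs = default_phenotype_specs(),
                             optics = optical_config(),
                             noise = noise_model(), seed,
                             n_override = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(inherits(optics, "optical_config"), inherits(noise, "noise_model"))
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, 2L * length(specs))
  cells <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    n <- sp$n
    if (!is.null(n_override) && sp$label %in% names(n_override))
      n <- n_override[[sp$label]]
    cells[[i]] <- sample_cells(sp, n = n, seed = subseeds[2 * i - 1])
  }
  truth <- do.call(rbind, cells)
  rownames(truth) <- NULL
  ints <- lsp_intensity(truth, optics)
  for (i in seq_along(specs)) {
    rows <- which(truth$label == specs[[i]]$label)
    set.seed(subseeds[2 * i])
    ints[rows, ] <- add_noise(ints[rows, , drop = FALSE], noise,
                              angles = lsp_angles(optics))
  }
  structure(list(angles = lsp_angles(optics), intensities = ints,
                 labels = truth$label, truth = truth,
                 meta = list(seed = seed, noise = unclass(noise),
                             optics = unclass(optics))),
            class = "lsp_set")
}

#' @export
print.lsp_set <- function(x, ...) {
  cat(sprintf("LSP set: %d cells x %d angles\n", nrow(x$intensities),
              length(x$angles)))
  print(table(x$labels))
  invisible(x)
}

#' Write / read an LSP set as flat CSV
#'
#' One row per cell: intensity columns named `a<angle>` followed by the
#' phenotype label. The angle grid is recovered from the header on read.
#'
#' @param x An `lsp_set`.
#' @param path CSV file path.
#' @return `read_lsp_csv` returns an `lsp_set` (without ground truth).
#' @export
write_lsp_csv <- function(x, path) {
  stopifnot(inherits(x, "lsp_set"))
  df <- as.data.frame(x$intensities)
  names(df) <- paste0("a", format(x$angles, trim = TRUE))
  df$label <- x$labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lsp_csv
#' @export
read_lsp_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  acol <- grep("^a[0-9]", names(df))
  structure(list(angles = as.numeric(sub("^a", "", names(df)[acol])),
                 intensities = as.matrix(df[, acol]),
                 labels = if ("label" %in% names(df)) df$label else NULL,
                 truth = NULL, meta = list(source = path)),
            class = "lsp_set")
}
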