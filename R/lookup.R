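#' Parameter grid of the lookup table
#'
#' Defines the four axes of the inversion grid as (min, max, step) triples.
#' The defaults span the biophysical ranges observed for monocytes and
#' macrophage phenotypes with margin: diameter 6--20 um in 0.25 um steps
#' (57), N/C ratio 0.70--0.95 in 0.01 steps (26), nuclear RI 1.36--1.46 in
#' 0.005 steps (21) and cytoplasmic RI 1.33--1.43 in 0.01 steps (11), i.e.
#' 342 342 parameter tuples in total.
#'
#' @param diameter,nc_ratio,ri_nucleus,ri_cytoplasm Numeric `c(min, max,
#'   step)` per axis.
#' @return Object of class `grid_spec`.
#' @examples
#' prod(grid_axis_counts(grid_spec()))  # 342342
#' @export
grid_spec <- function(diameter = c(6, 20, 0.25),
                      nc_ratio = c(0.70, 0.95, 0.01),
                      ri_nucleus = c(1.36, 1.46, 0.005),
                      ri_cytoplasm = c(1.33, 1.43, 0.01)) {
  axes <- list(diameter = diameter, nc_ratio = nc_ratio,
               ri_nucleus = ri_nucleus, ri_cytoplasm = ri_cytoplasm)
  for (nm in names(axes)) {
    a <- axes[[nm]]
    if (length(a) != 3 || !all(is.finite(a)))
      stop(nm, " must be c(min, max, step)")
    if (!(a[1] < a[2])) stop(nm, ": min must be below max")
    if (!(a[3] > 0)) stop(nm, ": step must be positive")
    if (a[3] > (a[2] - a[1]) * (1 + 1e-9))
      stop(nm, ": step larger than the axis range")
  }
  structure(axes, class = "grid_spec")
}

.axis_values <- function(a) {
  n <- floor((a[2] - a[1]) / a[3] + 1e-9) + 1L
  a[1] + a[3] * (seq_len(n) - 1)
}

#' @rdname grid_spec
#' @param spec A `grid_spec`.
#' @return `grid_axis_counts`: named integer vector of points per axis.
#' @export
grid_axis_counts <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  vapply(spec, function(a) length(.axis_values(a)), integer(1))
}

#' @export
print.grid_spec <- function(x, ...) {
  cnt <- grid_axis_counts(x)
  cat("Lookup grid specification\n")
  for (nm in names(x))
    cat(sprintf("  %-12s: %g to %g step %g (%d)\n", nm, x[[nm]][1],
                x[[nm]][2], x[[nm]][3], cnt[[nm]]))
  cat(sprintf("  total tuples: %d\n", prod(cnt)))
  invisible(x)
}

#' Enumerate the parameter tuples of a grid
#'
#' Cartesian product in deterministic lexicographic order: diameter varies
#' slowest, then N/C ratio, then nuclear RI, with cytoplasmic RI fastest.
#'
#' @param spec A [grid_spec()].
#' @param cap Refuse grids with more than this many tuples.
#' @return Data frame with columns `diameter_um`, `nc_ratio`, `ri_nucleus`,
#'   `ri_cytoplasm`, one row per tuple.
#' @export
build_grid <- function(spec, cap = 5e6) {
  stopifnot(inherits(spec, "grid_spec"))
  cnt <- grid_axis_counts(spec)
  if (prod(cnt) > cap)
    stop(sprintf("grid has %.0f tuples, exceeding the cap of %.0f",
                 prod(cnt), cap))
  vals <- lapply(spec, .axis_values)
  g <- expand.grid(ri_cytoplasm = vals$ri_cytoplasm,
                   ri_nucleus = vals$ri_nucleus,
                   nc_ratio = vals$nc_ratio,
                   diameter_um = vals$diameter,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("diameter_um", "nc_ratio", "ri_nucleus", "ri_cytoplasm")]
}

#' Log unit-mean normalisation of an LSP
#'
#' Matching is scale-invariant (no radiometric calibration): profiles are
#' scaled to unit mean intensity and compared in log10. Intensities below
#' 1e-12 of the mean are floored before taking the logarithm so that exact
#' interference nulls cannot dominate the metric.
#'
#' @param x An [lsp()] or a nonnegative numeric vector.
#' @return Numeric vector, `log10(I / mean(I))`.
#' @export
normalize_lsp <- function(x) {
  v <- if (inherits(x, "lsp")) x$intensities else as.numeric(x)
  if (any(v < 0)) stop("intensities must be nonnegative")
  m <- mean(v)
  if (!(m > 0)) stop("cannot normalise an all-zero profile")
  log10(pmax(v, m * 1e-12) / m)
}

#' Build the theoretical-LSP lookup table
#'
#' Forward-models one LSP per grid tuple and stores the curves in the
#' log unit-mean normalisation used for matching. Rebuilding with an
#' identical configuration is deterministic and bit-identical. An optional
#' cache file (RDS) avoids recomputation; the cache stores a configuration
#' fingerprint and loading it with a different grid or optics errors.
#'
#' @param spec A [grid_spec()].
#' @param optics An [optical_config()].
#' @param cache_path Optional path of an `.rds` cache file.
#' @param quiet Suppress the progress message.
#' @return Object of class `lookup_table` with elements `grid`, `params`
#'   (data frame of tuples), `curves` (normalised log10 matrix, tuples x
#'   angles), `optics`, `normalization`, `config_hash`.
#' @export
build_lookup <- function(spec = grid_spec(), optics = optical_config(),
                         cache_path = NULL, quiet = FALSE) {
  stopifnot(inherits(spec, "grid_spec"), inherits(optics, "optical_config"))
  hash <- .config_fingerprint(spec, optics)
  if (!is.null(cache_path) && file.exists(cache_path)) {
    tab <- readRDS(cache_path)
    if (!identical(tab$config_hash, hash))
      stop("lookup cache at ", cache_path,
           " was built with a different configuration")
    return(tab)
  }
  params <- build_grid(spec)
  if (!quiet)
    message(sprintf("building lookup table: %d curves x %d angles",
                    nrow(params), length(lsp_angles(optics))))
  pol <- match(optics$polarization,
               c("unpolarized", "perpendicular", "parallel")) - 1L
  curves <- .lsp_batch_cpp(params$diameter_um, params$nc_ratio,
                           params$ri_nucleus, params$ri_cytoplasm,
                           optics$wavelength_nm, optics$medium_ri,
                           lsp_angles(optics), pol, TRUE)
  tab <- structure(list(grid = spec, params = params, curves = curves,
                        rowsq = rowSums(curves^2), optics = optics,
                        normalization = "log10-unit-mean",
                        config_hash = hash),
                   class = "lookup_table")
  if (!is.null(cache_path)) saveRDS(tab, cache_path)
  tab
}

.config_fingerprint <- function(spec, optics) {
  paste(c("v1", vapply(spec, function(a) paste(format(a, digits = 15),
                                               collapse = ","),
                       character(1)),
          format(unlist(optics[c("wavelength_nm", "medium_ri", "angle_min",
                                 "angle_max", "angle_step")]), digits = 15),
          optics$polarization),
        collapse = "|")
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("Lookup table: %d theoretical LSPs x %d angles (%s)\n",
              nrow(x$curves), ncol(x$curves), x$normalization))
  print(x$grid)
  invisible(x)
}

# Interpolate a query LSP onto the table's angle grid; extrapolation is
# refused (the query must cover the table window).
.resample_to_grid <- function(q_angles, q_int, t_angles) {
  if (isTRUE(all.equal(q_angles, t_angles, tolerance = 1e-9)))
    return(q_int)
  if (min(q_angles) > min(t_angles) + 1e-9 ||
        max(q_angles) < max(t_angles) - 1e-9)
    stop("query LSP does not cover the lookup-table angular range")
  approx(q_angles, q_int, xout = t_angles, rule = 1)$y
}

# Batch nearest-row search on normalised curves. Returns 1-based indices and
# exact MSE residuals; ties break to the lowest row index.
.match_batch <- function(table, queries_norm) {
  stopifnot(is.matrix(queries_norm),
            ncol(queries_norm) == ncol(table$curves))
  nq <- nrow(queries_norm)
  p <- ncol(table$curves)
  idx <- integer(nq)
  resid <- numeric(nq)
  gap <- numeric(nq)
  block <- 64L
  for (s in seq(1, nq, by = block)) {
    e <- min(s + block - 1L, nq)
    qb <- queries_norm[s:e, , drop = FALSE]
    cross <- table$curves %*% t(qb)                     # N x b
    qn <- rowSums(qb^2)
    for (j in seq_len(ncol(cross))) {
      score <- table$rowsq - 2 * cross[, j]             # + qn[j], const
      i1 <- which.min(score)
      # exact residual for the winner (avoids cancellation noise); values
      # at double-precision rounding level report as an exact self-match
      d <- table$curves[i1, ] - qb[j, ]
      r1 <- sum(d * d) / p
      if (r1 < 1e-18) r1 <- 0
      s2 <- sort(score, partial = 2)[2]
      r2 <- max((s2 + qn[j]) / p, 0)
      idx[s + j - 1L] <- i1
      resid[s + j - 1L] <- r1
      gap[s + j - 1L] <- max(r2 - r1, 0)
    }
  }
  list(index = idx, residual = resid, runner_up_gap = gap)
}

#' Match one LSP against the lookup table
#'
#' Finds the grid tuple whose theoretical profile minimises the mean squared
#' difference of log unit-mean normalised curves. Queries on a different
#' angle grid are linearly interpolated onto the table grid; extrapolation
#' is refused.
#'
#' @param x An [lsp()].
#' @param table A [build_lookup()] table.
#' @return Object of class `match_result`: `best` (a [core_shell_cell()]),
#'   `residual` (minimised mean squared log-difference) and
#'   `runner_up_gap` (residual margin to the second-best row).
#' @examples
#' \donttest{
#' tab <- build_lookup(grid_spec(c(8, 12, 2), c(0.7, 0.9, 0.1),
#'                               c(1.40, 1.44, 0.02), c(1.36, 1.38, 0.01)),
#'                     quiet = TRUE)
#' obs <- lsp_intensity(core_shell_cell(10, 0.8, 1.42, 1.37))
#' match_lsp(obs, tab)
#' }
#' @export
match_lsp <- function(x, table) {
  stopifnot(inherits(x, "lsp"), inherits(table, "lookup_table"))
  t_ang <- lsp_angles(table$optics)
  v <- .resample_to_grid(x$angles, x$intensities, t_ang)
  q <- matrix(normalize_lsp(v), nrow = 1)
  m <- .match_batch(table, q)
  best <- table$params[m$index, ]
  structure(list(best = core_shell_cell(best$diameter_um, best$nc_ratio,
                                        best$ri_nucleus, best$ri_cytoplasm),
                 index = m$index, residual = m$residual,
                 runner_up_gap = m$runner_up_gap),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("Lookup match\n  ")
  print(x$best)
  cat(sprintf("  residual = %.4g (runner-up gap %.4g)\n",
              x$residual, x$runner_up_gap))
  invisible(x)
}

#' Invert a set of LSPs to biophysical properties
#'
#' The central estimator of the package: every observed profile is matched
#' against the lookup table and summarised by the four retrieved properties.
#' Per-record failures (for example profiles that cannot be normalised) are
#' flagged, never silently dropped.
#'
#' @param x An `lsp_set` (see [simulate_dataset()]), a numeric matrix of
#'   intensities (cells x angles, on the table's angle grid), or a list of
#'   [lsp()] objects.
#' @param table A [build_lookup()] table.
#' @param labels Optional character/factor vector of phenotype labels, one
#'   per profile (taken from an `lsp_set` automatically).
#' @return Object of class `lsp_fit` with methods [coef.lsp_fit()],
#'   [residuals.lsp_fit()], [predict.lsp_fit()], `print` and `summary`. The
#'   coefficient table has columns `D_um`, `nc_ratio`, `ri_n`, `ri_c`,
#'   `label`, `residual`, `flagged`.
#' @export
lsp_fit <- function(x, table, labels = NULL) {
  stopifnot(inherits(table, "lookup_table"))
  t_ang <- lsp_angles(table$optics)
  if (inherits(x, "lsp_set")) {
    labels <- if (is.null(labels)) x$labels else labels
    mat <- x$intensities
    angles <- x$angles
  } else if (is.matrix(x)) {
    mat <- x
    angles <- t_ang
    if (ncol(mat) != length(t_ang))
      stop("matrix input must be on the lookup-table angle grid")
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "lsp"))) {
    if (length(x) == 0) stop("empty input")
    mat <- do.call(rbind, lapply(x, function(l)
      .resample_to_grid(l$angles, l$intensities, t_ang)))
    angles <- t_ang
  } else stop("unsupported input type")
  if (nrow(mat) == 0) stop("empty input")

  n <- nrow(mat)
  qnorm_mat <- matrix(NA_real_, n, length(t_ang))
  flagged <- logical(n)
  notes <- character(n)
  for (i in seq_len(n)) {
    qi <- tryCatch(normalize_lsp(.resample_to_grid(angles, mat[i, ], t_ang)),
                   error = function(e) e)
    if (inherits(qi, "error")) {
      flagged[i] <- TRUE
      notes[i] <- conditionMessage(qi)
    } else qnorm_mat[i, ] <- qi
  }
  ok <- !flagged
  coefs <- data.frame(D_um = rep(NA_real_, n), nc_ratio = rep(NA_real_, n),
                      ri_n = rep(NA_real_, n), ri_c = rep(NA_real_, n),
                      label = if (is.null(labels)) rep(NA_character_, n)
                              else as.character(labels),
                      residual = rep(NA_real_, n), flagged = flagged,
                      stringsAsFactors = FALSE)
  gaps <- rep(NA_real_, n)
  if (any(ok)) {
    m <- .match_batch(table, qnorm_mat[ok, , drop = FALSE])
    best <- table$params[m$index, ]
    coefs$D_um[ok] <- best$diameter_um
    coefs$nc_ratio[ok] <- best$nc_ratio
    coefs$ri_n[ok] <- best$ri_nucleus
    coefs$ri_c[ok] <- best$ri_cytoplasm
    coefs$residual[ok] <- m$residual
    gaps[ok] <- m$runner_up_gap
  }
  if (any(flagged))
    warning(sum(flagged), " profile(s) could not be inverted and were ",
            "flagged")
  structure(list(coefficients = coefs, runner_up_gap = gaps, notes = notes,
                 table_hash = table$config_hash, grid = table$grid,
                 optics = table$optics, call = match.call()),
            class = "lsp_fit")
}

#' Feature table from a batch of LSPs
#'
#' Thin wrapper around [lsp_fit()] returning the plain feature data frame
#' consumed by the classification stage.
#'
#' @inheritParams lsp_fit
#' @return Data frame with columns `D_um`, `nc_ratio`, `ri_n`, `ri_c`,
#'   `label`, `residual`, `flagged`, rows in input order.
#' @export
batch_extract_features <- function(x, table, labels = NULL) {
  coef(lsp_fit(x, table, labels))
}

#' @export
coef.lsp_fit <- function(object, ...) object$coefficients

#' @export
residuals.lsp_fit <- function(object, ...) object$coefficients$residual

#' @export
print.lsp_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("LSP inversion fit: %d profiles (%d flagged)\n", nrow(cf),
              sum(cf$flagged)))
  print(head(cf, 6))
  if (nrow(cf) > 6) cat(sprintf("  ... %d more rows\n", nrow(cf) - 6))
  invisible(x)
}

#' @export
summary.lsp_fit <- function(object, ...) {
  cf <- object$coefficients[!object$coefficients$flagged, ]
  by_lab <- if (all(is.na(cf$label))) list(all = cf)
            else split(cf, cf$label)
  tab <- do.call(rbind, lapply(names(by_lab), function(nm) {
    s <- by_lab[[nm]]
    data.frame(label = nm, n = nrow(s), D_um = mean(s$D_um),
               nc_ratio = mean(s$nc_ratio), ri_n = mean(s$ri_n),
               ri_c = mean(s$ri_c), residual = mean(s$residual))
  }))
  structure(list(means = tab, n_flagged = sum(object$coefficients$flagged)),
            class = "summary.lsp_fit")
}

#' @export
print.summary.lsp_fit <- function(x, ...) {
  cat("Recovered population means\n")
  print(x$means, row.names = FALSE, digits = 4)
  if (x$n_flagged > 0) cat(sprintf("%d profile(s) flagged\n", x$n_flagged))
  invisible(x)
}

#' @describeIn lsp_fit forward-model the theoretical LSPs of the recovered
#'   parameter tuples (rows of flagged records are `NA`).
#' @param object,... Method arguments.
#' @export
predict.lsp_fit <- function(object, ...) {
  cf <- object$coefficients
  out <- matrix(NA_real_, nrow(cf), length(lsp_angles(object$optics)))
  ok <- !cf$flagged
  if (any(ok)) {
    cells <- data.frame(diameter_um = cf$D_um[ok], nc_ratio = cf$nc_ratio[ok],
                        ri_nucleus = cf$ri_n[ok], ri_cytoplasm = cf$ri_c[ok])
    out[ok, ] <- lsp_intensity(cells, object$optics)
  }
  out
}
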