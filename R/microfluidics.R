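#' Viscoelastic alignment parameters
#'
#' Operating point of the viscoelastic focusing stage that drives cells onto
#' the centreline of the round glass capillary ahead of the optical readout.
#' Defaults describe the dilute PEO carrier fluid and capillary geometry of
#' the reference device.
#'
#' @param relaxation_time_ms Fluid relaxation time, milliseconds.
#' @param mean_velocity_um_s Average fluid velocity, micrometres per second.
#' @param channel_radius_um Capillary radius R, micrometres.
#' @param channel_length_m Capillary length L, metres.
#' @param cell_radius_um Cell radius r1, micrometres; must be below R.
#' @return Object of class `alignment_params`.
#' @export
alignment_params <- function(relaxation_time_ms = 0.197,
                             mean_velocity_um_s = 1496,
                             channel_radius_um = 25,
                             channel_length_m = 0.35,
                             cell_radius_um) {
  vals <- c(relaxation_time_ms, mean_velocity_um_s, channel_radius_um,
            channel_length_m, cell_radius_um)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all alignment parameters must be finite and positive")
  if (cell_radius_um >= channel_radius_um)
    stop("cell radius must be smaller than the channel radius")
  structure(list(relaxation_time_ms = relaxation_time_ms,
                 mean_velocity_um_s = mean_velocity_um_s,
                 channel_radius_um = channel_radius_um,
                 channel_length_m = channel_length_m,
                 cell_radius_um = cell_radius_um),
            class = "alignment_params")
}

#' Weissenberg number of the focusing flow
#'
#' `Wi = lambda * Ubar / R` with the relaxation time in seconds and velocity
#' and radius in consistent micrometre units (the shear-rate scale of a
#' pipe flow of mean velocity Ubar and radius R).
#'
#' @param p An [alignment_params()].
#' @return Dimensionless Weissenberg number.
#' @examples
#' weissenberg(alignment_params(cell_radius_um = 5))  # about 0.0118
#' @export
weissenberg <- function(p) {
  stopifnot(inherits(p, "alignment_params"))
  (p$relaxation_time_ms * 1e-3) * p$mean_velocity_um_s / p$channel_radius_um
}

#' Three-dimensional alignment criterion
#'
#' Centreline focusing over the channel length is predicted when
#' `3 Wi beta^2 (L / 2R) > -ln(3.5 beta)` with `beta = r1 / R`. The margin
#' (left side minus right side) is returned along with the verdict; the
#' margin grows with Wi, channel length and cell size, so larger or slower
#' relaxing cells focus more easily.
#'
#' @param p An [alignment_params()].
#' @return Object of class `alignment_check`: `satisfied`, `margin`, `wi`,
#'   `beta`, `lhs`, `rhs`.
#' @examples
#' alignment_satisfied(alignment_params(cell_radius_um = 5))
#' @export
alignment_satisfied <- function(p) {
  stopifnot(inherits(p, "alignment_params"))
  beta <- p$cell_radius_um / p$channel_radius_um
  wi <- weissenberg(p)
  lhs <- 3 * wi * beta^2 *
    (p$channel_length_m * 1e6 / (2 * p$channel_radius_um))
  rhs <- -log(3.5 * beta)
  margin <- lhs - rhs
  structure(list(satisfied = margin > 0, margin = margin, wi = wi,
                 beta = beta, lhs = lhs, rhs = rhs, params = p),
            class = "alignment_check")
}

#' @export
print.alignment_check <- function(x, ...) {
  cat("Viscoelastic alignment check\n")
  cat(sprintf("  Wi = %.4g, beta = %.3f\n", x$wi, x$beta))
  cat(sprintf("  criterion: %.4g > %.4g  ->  %s (margin %.4g)\n",
              x$lhs, x$rhs,
              if (x$satisfied) "aligned" else "NOT aligned", x$margin))
  invisible(x)
}
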