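#' Optical configuration of the scattering readout
#'
#' Describes the illumination and the angular window over which
#' light-scattering profiles (LSPs) are recorded: a collimated HeNe-type beam
#' (632.8 nm) scattered by a single cell in aqueous buffer, collected over
#' small-to-mid polar angles.
#'
#' The angular grid is inclusive of `angle_min` and contains
#' `floor((angle_max - angle_min)/angle_step) + 1` points; the defaults give
#' 281 points on 2--30 degrees at 0.1 degree resolution.
#'
#' @param wavelength_nm Vacuum wavelength of the laser, nm.
#' @param medium_ri Refractive index of the suspension medium (PBS with a
#'   dilute viscoelastic polymer barely shifts the PBS value, hence 1.334).
#' @param angle_min,angle_max,angle_step Polar angle window and resolution,
#'   degrees.
#' @param polarization One of `"unpolarized"` (default, the average
#'   `(|S1|^2 + |S2|^2)/2`), `"perpendicular"` (`|S1|^2`) or `"parallel"`
#'   (`|S2|^2`).
#' @return An object of class `optical_config`.
#' @examples
#' opt <- optical_config()
#' length(lsp_angles(opt))  # 281
#' @export
optical_config <- function(wavelength_nm = 632.8, medium_ri = 1.334,
                           angle_min = 2.0, angle_max = 30.0,
                           angle_step = 0.1,
                           polarization = c("unpolarized", "perpendicular",
                                            "parallel")) {
  polarization <- match.arg(polarization)
  stopifnot(wavelength_nm > 0, medium_ri >= 1, angle_step > 0)
  if (!(angle_min > 0 && angle_min < angle_max && angle_max <= 180))
    stop("require 0 < angle_min < angle_max <= 180")
  structure(list(wavelength_nm = wavelength_nm, medium_ri = medium_ri,
                 angle_min = angle_min, angle_max = angle_max,
                 angle_step = angle_step, polarization = polarization),
            class = "optical_config")
}

#' Angular grid of an optical configuration
#'
#' @param optics An [optical_config()].
#' @return Numeric vector of polar angles in degrees, strictly increasing,
#'   starting at `angle_min`.
#' @export
lsp_angles <- function(optics) {
  stopifnot(inherits(optics, "optical_config"))
  n <- floor((optics$angle_max - optics$angle_min) / optics$angle_step +
               1e-9) + 1L
  optics$angle_min + optics$angle_step * (seq_len(n) - 1)
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  wavelength : %.1f nm (in medium n = %.4f)\n",
              x$wavelength_nm, x$medium_ri))
  cat(sprintf("  angles     : %.1f - %.1f deg, step %.2f deg (%d points)\n",
              x$angle_min, x$angle_max, x$angle_step, length(lsp_angles(x))))
  cat(sprintf("  detection  : %s\n", x$polarization))
  invisible(x)
}

#' Core-shell biophysical cell model
#'
#' A cell is idealised as two concentric spheres: the nucleus (core) of
#' refractive index `ri_nucleus` inside the cytoplasm (shell) of index
#' `ri_cytoplasm`. The four parameters are exactly the properties retrieved
#' by lookup-table inversion: total diameter D, nucleus/cytoplasm diameter
#' ratio (N/C ratio), RI_N and RI_C.
#'
#' @param diameter_um Total cell diameter, micrometres.
#' @param nc_ratio Core diameter as a fraction of the total diameter,
#'   in (0, 1].
#' @param ri_nucleus,ri_cytoplasm Refractive indices of core and shell,
#'   each in (1, 2).
#' @return An object of class `core_shell_cell` (also a one-row list).
#' @examples
#' core_shell_cell(15.66, 0.85, 1.42, 1.39)
#' @export
core_shell_cell <- function(diameter_um, nc_ratio, ri_nucleus, ri_cytoplasm) {
  stopifnot(length(diameter_um) == 1, length(nc_ratio) == 1,
            length(ri_nucleus) == 1, length(ri_cytoplasm) == 1)
  if (!(diameter_um > 0)) stop("diameter must be positive")
  if (!(nc_ratio > 0 && nc_ratio <= 1)) stop("nc_ratio must be in (0, 1]")
  if (!(ri_nucleus > 1 && ri_nucleus < 2 && ri_cytoplasm > 1 &&
          ri_cytoplasm < 2))
    stop("refractive indices must lie in (1, 2)")
  structure(list(diameter_um = diameter_um, nc_ratio = nc_ratio,
                 ri_nucleus = ri_nucleus, ri_cytoplasm = ri_cytoplasm),
            class = "core_shell_cell")
}

#' @export
print.core_shell_cell <- function(x, ...) {
  cat(sprintf(
    "Core-shell cell: D = %.2f um, N/C = %.3f, RI_N = %.4f, RI_C = %.4f\n",
    x$diameter_um, x$nc_ratio, x$ri_nucleus, x$ri_cytoplasm))
  invisible(x)
}

#' Mie nondimensionalisation of a core-shell cell
#'
#' Converts a cell and optical configuration into the dimensionless inputs of
#' the coated-sphere scattering solution: size parameters of core and total
#' sphere and relative refractive indices of core and shell.
#'
#' @param cell A [core_shell_cell()].
#' @param optics An [optical_config()].
#' @return List with `x_core`, `y_total`, `m_core`, `m_shell`.
#' @export
size_parameters <- function(cell, optics) {
  stopifnot(inherits(cell, "core_shell_cell"),
            inherits(optics, "optical_config"))
  lam_um <- optics$wavelength_nm / 1000
  y <- pi * cell$diameter_um * optics$medium_ri / lam_um
  list(x_core = y * cell$nc_ratio, y_total = y,
       m_core = cell$ri_nucleus / optics$medium_ri,
       m_shell = cell$ri_cytoplasm / optics$medium_ri)
}

#' Partial-wave coefficients of the coated sphere
#'
#' Computes the electromagnetic scattering coefficients `a_n`, `b_n` of a
#' concentric two-layer sphere (Aden-Kerker solution), truncated at the
#' Wiscombe order `n_max = ceil(y + 4 y^(1/3) + 2)`. When the core and shell
#' indices coincide (or the core fills the sphere) the computation delegates
#' to the homogeneous Mie solution.
#'
#' @param x_core Core size parameter (`pi * d_core * n_medium / lambda`).
#' @param y_total Total size parameter; must satisfy `x_core <= y_total`.
#' @param m_core,m_shell Refractive indices of core and shell relative to the
#'   medium.
#' @return An object of class `mie_coefficients` with complex vectors `a`,
#'   `b` of length `n_max`.
#' @examples
#' sp <- size_parameters(core_shell_cell(10, 0.5, 1.40, 1.37),
#'                       optical_config())
#' cf <- coated_sphere_coefficients(sp$x_core, sp$y_total,
#'                                  sp$m_core, sp$m_shell)
#' cf$n_max
#' @export
coated_sphere_coefficients <- function(x_core, y_total, m_core, m_shell) {
  if (!(x_core > 0 && y_total > 0 && x_core <= y_total * (1 + 1e-12)))
    stop("require 0 < x_core <= y_total")
  if (!all(is.finite(c(m_core, m_shell))) || m_core <= 0 || m_shell <= 0)
    stop("relative indices must be finite and positive")
  res <- .mie_coated_coeffs_cpp(x_core, y_total, m_core, m_shell)
  structure(list(a = res$a, b = res$b, order_count = res$n_max),
            class = "mie_coefficients")
}

#' Scattering amplitudes S1, S2 at given angles
#'
#' Sums the partial-wave series
#' `S1 = sum (2n+1)/(n(n+1)) (a_n pi_n + b_n tau_n)` (and `S2` with the
#' angular functions swapped) over the truncated coefficient set.
#'
#' @param coeffs A `mie_coefficients` object.
#' @param angles_deg Polar angles in degrees, each in (0, 180).
#' @return List with complex vectors `S1` and `S2`.
#' @export
scattering_amplitudes <- function(coeffs, angles_deg) {
  stopifnot(inherits(coeffs, "mie_coefficients"))
  if (any(angles_deg <= 0 | angles_deg >= 180))
    stop("angles must lie in (0, 180) degrees")
  .mie_amplitudes_cpp(coeffs$a, coeffs$b, as.numeric(angles_deg))
}

#' Light-scattering profile (LSP) container
#'
#' @param angles_deg Strictly increasing polar angles, degrees.
#' @param intensities Nonnegative relative intensities, same length.
#' @param meta Optional provenance list (cell parameters, seed, noise).
#' @return Object of class `lsp`.
#' @export
lsp <- function(angles_deg, intensities, meta = list()) {
  if (length(angles_deg) != length(intensities))
    stop("angles and intensities must have equal length")
  if (any(diff(angles_deg) <= 0)) stop("angles must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  structure(list(angles = as.numeric(angles_deg),
                 intensities = as.numeric(intensities), meta = meta),
            class = "lsp")
}

#' @export
print.lsp <- function(x, ...) {
  cat(sprintf("LSP: %d angles on [%.2f, %.2f] deg, peak intensity %.4g\n",
              length(x$angles), min(x$angles), max(x$angles),
              max(x$intensities)))
  invisible(x)
}

#' Forward-model the LSP of a core-shell cell
#'
#' The instrument observable: relative scattered intensity versus polar angle
#' on the configured angular grid, computed from the coated-sphere solution.
#' Under the default unpolarized detection the intensity is
#' `(|S1|^2 + |S2|^2)/2`.
#'
#' @param cell A [core_shell_cell()] or a data frame of cells (columns
#'   `diameter_um`, `nc_ratio`, `ri_nucleus`, `ri_cytoplasm`), in which case
#'   a matrix with one row per cell is returned.
#' @param optics An [optical_config()].
#' @return For a single cell, an [lsp()]; for a data frame, a numeric matrix
#'   (cells x angles) with the angle grid in `dimnames` attribute-free form
#'   accessible via [lsp_angles()].
#' @examples
#' prof <- lsp_intensity(core_shell_cell(15, 0.85, 1.42, 1.39),
#'                       optical_config())
#' range(prof$intensities)
#' @export
lsp_intensity <- function(cell, optics = optical_config()) {
  stopifnot(inherits(optics, "optical_config"))
  pol <- match(optics$polarization,
               c("unpolarized", "perpendicular", "parallel")) - 1L
  ang <- lsp_angles(optics)
  if (is.data.frame(cell)) {
    .validate_cell_frame(cell)
    return(.lsp_batch_cpp(cell$diameter_um, cell$nc_ratio, cell$ri_nucleus,
                          cell$ri_cytoplasm, optics$wavelength_nm,
                          optics$medium_ri, ang, pol, FALSE))
  }
  stopifnot(inherits(cell, "core_shell_cell"))
  ints <- .lsp_batch_cpp(cell$diameter_um, cell$nc_ratio, cell$ri_nucleus,
                         cell$ri_cytoplasm, optics$wavelength_nm,
                         optics$medium_ri, ang, pol, FALSE)
  lsp(ang, as.numeric(ints[1, ]),
      meta = list(cell = unclass(cell), polarization = optics$polarization))
}

.validate_cell_frame <- function(df) {
  need <- c("diameter_um", "nc_ratio", "ri_nucleus", "ri_cytoplasm")
  if (!all(need %in% names(df)))
    stop("cell data frame needs columns: ", paste(need, collapse = ", "))
  if (any(df$diameter_um <= 0)) stop("diameters must be positive")
  if (any(df$nc_ratio <= 0 | df$nc_ratio > 1))
    stop("nc_ratio must be in (0, 1]")
  invisible(TRUE)
}

#' Idealised detector pattern and its radial average
#'
#' `detector_pattern()` maps an azimuthally symmetric LSP onto a square
#' camera sensor placed behind the cell; `radial_average()` bins the pixels
#' of such an image back onto the angular grid. The pair idealises the
#' camera readout; real instruments add calibration and background steps
#' that are outside this model.
#'
#' @param x An [lsp()] (for `detector_pattern`) or a numeric matrix image
#'   (for `radial_average`).
#' @param det A [detector_config()].
#' @param optics An [optical_config()] giving the target angular grid for
#'   `radial_average`.
#' @return `detector_pattern`: numeric matrix (pixel_count x pixel_count);
#'   `radial_average`: an [lsp()] on the optics grid (angles with no pixel
#'   support are dropped).
#' @export
detector_pattern <- function(x, det) {
  stopifnot(inherits(x, "lsp"), inherits(det, "detector_config"))
  geo <- .detector_angles(det)
  if (max(x$angles) > max(geo) + 1e-9)
    stop("LSP angular range exceeds detector extent")
  img <- approx(x$angles, x$intensities, xout = geo, rule = 1)$y
  img[is.na(img)] <- 0
  matrix(img, det$pixel_count, det$pixel_count)
}

#' @rdname detector_pattern
#' @export
radial_average <- function(x, det, optics) {
  stopifnot(is.matrix(x), inherits(det, "detector_config"),
            inherits(optics, "optical_config"))
  geo <- .detector_angles(det)
  ang <- lsp_angles(optics)
  half <- optics$angle_step / 2
  bin <- findInterval(geo, c(ang - half, ang[length(ang)] + half))
  keep <- bin >= 1 & bin <= length(ang) &
    geo >= ang[1] - half & geo <= ang[length(ang)] + half
  sums <- tapply(as.numeric(x)[keep], bin[keep], mean)
  idx <- as.integer(names(sums))
  lsp(ang[idx], pmax(as.numeric(sums), 0),
      meta = list(source = "radial_average"))
}

.detector_angles <- function(det) {
  half <- (seq_len(det$pixel_count) - (det$pixel_count + 1) / 2) *
    det$pixel_pitch_um
  r <- sqrt(outer(half^2, half^2, "+"))        # um from the optic axis
  atan2(r, det$propagation_distance_mm * 1000) * 180 / pi
}

#' Detector geometry for the idealised camera stage
#'
#' @param pixel_count Pixels per side of the square sensor.
#' @param pixel_pitch_um Pixel pitch, micrometres.
#' @param propagation_distance_mm Cell-to-sensor distance, millimetres.
#' @return Object of class `detector_config`.
#' @export
detector_config <- function(pixel_count = 1200, pixel_pitch_um = 10,
                            propagation_distance_mm = 10) {
  stopifnot(pixel_count > 0, pixel_pitch_um > 0, propagation_distance_mm > 0)
  structure(list(pixel_count = as.integer(pixel_count),
                 pixel_pitch_um = pixel_pitch_um,
                 propagation_distance_mm = propagation_distance_mm),
            class = "detector_config")
}
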