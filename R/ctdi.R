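# ---- validation helpers ----------------------------------------------------

stop_ctdose <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_ctdose(sprintf("'%s' must be a single nonnegative number, got %s",
                        name, deparse(substitute(x))))
  invisible(x)
}

# ---- DoseProfile -----------------------------------------------------------

#' Longitudinal dose profile
#'
#' A sampled single-rotation dose distribution D(z) along the scanner z-axis,
#' as measured e.g. with a translated small-volume chamber or film. Positions
#' are in mm, doses in mGy. By convention z = 0 is the profile isocenter; if
#' the supplied positions are not centered, `center` re-expresses them about
#' the mid-span (no automatic peak-finding is performed).
#'
#' @param z_mm numeric vector of strictly increasing axial positions (mm).
#' @param dose_mGy numeric vector of nonnegative dose readings (mGy), same
#'   length as `z_mm`.
#' @param description free-text label.
#' @param center if `TRUE` (default), shift `z_mm` so that the mid-span of
#'   the supplied range maps to z = 0.
#' @return An object of class `dose_profile`.
#' @examples
#' z <- seq(-150, 150, by = 1)
#' p <- dose_profile(z, rep(1, length(z)), "flat unit profile")
#' @export
dose_profile <- function(z_mm, dose_mGy, description = "", center = TRUE) {
  z_mm <- as.numeric(z_mm); dose_mGy <- as.numeric(dose_mGy)
  if (length(z_mm) < 2L)
    stop_ctdose("a dose profile needs at least 2 samples")
  if (length(z_mm) != length(dose_mGy))
    stop_ctdose("z_mm and dose_mGy must have equal length")
  if (any(diff(z_mm) <= 0))
    stop_ctdose("z_mm must be strictly increasing")
  if (any(!is.finite(dose_mGy)) || any(dose_mGy < 0))
    stop_ctdose("dose_mGy must be finite and nonnegative")
  if (isTRUE(center)) {
    mid <- (z_mm[1L] + z_mm[length(z_mm)]) / 2
    z_mm <- z_mm - mid
  }
  structure(list(z_mm = z_mm, dose_mGy = dose_mGy,
                 description = as.character(description)[1L]),
            class = "dose_profile")
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf("<dose_profile> %s\n  %d samples over [%.1f, %.1f] mm, peak %.3g mGy\n",
              if (nzchar(x$description)) x$description else "(unnamed)",
              length(x$z_mm), min(x$z_mm), max(x$z_mm), max(x$dose_mGy)))
  invisible(x)
}

#' Beam geometry
#'
#' Detector-row count N and nominal slice thickness T (mm). Their product NT
#' is the nominal beam width entering the CTDI100 denominator.
#'
#' @param n_rows integer, number of detector rows (>= 1).
#' @param nominal_slice_mm nominal slice thickness T in mm (> 0).
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(n_rows, nominal_slice_mm) {
  if (!is.numeric(n_rows) || length(n_rows) != 1L || n_rows < 1)
    stop_ctdose("n_rows must be a single number >= 1")
  if (!is.numeric(nominal_slice_mm) || length(nominal_slice_mm) != 1L ||
      nominal_slice_mm <= 0)
    stop_ctdose("nominal_slice_mm must be a single positive number")
  structure(list(n_rows = as.numeric(n_rows),
                 nominal_slice_mm = as.numeric(nominal_slice_mm)),
            class = "beam_geometry")
}

beam_width_mm <- function(geom) geom$n_rows * geom$nominal_slice_mm

# ---- CTDI100 ---------------------------------------------------------------

#' Compute CTDI100 from a dose profile
#'
#' Integrates the longitudinal dose profile D(z) over the central 100 mm
#' (z in [-50, +50] mm) by the trapezoidal rule and divides by min(NT, 100):
#' \deqn{CTDI_{100} = \frac{1}{\min\{NT, 100\}} \int_{-50}^{+50} D(z)\,dz}
#' The clamp reflects wide-cone scanners: once the beam width NT exceeds the
#' 100 mm chamber length the quantity becomes the average dose over the
#' central 100 mm of a single axial exposure rather than the full-beam
#' average. Samples are linearly interpolated at the +/-50 mm boundaries.
#'
#' @param profile a [dose_profile]; must span at least [-50, +50] mm.
#' @param geom a [beam_geometry] giving N and T.
#' @return CTDI100 in mGy (scalar).
#' @examples
#' z <- seq(-150, 150, by = 1)
#' p <- dose_profile(z, rep(1, length(z)))
#' compute_ctdi100(p, beam_geometry(100, 1))   # 1.0
#' compute_ctdi100(p, beam_geometry(32, 0.5))  # 100/16 = 6.25
#' @export
compute_ctdi100 <- function(profile, geom) {
  stopifnot(inherits(profile, "dose_profile"), inherits(geom, "beam_geometry"))
  z <- profile$z_mm; d <- profile$dose_mGy
  lo <- -50; hi <- 50
  if (z[1L] > lo || z[length(z)] < hi)
    stop_ctdose(sprintf(
      "profile spans [%.1f, %.1f] mm but must cover [-50, +50] mm (missing %s)",
      z[1L], z[length(z)],
      paste(c(if (z[1L] > lo) sprintf("[-50, %.1f)", z[1L]),
              if (z[length(z)] < hi) sprintf("(%.1f, 50]", z[length(z)])),
            collapse = " and ")))
  keep <- z > lo & z < hi
  zz <- c(lo, z[keep], hi)
  dd <- c(stats::approx(z, d, xout = lo)$y, d[keep],
          stats::approx(z, d, xout = hi)$y)
  numerator <- pracma::trapz(zz, dd)      # mGy * mm
  nt <- beam_width_mm(geom)
  if (nt <= 0) stop_ctdose("beam width NT must be positive")
  numerator / min(nt, 100)
}

#' Weighted CTDI
#'
#' Standard weighted combination of the center and peripheral CTDI100 of a
#' PMMA phantom: one third center plus two thirds periphery.
#'
#' @param ctdi_c center CTDI100 (mGy, >= 0).
#' @param ctdi_p peripheral CTDI100, mean of the 12/3/6/9 o'clock positions
#'   (mGy, >= 0).
#' @return CTDIw in mGy.
#' @export
compute_ctdiw <- function(ctdi_c, ctdi_p) {
  check_nonneg_scalar(ctdi_c, "ctdi_c")
  check_nonneg_scalar(ctdi_p, "ctdi_p")
  ctdi_c / 3 + 2 * ctdi_p / 3
}

#' Dose-length product
#'
#' DLP = CTDIvol x scan length, the console-reported total-exposure metric.
#' Scan length is supplied in mm and converted to cm internally, giving the
#' conventional mGy.cm unit.
#'
#' @param ctdi_vol volume CTDI in mGy (>= 0).
#' @param scan_length_mm scan length in mm (>= 0).
#' @return DLP in mGy.cm.
#' @export
compute_dlp <- function(ctdi_vol, scan_length_mm) {
  check_nonneg_scalar(ctdi_vol, "ctdi_vol")
  check_nonneg_scalar(scan_length_mm, "scan_length_mm")
  ctdi_vol * scan_length_mm / 10
}

# ---- relative CTDI ---------------------------------------------------------

#' Relative-CTDI table
#'
#' Collimation-dependent CTDI efficiency factors relative to a reference
#' collimation (whose factor is exactly 1.0). Collimations form a discrete
#' scanner menu; lookups are exact, never interpolated.
#'
#' @param collimation_mm strictly increasing nominal beam widths (mm).
#' @param rel_ctdi positive dimensionless factor per width.
#' @param reference_collimation_mm the width whose factor is defined as 1.0.
#' @return An object of class `rel_ctdi_table`.
#' @examples
#' tab <- rel_ctdi_table(c(2, 16, 32, 160), c(1.30, 1.0, 0.97, 0.90), 16)
#' rel_ctdi(tab, 160)
#' @export
rel_ctdi_table <- function(collimation_mm, rel_ctdi,
                           reference_collimation_mm = 16) {
  collimation_mm <- as.numeric(collimation_mm)
  rel_ctdi <- as.numeric(rel_ctdi)
  if (length(collimation_mm) != length(rel_ctdi) || length(collimation_mm) < 1L)
    stop_ctdose("collimation_mm and rel_ctdi must be non-empty, equal length")
  if (any(diff(collimation_mm) <= 0))
    stop_ctdose("collimation_mm must be strictly increasing")
  if (any(rel_ctdi <= 0))
    stop_ctdose("all rel_ctdi factors must be > 0")
  i <- match(reference_collimation_mm, collimation_mm)
  if (is.na(i))
    stop_ctdose("reference_collimation_mm must be one of the listed widths")
  if (rel_ctdi[i] != 1.0)
    stop_ctdose(sprintf(
      "rel_ctdi at the reference collimation (%g mm) must equal 1.0 exactly, got %g",
      reference_collimation_mm, rel_ctdi[i]))
  structure(list(collimation_mm = collimation_mm, rel_ctdi = rel_ctdi,
                 reference_collimation_mm = as.numeric(reference_collimation_mm)),
            class = "rel_ctdi_table")
}

#' Look up a relative-CTDI factor
#'
#' @param table a [rel_ctdi_table].
#' @param collimation_mm a collimation listed in the table (mm).
#' @return The dimensionless factor; exactly 1.0 at the reference width.
#' @export
rel_ctdi <- function(table, collimation_mm) {
  stopifnot(inherits(table, "rel_ctdi_table"))
  i <- match(collimation_mm, table$collimation_mm)
  if (is.na(i))
    stop_ctdose(sprintf(
      "collimation %g mm not in the table; available widths: %s mm",
      collimation_mm, paste(table$collimation_mm, collapse = ", ")))
  table$rel_ctdi[i]
}
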