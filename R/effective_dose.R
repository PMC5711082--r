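# Equivalent and effective dose.
#
# Organ absorbed doses D_T (mGy) are weighted by the radiation weighting
# factor W_R to give equivalent doses H_T (mSv); for photons W_R = 1 and
# the numbers are unchanged. Effective dose is the tissue-weighted sum
# ED = sum_T W_T H_T under a tissue weighting scheme whose weights sum to 1,
# the remainder tissues sharing one weight applied to their arithmetic mean.

#' Radiation weighting factor
#'
#' @param w_r dimensionless factor (> 0); 1.0 for photons, the only value
#'   relevant to CT.
#' @return An object of class `radiation_weighting`.
#' @export
radiation_weighting <- function(w_r = 1.0) {
  if (!is.numeric(w_r) || length(w_r) != 1L || !is.finite(w_r) || w_r <= 0)
    stop_ctdose("w_r must be a single positive number")
  structure(list(w_r = as.numeric(w_r)), class = "radiation_weighting")
}

#' Tissue weighting scheme
#'
#' Named tissue weights plus a single remainder weight shared (as an
#' arithmetic mean) by the listed remainder tissues. The total
#' (named weights + remainder weight, counted once) must equal 1.
#'
#' @param name scheme name.
#' @param weights named numeric vector of per-tissue weights (> 0).
#' @param remainder_weight the shared remainder weight (> 0, or 0 to disable).
#' @param remainder_tissues tissues contributing to the remainder mean.
#' @return An object of class `tissue_weighting_scheme`.
#' @export
tissue_weighting_scheme <- function(name, weights, remainder_weight,
                                    remainder_tissues) {
  weights <- unlist(weights)
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop_ctdose("weights must be a named tissue -> weight vector")
  if (any(weights <= 0)) stop_ctdose("all tissue weights must be > 0")
  if (remainder_weight < 0) stop_ctdose("remainder_weight must be >= 0")
  total <- sum(weights) + remainder_weight
  if (abs(total - 1) > 1e-9)
    stop_ctdose(sprintf(
      "tissue weights must sum to 1 (remainder counted once); got %.12f", total))
  structure(list(name = as.character(name)[1L], weights = weights,
                 remainder_weight = as.numeric(remainder_weight),
                 remainder_tissues = as.character(remainder_tissues)),
            class = "tissue_weighting_scheme")
}

#' The built-in ICRP 103 tissue weighting scheme
#'
#' Loads the packaged transcription of the ICRP Publication 103 weights
#' (gonads 0.08; red bone marrow, colon, lung, stomach, breasts 0.12 each;
#' bladder, oesophagus, liver, thyroid 0.04 each; bone surface, brain,
#' salivary glands, skin 0.01 each; remainder 0.12 over 14 tissues). The
#' sum-to-one invariant is validated at load.
#'
#' @return A [tissue_weighting_scheme].
#' @export
icrp103_scheme <- function() {
  path <- system.file("extdata", "icrp103_weights.json", package = "ctdose",
                      mustWork = TRUE)
  load_scheme_json(path)
}

#' Load a tissue weighting scheme from JSON
#'
#' @param path JSON file with fields `name`, `weights`, `remainder_weight`,
#'   `remainder_tissues`.
#' @return A [tissue_weighting_scheme].
#' @export
load_scheme_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tissue_weighting_scheme(j$name, unlist(j$weights), j$remainder_weight,
                          j$remainder_tissues)
}

# ---- equivalent dose -------------------------------------------------------

#' Equivalent dose from organ absorbed doses
#'
#' H_T = D_T x W_R per organ; with W_R = 1 (photons) the values are
#' numerically unchanged and only the unit is relabelled mGy -> mSv.
#'
#' @param d_t named numeric vector of organ absorbed doses (mGy, >= 0).
#' @param w a [radiation_weighting] (default photons, W_R = 1).
#' @return Named numeric vector of equivalent doses (mSv).
#' @export
equivalent_dose <- function(d_t, w = radiation_weighting(1.0)) {
  stopifnot(inherits(w, "radiation_weighting"))
  d_t <- unlist(d_t)
  if (length(d_t) && (any(!is.finite(d_t)) || any(d_t < 0)))
    stop_ctdose("organ doses must be finite and >= 0")
  d_t * w$w_r
}

#' Map organ doses to weighting-scheme tissues
#'
#' Renames sex-specific gonad organs to the scheme's `gonads` tissue
#' (testes for the male map, ovaries for the female map, dropping the
#' opposite-sex organ if present) and normalizes a few common aliases
#' (breast -> breasts, esophagus -> oesophagus). Other names pass through.
#'
#' @param doses named numeric vector keyed by organ.
#' @param sex `"male"` or `"female"`.
#' @return Named numeric vector keyed by scheme tissue.
#' @export
map_organs_to_tissues <- function(doses, sex = c("male", "female")) {
  sex <- match.arg(sex)
  nm <- names(doses)
  alias <- c(breast = "breasts", esophagus = "oesophagus",
             salivary = "salivary_glands", bone_marrow = "red_bone_marrow")
  hit <- nm %in% names(alias)
  nm[hit] <- alias[nm[hit]]
  gonad <- if (sex == "male") "testes" else "ovaries"
  other <- if (sex == "male") "ovaries" else "testes"
  doses <- doses[!(nm %in% other)]
  nm <- nm[!(nm %in% other)]
  nm[nm == gonad] <- "gonads"
  stats::setNames(as.numeric(doses), nm)
}

# ---- effective dose --------------------------------------------------------

#' Effective dose from equivalent doses
#'
#' ED = sum over named tissues of W_T x H_T, plus the remainder weight
#' times the arithmetic mean of the remainder tissues' H values. Remainder
#' tissues absent from the dose map are excluded from the mean (not counted
#' as zero), with a warning; named scheme tissues absent from the map
#' contribute zero, with a warning.
#'
#' @param h_t named numeric vector of equivalent doses (mSv).
#' @param scheme a [tissue_weighting_scheme].
#' @return An object of class `effective_dose_result`: list with `ed`
#'   (mSv), `h_t`, `scheme`, `sex`.
#' @param sex recorded on the result (`"male"`, `"female"`, `"averaged"`,
#'   or `"unspecified"`).
#' @export
effective_dose <- function(h_t, scheme, sex = "unspecified") {
  stopifnot(inherits(scheme, "tissue_weighting_scheme"))
  h_t <- unlist(h_t)
  named <- names(scheme$weights)
  present <- intersect(named, names(h_t))
  absent <- setdiff(named, present)
  if (length(absent))
    warning("scheme tissues absent from the dose map contribute zero: ",
            paste(absent, collapse = ", "))
  ed <- sum(scheme$weights[present] * h_t[present])
  if (scheme$remainder_weight > 0) {
    rem_present <- intersect(scheme$remainder_tissues, names(h_t))
    rem_absent <- setdiff(scheme$remainder_tissues, rem_present)
    if (length(rem_absent))
      warning("remainder tissues absent from the dose map excluded from the remainder mean: ",
              paste(rem_absent, collapse = ", "))
    if (length(rem_present))
      ed <- ed + scheme$remainder_weight * mean(h_t[rem_present])
  }
  structure(list(ed = ed, h_t = h_t, scheme = scheme$name, sex = sex),
            class = "effective_dose_result")
}

#' @export
print.effective_dose_result <- function(x, ...) {
  cat(sprintf("<effective_dose_result> ED = %.4g mSv (%s, scheme %s)\n",
              x$ed, x$sex, x$scheme))
  invisible(x)
}

#' Sex-averaged effective dose
#'
#' Averages the male and female equivalent-dose maps tissue by tissue over
#' the union of tissues, a tissue present in only one sex contributing its
#' value at half weight (this is how the single-sex gonad doses enter the
#' averaged gonad term), and recomputes ED from the averaged map.
#'
#' @param male,female `effective_dose_result` objects computed under the
#'   same scheme.
#' @param scheme the [tissue_weighting_scheme] both were computed under.
#' @return An `effective_dose_result` with `sex = "averaged"`.
#' @export
sex_averaged_ed <- function(male, female, scheme) {
  stopifnot(inherits(male, "effective_dose_result"),
            inherits(female, "effective_dose_result"),
            inherits(scheme, "tissue_weighting_scheme"))
  if (!identical(male$scheme, female$scheme) ||
      !identical(male$scheme, scheme$name))
    stop_ctdose("male and female results must use the same weighting scheme")
  tissues <- union(names(male$h_t), names(female$h_t))
  get0n <- function(h, t) ifelse(t %in% names(h), h[t], 0)
  avg <- stats::setNames(
    (as.numeric(get0n(male$h_t, tissues)) +
     as.numeric(get0n(female$h_t, tissues))) / 2, tissues)
  suppressWarnings(effective_dose(avg, scheme, sex = "averaged"))
}
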