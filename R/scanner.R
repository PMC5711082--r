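# Scanner characterization and reference-library matching.
#
# New scanners are mapped onto the closest of the reference Monte Carlo
# scanner datasets through "ImPACT factors": fixed linear combinations of
# phantom-to-air CTDI ratios, one for the head (160 mm PMMA) and one for the
# body (320 mm PMMA) phantom. The published regression coefficients are
# hard constants of the method.

IMF_HEAD_C   <- 0.4738
IMF_HEAD_P   <- 0.8045
IMF_HEAD_0   <- 0.0752
IMF_BODY_C   <- 3.5842
IMF_BODY_P   <- 0.6328
IMF_BODY_0   <- -0.0902

#' One kV's CTDI characterization of a scanner
#'
#' All values are mGy per 100 mAs. Head values come from the 160 mm PMMA
#' phantom, body values from the 320 mm phantom, and `ctdi_air` is measured
#' free in air at isocenter (no phantom).
#'
#' @param kv tube voltage (kV).
#' @param ctdi100_c_head,ctdi100_p_head center / peripheral CTDI100 in the
#'   head phantom (mGy per 100 mAs).
#' @param ctdi100_c_body,ctdi100_p_body same for the body phantom.
#' @param ctdi_air free-in-air CTDI (mGy per 100 mAs); must be at least the
#'   attenuated body-center value.
#' @return An object of class `ctdi_measurement_set`.
#' @export
ctdi_measurement_set <- function(kv, ctdi100_c_head, ctdi100_p_head,
                                 ctdi100_c_body, ctdi100_p_body, ctdi_air) {
  vals <- c(kv = kv, ctdi100_c_head = ctdi100_c_head,
            ctdi100_p_head = ctdi100_p_head, ctdi100_c_body = ctdi100_c_body,
            ctdi100_p_body = ctdi100_p_body, ctdi_air = ctdi_air)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_ctdose("all CTDI measurement values must be finite and > 0")
  if (ctdi_air < ctdi100_c_body)
    stop_ctdose(sprintf(
      "ctdi_air (%g) must not be below the body-center CTDI100 (%g): free-in-air dose exceeds the attenuated center",
      ctdi_air, ctdi100_c_body))
  structure(as.list(vals), class = "ctdi_measurement_set")
}

#' Scanner model
#'
#' Bundles a scanner's per-kV CTDI measurement sets with its collimation
#' menu (relative-CTDI table).
#'
#' @param name scanner name.
#' @param measurements list of [ctdi_measurement_set] objects, one per kV
#'   (kV values must be unique).
#' @param rel_ctdi_table a [rel_ctdi_table].
#' @return An object of class `scanner_model`.
#' @export
scanner_model <- function(name, measurements, rel_ctdi_table) {
  if (inherits(measurements, "ctdi_measurement_set"))
    measurements <- list(measurements)
  if (length(measurements) < 1L ||
      !all(vapply(measurements, inherits, TRUE, "ctdi_measurement_set")))
    stop_ctdose("measurements must be a non-empty list of ctdi_measurement_set")
  kvs <- vapply(measurements, `[[`, 0.0, "kv")
  if (anyDuplicated(kvs))
    stop_ctdose("kV values must be unique across measurement sets")
  stopifnot(inherits(rel_ctdi_table, "rel_ctdi_table"))
  structure(list(name = as.character(name)[1L],
                 measurements = measurements[order(kvs)],
                 rel_ctdi_table = rel_ctdi_table),
            class = "scanner_model")
}

#' @export
print.scanner_model <- function(x, ...) {
  kvs <- vapply(x$measurements, `[[`, 0.0, "kv")
  cat(sprintf("<scanner_model> %s\n  kV: %s\n  collimations (mm): %s\n",
              x$name, paste(kvs, collapse = ", "),
              paste(x$rel_ctdi_table$collimation_mm, collapse = ", ")))
  invisible(x)
}

scanner_measurement_at <- function(scanner, kv) {
  kvs <- vapply(scanner$measurements, `[[`, 0.0, "kv")
  i <- match(kv, kvs)
  if (is.na(i))
    stop_ctdose(sprintf("scanner '%s' has no measurements at %g kV (available: %s)",
                        scanner$name, kv, paste(kvs, collapse = ", ")))
  scanner$measurements[[i]]
}

# ---- ImPACT factors --------------------------------------------------------

#' Head ImPACT factor
#'
#' ImF(head) = 0.4738 (c/air) + 0.8045 (p/air) + 0.0752, where c and p are
#' the head-phantom center and peripheral CTDI100 and air is the free-in-air
#' CTDI, all at the same kV and per 100 mAs. Depends only on the two ratios,
#' so any common normalization of the three inputs cancels.
#'
#' @param ctdi_c,ctdi_p head-phantom center/peripheral CTDI100 (mGy, >= 0).
#' @param ctdi_air free-in-air CTDI (mGy, > 0).
#' @return Dimensionless factor.
#' @export
impact_factor_head <- function(ctdi_c, ctdi_p, ctdi_air) {
  if (!is.numeric(ctdi_air) || ctdi_air <= 0)
    stop_ctdose("ctdi_air must be > 0")
  if (ctdi_c < 0 || ctdi_p < 0) stop_ctdose("CTDI inputs must be >= 0")
  IMF_HEAD_C * (ctdi_c / ctdi_air) + IMF_HEAD_P * (ctdi_p / ctdi_air) + IMF_HEAD_0
}

#' Body ImPACT factor
#'
#' ImF(body) = 3.5842 (c/air) + 0.6328 (p/air) - 0.0902 with body-phantom
#' inputs; see [impact_factor_head].
#'
#' @inheritParams impact_factor_head
#' @return Dimensionless factor.
#' @export
impact_factor_body <- function(ctdi_c, ctdi_p, ctdi_air) {
  if (!is.numeric(ctdi_air) || ctdi_air <= 0)
    stop_ctdose("ctdi_air must be > 0")
  if (ctdi_c < 0 || ctdi_p < 0) stop_ctdose("CTDI inputs must be >= 0")
  IMF_BODY_C * (ctdi_c / ctdi_air) + IMF_BODY_P * (ctdi_p / ctdi_air) + IMF_BODY_0
}

#' Characterize a scanner by its ImPACT factors
#'
#' Computes the head and body ImPACT factors at every kV the scanner was
#' measured at.
#'
#' @param model a [scanner_model].
#' @return A data.frame with columns `kv`, `imf_head`, `imf_body`, one row
#'   per measured kV (ascending).
#' @export
characterize_scanner <- function(model) {
  stopifnot(inherits(model, "scanner_model"))
  rows <- lapply(model$measurements, function(m) {
    data.frame(kv = m$kv,
               imf_head = impact_factor_head(m$ctdi100_c_head,
                                             m$ctdi100_p_head, m$ctdi_air),
               imf_body = impact_factor_body(m$ctdi100_c_body,
                                             m$ctdi100_p_body, m$ctdi_air))
  })
  do.call(rbind, rows)
}

# ---- reference library and matching ----------------------------------------

#' Reference scanner library
#'
#' The library of previously characterized scanners with Monte Carlo dose
#' datasets. Each entry carries the scanner's ImPACT factors at one kV and
#' the identifier of its dataset.
#'
#' @param entries data.frame with columns `name`, `kv`, `imf_head`,
#'   `imf_body`, `dataset_id`; (name, kv) pairs must be unique.
#' @return An object of class `reference_library`.
#' @export
reference_library <- function(entries) {
  need <- c("name", "kv", "imf_head", "imf_body", "dataset_id")
  if (!is.data.frame(entries) || nrow(entries) < 1L ||
      !all(need %in% names(entries)))
    stop_ctdose("entries must be a non-empty data.frame with columns ",
                paste(need, collapse = ", "))
  if (anyDuplicated(entries[c("name", "kv")]))
    stop_ctdose("(name, kv) pairs must be unique in the reference library")
  entries <- entries[need]
  entries$name <- as.character(entries$name)
  entries$dataset_id <- as.character(entries$dataset_id)
  structure(list(entries = entries), class = "reference_library")
}

#' Match a scanner to the closest reference dataset
#'
#' Scores every library entry at the requested kV by the sum of relative
#' absolute differences of the head and body ImPACT factors,
#' |dImF_head|/ImF_head + |dImF_body|/ImF_body (denominators from the target
#' scanner), and returns the minimizer. Ties go to the earlier library entry.
#' If the library has no entry at the requested kV the nearest available kV
#' is used, with a warning.
#'
#' @param target data.frame as returned by [characterize_scanner].
#' @param library a [reference_library].
#' @param kv the tube voltage to match at; must be present in `target`.
#' @param all if `TRUE`, return the full ranked table instead of the winner.
#' @return A list with `dataset_id`, `name`, `kv`, `score` (and `ranked`,
#'   the scored table, when `all = TRUE`).
#' @export
match_scanner <- function(target, library, kv, all = FALSE) {
  stopifnot(inherits(library, "reference_library"), is.data.frame(target))
  ti <- match(kv, target$kv)
  if (is.na(ti))
    stop_ctdose(sprintf("target has no ImPACT factors at %g kV (available: %s)",
                        kv, paste(target$kv, collapse = ", ")))
  ent <- library$entries
  if (nrow(ent) == 0L) stop_ctdose("reference library is empty")
  if (!any(ent$kv == kv)) {
    kvs <- sort(unique(ent$kv))
    near <- kvs[which.min(abs(kvs - kv))]
    warning(sprintf("library has no entries at %g kV; using nearest kV %g",
                    kv, near))
    ent <- ent[ent$kv == near, , drop = FALSE]
  } else {
    ent <- ent[ent$kv == kv, , drop = FALSE]
  }
  h0 <- target$imf_head[ti]; b0 <- target$imf_body[ti]
  if (h0 <= 0 || b0 <= 0)
    stop_ctdose("target ImPACT factors must be positive for relative scoring")
  ent$score <- abs(ent$imf_head - h0) / h0 + abs(ent$imf_body - b0) / b0
  best <- which.min(ent$score)   # which.min keeps the first on ties
  out <- list(dataset_id = ent$dataset_id[best], name = ent$name[best],
              kv = ent$kv[best], score = ent$score[best])
  if (isTRUE(all)) out$ranked <- ent[order(ent$score), , drop = FALSE]
  out
}
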