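# End-to-end dose report: stylized-phantom organ doses -> reference
# male/female organ doses via conversion factors -> equivalent doses ->
# effective dose per sex and sex-averaged, with console metrics (CTDIw,
# CTDIvol, DLP) alongside.

#' Run the full dosimetry pipeline
#'
#' Deterministic composition of [organ_dose], [apply_cf] per sex,
#' [equivalent_dose], [effective_dose] and [sex_averaged_ed]. Head-region
#' examination categories (head, neck, head-neck) take their console CTDI
#' metrics from the head-phantom measurements, all others from the body
#' phantom.
#'
#' @param scanner a [scanner_model].
#' @param dataset a [dose_dataset].
#' @param protocol a [scan_protocol].
#' @param cf_male,cf_female [conversion_table]s for the examination
#'   category, one per sex.
#' @param scheme a [tissue_weighting_scheme] (default the built-in ICRP 103
#'   scheme).
#' @param quiet suppress coverage warnings from CF application and tissue
#'   resolution (default TRUE; the warnings are routine when a dataset does
#'   not score every scheme tissue).
#' @return An object of class `dose_report`: list with `mird`, `male`,
#'   `female` organ-dose results, `ed_male`, `ed_female`, `ed_averaged`
#'   effective-dose results, and `console` metrics (ctdiw, ctdi_vol, dlp,
#'   scan_length_mm).
#' @export
full_pipeline <- function(scanner, dataset, protocol, cf_male, cf_female,
                          scheme = icrp103_scheme(), quiet = TRUE) {
  stopifnot(inherits(cf_male, "conversion_table"),
            inherits(cf_female, "conversion_table"))
  if (cf_male$category$sex != "male" || cf_female$category$sex != "female")
    stop_ctdose("cf_male/cf_female must carry sexes male/female")
  maybe_quiet <- if (quiet) suppressWarnings else identity

  mird <- organ_dose(dataset, protocol, scanner)
  male <- maybe_quiet(apply_cf(mird, cf_male))
  female <- maybe_quiet(apply_cf(mird, cf_female))

  h_m <- equivalent_dose(map_organs_to_tissues(male$doses, "male"))
  h_f <- equivalent_dose(map_organs_to_tissues(female$doses, "female"))
  ed_m <- maybe_quiet(effective_dose(h_m, scheme, sex = "male"))
  ed_f <- maybe_quiet(effective_dose(h_f, scheme, sex = "female"))
  ed_avg <- sex_averaged_ed(ed_m, ed_f, scheme)

  meas <- scanner_measurement_at(scanner, protocol$kv)
  region <- cf_male$category$name
  head_like <- region %in% c("head", "neck", "head-neck")
  ctdiw100 <- if (head_like)
    compute_ctdiw(meas$ctdi100_c_head, meas$ctdi100_p_head)
  else
    compute_ctdiw(meas$ctdi100_c_body, meas$ctdi100_p_body)
  mas <- protocol$ma * protocol$rotation_time_s
  rc <- rel_ctdi(scanner$rel_ctdi_table, protocol$collimation_mm)
  p_eff <- if (protocol$mode == "helical") protocol$pitch else 1.0
  ctdiw <- ctdiw100 * (mas / 100) * rc
  ctdi_vol <- ctdiw / p_eff
  scan_len <- protocol$end_mm - protocol$start_mm
  console <- list(ctdiw = ctdiw, ctdi_vol = ctdi_vol,
                  dlp = compute_dlp(ctdi_vol, scan_len),
                  scan_length_mm = scan_len,
                  phantom = if (head_like) "head" else "body")

  structure(list(mird = mird, male = male, female = female,
                 ed_male = ed_m, ed_female = ed_f, ed_averaged = ed_avg,
                 console = console, category = region,
                 scheme = scheme$name),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> category %s, dataset %s\n", x$category,
              x$mird$dataset_id))
  cat(sprintf("  ED male %.4g mSv | female %.4g mSv | averaged %.4g mSv\n",
              x$ed_male$ed, x$ed_female$ed, x$ed_averaged$ed))
  cat(sprintf("  CTDIvol %.4g mGy, DLP %.4g mGy.cm over %g mm\n",
              x$console$ctdi_vol, x$console$dlp, x$console$scan_length_mm))
  invisible(x)
}

#' Organ-dose table of a report
#'
#' @param report a `dose_report`.
#' @return data.frame with columns `organ`, `d_mird`, `d_icrp_male`,
#'   `d_icrp_female`, `h_avg` (mGy / mSv).
#' @export
report_organ_table <- function(report) {
  stopifnot(inherits(report, "dose_report"))
  organs <- names(report$mird$doses)
  pick <- function(v) ifelse(organs %in% names(v), v[organs], NA_real_)
  data.frame(organ = organs,
             d_mird = as.numeric(report$mird$doses),
             d_icrp_male = as.numeric(pick(report$male$doses)),
             d_icrp_female = as.numeric(pick(report$female$doses)),
             h_avg = as.numeric(pick(report$ed_averaged$h_t)))
}

#' Write a dose report
#'
#' Writes the per-organ table as CSV and the summary (effective doses, DLP,
#' protocol echo) as JSON.
#'
#' @param report a `dose_report`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary list.
#' @export
write_dose_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "dose_report"))
  if (!is.null(csv_path))
    utils::write.csv(report_organ_table(report), csv_path, row.names = FALSE)
  p <- report$mird$protocol
  summary <- list(ed_male = report$ed_male$ed, ed_female = report$ed_female$ed,
                  ed_averaged = report$ed_averaged$ed,
                  ctdi_vol = report$console$ctdi_vol, dlp = report$console$dlp,
                  category = report$category, scheme = report$scheme,
                  dataset_id = report$mird$dataset_id,
                  protocol = unclass(p))
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(summary)
}
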