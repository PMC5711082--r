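# Plain-text readers and writers for the pipeline's input formats. All
# files are CSV (with headers) or JSON; units are fixed at mm and mGy per
# 100 mAs as noted per format.

#' Read a dose profile CSV
#'
#' Expects columns `z_mm,dose_mGy` with a header row.
#'
#' @param path CSV file.
#' @param ... passed to [dose_profile] (e.g. `center = FALSE`).
#' @return A [dose_profile].
#' @export
read_dose_profile <- function(path, ...) {
  d <- utils::read.csv(path)
  if (!all(c("z_mm", "dose_mGy") %in% names(d)))
    stop_ctdose("dose profile CSV needs columns z_mm,dose_mGy: ", path)
  dose_profile(d$z_mm, d$dose_mGy, description = basename(path), ...)
}

#' Read a relative-CTDI CSV
#'
#' Expects columns `collimation_mm,rel_ctdi`; the reference row (factor
#' exactly 1.0) identifies the reference collimation. With several rows at
#' 1.0 the reference may be given explicitly.
#'
#' @param path CSV file.
#' @param reference_collimation_mm optional explicit reference width.
#' @return A [rel_ctdi_table].
#' @export
read_rel_ctdi <- function(path, reference_collimation_mm = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("collimation_mm", "rel_ctdi") %in% names(d)))
    stop_ctdose("rel. CTDI CSV needs columns collimation_mm,rel_ctdi: ", path)
  d <- d[order(d$collimation_mm), ]
  if (is.null(reference_collimation_mm)) {
    ref <- d$collimation_mm[d$rel_ctdi == 1.0]
    if (length(ref) < 1L)
      stop_ctdose("no reference row (rel_ctdi == 1.0) in ", path)
    reference_collimation_mm <- ref[1L]
  }
  rel_ctdi_table(d$collimation_mm, d$rel_ctdi, reference_collimation_mm)
}

#' Read a scanner model JSON
#'
#' Expects `{name, measurements: [{kv, head: {c, p}, body: {c, p}, air}]}`
#' (all mGy per 100 mAs) plus either an inline `rel_ctdi:
#' {collimation_mm: [...], rel_ctdi: [...], reference_collimation_mm}` or a
#' `rel_ctdi_csv` path (resolved relative to the JSON file).
#'
#' @param path JSON file.
#' @return A [scanner_model].
#' @export
read_scanner_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  meas <- lapply(j$measurements, function(m)
    ctdi_measurement_set(m$kv, m$head$c, m$head$p, m$body$c, m$body$p, m$air))
  if (!is.null(j$rel_ctdi)) {
    rt <- rel_ctdi_table(unlist(j$rel_ctdi$collimation_mm),
                         unlist(j$rel_ctdi$rel_ctdi),
                         j$rel_ctdi$reference_collimation_mm)
  } else if (!is.null(j$rel_ctdi_csv)) {
    rt <- read_rel_ctdi(file.path(dirname(path), j$rel_ctdi_csv))
  } else stop_ctdose("scanner JSON needs rel_ctdi or rel_ctdi_csv: ", path)
  scanner_model(j$name, meas, rt)
}

#' Read a reference-library CSV
#'
#' Expects columns `name,kv,imf_head,imf_body,dataset_id`.
#'
#' @param path CSV file.
#' @return A [reference_library].
#' @export
read_reference_library <- function(path) {
  reference_library(utils::read.csv(path))
}

#' Read conversion-factor tables from CSV
#'
#' Expects columns `category,sex,organ,cf`; category names must be among
#' the 13 examination categories, sex one of male/female/none. Returns the
#' table for one requested (category, sex) pair.
#'
#' @param path CSV file.
#' @param category,sex the pair to extract.
#' @return A [conversion_table].
#' @export
read_cf_table <- function(path, category, sex) {
  d <- utils::read.csv(path)
  need <- c("category", "sex", "organ", "cf")
  if (!all(need %in% names(d)))
    stop_ctdose("CF CSV needs columns ", paste(need, collapse = ","), ": ", path)
  bad <- setdiff(unique(tolower(d$category)), EXAM_CATEGORIES)
  if (length(bad))
    stop_ctdose("unknown categories in ", path, ": ",
                paste(bad, collapse = ", "))
  cat_obj <- select_category(category, sex)
  sel <- d[tolower(d$category) == cat_obj$name & tolower(d$sex) == cat_obj$sex, ]
  if (!nrow(sel))
    stop_ctdose(sprintf("no rows for category '%s' sex '%s' in %s",
                        cat_obj$name, cat_obj$sex, path))
  conversion_table(cat_obj, stats::setNames(sel$cf, sel$organ))
}

#' Read a per-slab dose dataset
#'
#' Long-form CSV `organ,slab_index,coefficient` (slab indices 0-based;
#' omitted cells are zero) plus a JSON sidecar
#' `{dataset_id, kv, n_slabs, slab_thickness_mm}`.
#'
#' @param csv_path long-form coefficient CSV.
#' @param json_path sidecar; defaults to the CSV path with extension
#'   `.json`.
#' @return A [dose_dataset].
#' @export
read_dose_dataset <- function(csv_path,
                              json_path = sub("\\.csv$", ".json", csv_path)) {
  d <- utils::read.csv(csv_path)
  need <- c("organ", "slab_index", "coefficient")
  if (!all(need %in% names(d)))
    stop_ctdose("dataset CSV needs columns ", paste(need, collapse = ","))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  organs <- unique(d$organ)
  ph <- slab_phantom(meta$n_slabs, meta$slab_thickness_mm, organs)
  co <- matrix(0, length(organs), meta$n_slabs,
               dimnames = list(organs, NULL))
  if (any(d$slab_index < 0 | d$slab_index >= meta$n_slabs))
    stop_ctdose("slab_index out of range [0, n_slabs)")
  co[cbind(match(d$organ, organs), d$slab_index + 1L)] <- d$coefficient
  dose_dataset(ph, co, meta$kv, meta$dataset_id)
}

#' Write a per-slab dose dataset
#'
#' Inverse of [read_dose_dataset]: writes nonzero coefficients in long form
#' plus the JSON sidecar.
#'
#' @param dataset a [dose_dataset].
#' @param csv_path,json_path output paths.
#' @return Invisibly, `csv_path`.
#' @export
write_dose_dataset <- function(dataset, csv_path,
                               json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(dataset, "dose_dataset"))
  nz <- which(dataset$coeff != 0, arr.ind = TRUE)
  out <- data.frame(organ = rownames(dataset$coeff)[nz[, 1L]],
                    slab_index = nz[, 2L] - 1L,
                    coefficient = dataset$coeff[nz])
  out <- out[order(out$organ, out$slab_index), ]
  utils::write.csv(out, csv_path, row.names = FALSE)
  jsonlite::write_json(list(dataset_id = dataset$dataset_id, kv = dataset$kv,
                            n_slabs = dataset$phantom$n_slabs,
                            slab_thickness_mm = dataset$phantom$slab_thickness_mm),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
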