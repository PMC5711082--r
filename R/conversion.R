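# Phantom conversion factors.
#
# The stylized slab phantom is a partially hermaphrodite "reference man":
# it carries testes, ovaries and uterus but no female breasts. Voxel
# reference male/female phantoms differ organ by organ, so per-organ
# conversion factors CF = D(voxel phantom) / D(stylized phantom), keyed by
# examination category and sex, translate stylized-phantom organ doses into
# reference male/female organ doses.

#' The 13 examination-category names
#' @export
EXAM_CATEGORIES <- c(
  "chest-abdomen-pelvis", "chest", "abdomen-pelvis", "abdomen", "pelvis",
  "adrenals", "liver", "kidneys", "liver-kidneys", "kidneys-bladder",
  "head", "neck", "head-neck")

#' Resolve an examination category
#'
#' Normalizes a free-text category name (case-insensitive; spaces,
#' underscores and hyphens interchangeable) to one of the 13 canonical
#' examination categories and pairs it with a sex.
#'
#' @param name category name, e.g. `"Chest-Abdomen-Pelvis"` or `"head"`.
#' @param sex `"male"`, `"female"`, or `"none"` for stylized-phantom
#'   passthrough (identity conversion).
#' @return An object of class `exam_category` (list with `name`, `sex`).
#' @export
select_category <- function(name, sex = c("male", "female", "none")) {
  sex <- match.arg(sex)
  canon <- gsub("[ _]+", "-", tolower(trimws(name)))
  i <- match(canon, EXAM_CATEGORIES)
  if (is.na(i))
    stop_ctdose(sprintf("unknown examination category '%s'; valid names: %s",
                        name, paste(EXAM_CATEGORIES, collapse = ", ")))
  structure(list(name = EXAM_CATEGORIES[i], sex = sex),
            class = "exam_category")
}

#' Conversion-factor table
#'
#' Per-organ factors for one examination category and sex. All factors must
#' be positive; an all-ones table is the identity (stylized-phantom
#' passthrough).
#'
#' @param category an [select_category] result (or a category name, resolved
#'   with the given `sex`).
#' @param cf named numeric vector, organ -> factor (> 0).
#' @param sex used when `category` is given as a name.
#' @return An object of class `conversion_table`.
#' @export
conversion_table <- function(category, cf, sex = "none") {
  if (!inherits(category, "exam_category"))
    category <- select_category(category, sex)
  cf <- unlist(cf)
  if (is.null(names(cf)) || any(!nzchar(names(cf))))
    stop_ctdose("cf must be a named organ -> factor vector")
  if (any(!is.finite(cf)) || any(cf <= 0))
    stop_ctdose("all conversion factors must be finite and > 0")
  structure(list(category = category, cf = cf), class = "conversion_table")
}

#' Identity conversion table
#'
#' All factors equal to 1 over the given organ vocabulary: applying it
#' relabels the phantom without changing any dose.
#'
#' @param organs organ names.
#' @param category,sex examination category for the table.
#' @return A [conversion_table].
#' @export
identity_cf_table <- function(organs, category = "head", sex = "none") {
  conversion_table(select_category(category, sex),
                   stats::setNames(rep(1.0, length(organs)), organs))
}

#' Derive conversion factors from paired organ-dose maps
#'
#' CF = D(reference phantom) / D(stylized phantom), organ by organ over the
#' shared organ set. Organs present in only one map are omitted with a
#' warning; a zero stylized-phantom dose for a shared organ is an error
#' (the ratio is undefined).
#'
#' @param icrp_doses named numeric vector of reference-phantom organ doses
#'   (mGy).
#' @param mird_doses named numeric vector of stylized-phantom organ doses
#'   (mGy), strictly positive on the shared organs.
#' @param category,sex examination category for the resulting table.
#' @return A [conversion_table].
#' @export
derive_cf <- function(icrp_doses, mird_doses, category = "head", sex = "none") {
  shared <- intersect(names(icrp_doses), names(mird_doses))
  extra <- setdiff(union(names(icrp_doses), names(mird_doses)), shared)
  if (length(extra))
    warning("organs present in only one dose map omitted from the CF table: ",
            paste(extra, collapse = ", "))
  if (!length(shared)) stop_ctdose("the dose maps share no organs")
  zero <- shared[mird_doses[shared] == 0]
  if (length(zero))
    stop_ctdose("stylized-phantom dose is zero for ",
                paste(zero, collapse = ", "),
                "; the conversion ratio is undefined")
  conversion_table(select_category(category, sex),
                   icrp_doses[shared] / mird_doses[shared])
}

#' Apply conversion factors to an organ-dose result
#'
#' Multiplies each organ dose by its factor, relabelling the result as the
#' reference male/female phantom (or leaving the stylized label when the
#' table's sex is `"none"`). Organs without a factor are dropped with a
#' warning rather than passed through, since their reference-phantom dose is
#' undefined for that category.
#'
#' @param mird_result an `organ_dose_result` from [organ_dose].
#' @param table a [conversion_table].
#' @return An `organ_dose_result` with converted doses and updated
#'   `phantom_label` / `sex`.
#' @export
apply_cf <- function(mird_result, table) {
  stopifnot(inherits(mird_result, "organ_dose_result"),
            inherits(table, "conversion_table"))
  d <- mird_result$doses
  covered <- intersect(names(d), names(table$cf))
  missing <- setdiff(names(d), covered)
  if (length(missing))
    warning("organs without a conversion factor dropped from the converted result: ",
            paste(missing, collapse = ", "))
  out <- d[covered] * table$cf[covered]
  label <- switch(table$category$sex,
                  male = "ICRP110-male", female = "ICRP110-female",
                  none = mird_result$phantom_label)
  structure(list(doses = out, protocol = mird_result$protocol,
                 dataset_id = mird_result$dataset_id,
                 phantom_label = label, sex = table$category$sex,
                 category = table$category$name),
            class = "organ_dose_result")
}
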