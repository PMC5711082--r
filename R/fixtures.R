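# Synthetic fixture generators.
#
# Real per-slab Monte Carlo dose datasets and published conversion-factor
# tables are third-party data and are not redistributable, so every input
# the pipeline needs can be generated synthetically with known ground
# truth: dose profiles with closed-form integrals, slab datasets with
# independently computed organ-dose manifests, conversion-factor tables,
# scanner models and reference libraries with a planted best match. All
# generators are pure functions of (seed, spec); manifests are computed by
# straight-line loops that never call the dose engine, so they are true
# oracles.

#' Default fixture organ vocabulary
#'
#' Organs and tissues spanning the main weighted tissues plus the remainder
#' list, including the sex-specific gonad organs, so effective-dose paths
#' are exercised on realistic maps.
#' @export
FIXTURE_ORGANS <- c(
  "brain", "salivary_glands", "thyroid", "oesophagus", "lung", "breasts",
  "stomach", "liver", "colon", "bladder", "skin", "bone_surface",
  "red_bone_marrow", "testes", "ovaries", "uterus", "adrenals", "kidneys",
  "pancreas", "spleen", "small_intestine", "heart", "thymus",
  "gall_bladder", "muscle")

#' Fixture specification
#'
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical.
#' @param n_organs number of organs drawn from [FIXTURE_ORGANS].
#' @param n_slabs,slab_thickness_mm phantom grid (defaults 208 x 5 mm).
#' @param profile_family dose-profile shape family.
#' @param kv_list tube voltages the fixture scanner is characterized at.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_organs = length(FIXTURE_ORGANS),
                         n_slabs = 208L, slab_thickness_mm = 5,
                         profile_family = c("gaussian", "box", "mixture"),
                         kv_list = c(80, 100, 120, 135)) {
  profile_family <- match.arg(profile_family)
  if (n_organs < 1L || n_slabs < 1L) stop_ctdose("counts must be >= 1")
  if (n_organs > length(FIXTURE_ORGANS))
    stop_ctdose("n_organs must be <= ", length(FIXTURE_ORGANS))
  structure(list(seed = as.integer(seed), n_organs = as.integer(n_organs),
                 n_slabs = as.integer(n_slabs),
                 slab_thickness_mm = as.numeric(slab_thickness_mm),
                 profile_family = profile_family,
                 kv_list = as.numeric(kv_list)),
            class = "fixture_spec")
}

# ---- dose profiles ---------------------------------------------------------

#' Generate a dose profile with a closed-form integral
#'
#' Samples the chosen profile family at 1 mm spacing over [-150, 150] mm
#' and records the analytic integral of the underlying function over
#' [-50, +50] mm, so the trapezoidal CTDI100 can be checked against
#' `analytic_integral / min(NT, 100)`. Families: `gaussian`
#' (A exp(-z^2/2s^2)), `box` (height A over [-W/2, W/2], piecewise-linear
#' at the 1 mm grid), `mixture` (narrow primary + broad scatter Gaussian).
#'
#' @param spec a [fixture_spec] (its seed draws the family parameters when
#'   they are not supplied).
#' @param amplitude,sigma_mm,width_mm optional explicit parameters.
#' @return List of class `profile_fixture`: `profile` (a [dose_profile]),
#'   `analytic_integral` (mGy.mm over [-50, 50]), `params`, and
#'   `analytic_ctdi100(nt)` via [analytic_ctdi100].
#' @export
make_dose_profile <- function(spec, amplitude = NULL, sigma_mm = NULL,
                              width_mm = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    fam <- spec$profile_family
    A <- if (is.null(amplitude)) stats::runif(1, 5, 30) else amplitude
    z <- seq(-150, 150, by = 1)
    if (fam == "gaussian") {
      s <- if (is.null(sigma_mm)) stats::runif(1, 10, 60) else sigma_mm
      d <- A * exp(-z^2 / (2 * s^2))
      integ <- A * s * sqrt(2 * pi) * (stats::pnorm(50 / s) - stats::pnorm(-50 / s))
      params <- list(family = fam, amplitude = A, sigma_mm = s)
    } else if (fam == "box") {
      W <- if (is.null(width_mm)) 2 * sample(10:70, 1) else width_mm
      d <- ifelse(abs(z) <= W / 2, A, 0)
      # integral of the piecewise-linear interpolant over [-50, 50]:
      # flat top plus two 1 mm half-ramps where the edges fall inside
      integ <- if (W >= 100) 100 * A else A * W + A
      params <- list(family = fam, amplitude = A, width_mm = W)
    } else { # mixture: primary peak + broad scatter tail
      s1 <- if (is.null(sigma_mm)) stats::runif(1, 5, 15) else sigma_mm
      s2 <- stats::runif(1, 60, 120)
      A2 <- A * stats::runif(1, 0.05, 0.2)
      d <- A * exp(-z^2 / (2 * s1^2)) + A2 * exp(-z^2 / (2 * s2^2))
      gint <- function(a, s)
        a * s * sqrt(2 * pi) * (stats::pnorm(50 / s) - stats::pnorm(-50 / s))
      integ <- gint(A, s1) + gint(A2, s2)
      params <- list(family = fam, amplitude = A, sigma_mm = s1,
                     scatter_amplitude = A2, scatter_sigma_mm = s2)
    }
    structure(list(profile = dose_profile(z, d, paste0("synthetic ", fam),
                                          center = FALSE),
                   analytic_integral = integ, params = params,
                   seed = spec$seed),
              class = "profile_fixture")
  })
}

#' Closed-form CTDI100 of a profile fixture
#'
#' @param fixture a `profile_fixture`.
#' @param nt beam width NT in mm.
#' @return `analytic_integral / min(nt, 100)` in mGy.
#' @export
analytic_ctdi100 <- function(fixture, nt) {
  stopifnot(inherits(fixture, "profile_fixture"), nt > 0)
  fixture$analytic_integral / min(nt, 100)
}

# ---- scanner ---------------------------------------------------------------

#' Generate a synthetic scanner model
#'
#' Plausible per-kV CTDI measurement sets (free-in-air above body-center by
#' construction, doses rising roughly with kV^2) and a collimation menu
#' {2, 16, 32, 160} mm with wider beams slightly more efficient, the 16 mm
#' factor pinned at 1.0.
#'
#' @param spec a [fixture_spec].
#' @param name scanner name.
#' @return A [scanner_model].
#' @export
make_scanner <- function(spec, name = "synthetic-320") {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed + 1L, {
    meas <- lapply(spec$kv_list, function(kv) {
      base <- 20 * (kv / 120)^2 * stats::runif(1, 0.9, 1.1)  # air, mGy/100mAs
      hc <- base * stats::runif(1, 0.75, 0.9)
      hp <- base * stats::runif(1, 0.8, 0.95)
      bc <- base * stats::runif(1, 0.25, 0.4)
      bp <- base * stats::runif(1, 0.5, 0.65)
      ctdi_measurement_set(kv, hc, hp, bc, bp, base)
    })
    cols <- c(2, 16, 32, 160)
    rc <- c(stats::runif(1, 1.1, 1.4), 1.0, stats::runif(1, 0.92, 0.99),
            stats::runif(1, 0.85, 0.95))
    scanner_model(name, meas, rel_ctdi_table(cols, rc, 16))
  })
}

# ---- dose datasets ---------------------------------------------------------

#' Generate a synthetic per-slab dose dataset with an oracle manifest
#'
#' Each organ gets a Gaussian longitudinal coefficient profile centered at
#' a distinct slab with finite support (truncated at 3 sigma), emulating
#' localized organ response to single-slab irradiation. The manifest lists
#' exact organ doses for a catalogue of protocols, computed by an
#' independent straight-line loop (explicit per-slab overlap and summation,
#' no call into the dose engine).
#'
#' @param spec a [fixture_spec].
#' @param scanner the [scanner_model] the manifest protocols assume
#'   (default `make_scanner(spec)`).
#' @param kv dataset tube voltage (default 120).
#' @return List of class `dataset_fixture`: `dataset` (a [dose_dataset]),
#'   `scanner`, and `manifest` (list of `(protocol, expected)` pairs with
#'   `expected` a named organ-dose vector in mGy).
#' @export
make_dose_dataset <- function(spec, scanner = make_scanner(spec), kv = 120) {
  stopifnot(inherits(spec, "fixture_spec"))
  organs <- FIXTURE_ORGANS[seq_len(spec$n_organs)]
  n <- spec$n_slabs
  t <- spec$slab_thickness_mm
  withr::with_seed(spec$seed + 2L, {
    centers <- sort(sample(seq_len(n), spec$n_organs, replace = FALSE))
    co <- matrix(0, spec$n_organs, n, dimnames = list(organs, NULL))
    for (i in seq_len(spec$n_organs)) {
      s <- stats::runif(1, 2, 12)           # profile width in slabs
      amp <- stats::runif(1, 0.2, 1.5)      # peak coefficient
      js <- seq_len(n)
      prof <- amp * exp(-(js - centers[i])^2 / (2 * s^2))
      prof[abs(js - centers[i]) > 3 * s] <- 0   # finite support
      co[i, ] <- prof
    }
    ph <- slab_phantom(n, t, organs)
    ds <- dose_dataset(ph, co, kv, sprintf("synthetic-ds-%d", spec$seed))

    extent <- n * t
    protos <- list(
      scan_protocol(kv, 200, 0.5, 32, pitch = 1.0,
                    start_mm = 0, end_mm = extent, mode = "helical"),
      scan_protocol(kv, 200, 0.5, 32, pitch = 2.0,
                    start_mm = round(extent * 0.25), end_mm = round(extent * 0.6),
                    mode = "helical"),
      scan_protocol(kv, 100, 1.0, 32, pitch = 1.0,
                    start_mm = 0, end_mm = 160, mode = "axial_contiguous"),
      scan_protocol(kv, 200, 0.5, 160, pitch = 1.0,
                    start_mm = 40, end_mm = 200, mode = "volume_axial"))

    manifest <- lapply(protos, function(p)
      list(protocol = p,
           expected = manifest_organ_dose(co, p, scanner, t)))
    structure(list(dataset = ds, scanner = scanner, manifest = manifest,
                   seed = spec$seed),
              class = "dataset_fixture")
  })
}

# Straight-line oracle: per-slab overlap and summation written out long-hand.
manifest_organ_dose <- function(co, p, scanner, thick) {
  kvs <- vapply(scanner$measurements, `[[`, 0.0, "kv")
  m <- scanner$measurements[[which(kvs == p$kv)]]
  i <- which(scanner$rel_ctdi_table$collimation_mm == p$collimation_mm)
  rc <- scanner$rel_ctdi_table$rel_ctdi[i]
  if (p$mode == "volume_axial") {
    mid <- (p$start_mm + p$end_mm) / 2
    a <- mid - p$collimation_mm / 2; b <- mid + p$collimation_mm / 2
  } else {
    a <- p$start_mm; b <- p$end_mm
  }
  pit <- if (p$mode == "helical") p$pitch else 1.0
  out <- numeric(nrow(co)); names(out) <- rownames(co)
  for (o in seq_len(nrow(co))) {
    acc <- 0
    for (s in seq_len(ncol(co))) {
      lo <- (s - 1) * thick; hi <- s * thick
      ov <- min(hi, b) - max(lo, a)
      if (ov > 0) acc <- acc + co[o, s] * (ov / thick)
    }
    out[o] <- m$ctdi_air * (p$ma * p$rotation_time_s / 100) * rc * acc / pit
  }
  out
}

# ---- conversion-factor tables ----------------------------------------------

#' Generate conversion-factor tables for all 13 categories
#'
#' Factors drawn uniformly in [0.3, 2.0] per organ, category and sex. Male
#' tables omit ovaries and uterus, female tables omit testes; female tables
#' carry a breasts factor (the stylized phantom has no female breasts — the
#' factor encodes that correction). Identity tables over the full organ
#' list are included for passthrough tests.
#'
#' @param spec a [fixture_spec].
#' @param organs organ vocabulary (default the first `n_organs` of
#'   [FIXTURE_ORGANS]).
#' @return List of class `cf_fixture` with `male`, `female` (each a named
#'   list of [conversion_table] per category), `identity_male`,
#'   `identity_female`.
#' @export
make_cf_tables <- function(spec, organs = FIXTURE_ORGANS[seq_len(spec$n_organs)]) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed + 3L, {
    male_organs <- setdiff(organs, c("ovaries", "uterus"))
    female_organs <- setdiff(organs, "testes")
    draw <- function(orgs, cat, sex)
      conversion_table(select_category(cat, sex),
                       stats::setNames(stats::runif(length(orgs), 0.3, 2.0),
                                       orgs))
    male <- lapply(EXAM_CATEGORIES, draw, orgs = male_organs, sex = "male")
    female <- lapply(EXAM_CATEGORIES, draw, orgs = female_organs,
                     sex = "female")
    names(male) <- names(female) <- EXAM_CATEGORIES
    structure(list(
      male = male, female = female,
      identity_male = conversion_table(
        select_category("head", "male"),
        stats::setNames(rep(1.0, length(male_organs)), male_organs)),
      identity_female = conversion_table(
        select_category("head", "female"),
        stats::setNames(rep(1.0, length(female_organs)), female_organs)),
      seed = spec$seed), class = "cf_fixture")
  })
}

# ---- reference library -----------------------------------------------------

#' Generate a reference library with a planted best match
#'
#' Builds a library whose entries carry ImPACT factors at the target
#' scanner's kVs: one planted entry per kV within 0.5% of the target's
#' factors (match score at most 0.01) and decoys perturbed by at least 6%
#' on each factor (score at least 0.12), so the planted entry wins by
#' construction.
#'
#' @param spec a [fixture_spec].
#' @param target data.frame from [characterize_scanner] for the scanner the
#'   library should contain a near-twin of.
#' @param n_entries library size, including the planted entry (>= 1).
#' @return List of class `library_fixture`: `library` (a
#'   [reference_library]) and `planted` (dataset_id of the planted entry).
#' @export
make_reference_library <- function(spec, target, n_entries = 15L) {
  stopifnot(inherits(spec, "fixture_spec"), is.data.frame(target),
            n_entries >= 1L)
  withr::with_seed(spec$seed + 4L, {
    planted_id <- sprintf("planted-%d", spec$seed)
    rows <- list()
    for (k in seq_len(nrow(target))) {
      h0 <- target$imf_head[k]; b0 <- target$imf_body[k]
      rows[[length(rows) + 1L]] <- data.frame(
        name = "planted-twin", kv = target$kv[k],
        imf_head = h0 * stats::runif(1, 0.995, 1.005),
        imf_body = b0 * stats::runif(1, 0.995, 1.005),
        dataset_id = planted_id)
      for (j in seq_len(max(0L, n_entries - 1L))) {
        pert <- function() {
          mag <- stats::runif(1, 0.06, 0.40)
          1 + sample(c(-1, 1), 1) * mag
        }
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("decoy-%d-%d", k, j), kv = target$kv[k],
          imf_head = h0 * pert(), imf_body = b0 * pert(),
          dataset_id = sprintf("decoy-%d-%d", k, j))
      }
    }
    structure(list(library = reference_library(do.call(rbind, rows)),
                   planted = planted_id, seed = spec$seed),
              class = "library_fixture")
  })
}

# ---- bundle ----------------------------------------------------------------

#' Write a complete self-consistent fixture bundle
#'
#' Emits scanner JSON, dataset CSV + sidecar, conversion-factor CSV,
#' reference-library CSV, the tissue weighting scheme JSON, and a manifest
#' JSON of oracle organ doses, all generated from one seed.
#'
#' @param spec a [fixture_spec].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_fixture_bundle <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scanner <- make_scanner(spec)
  fx <- make_dose_dataset(spec, scanner)
  cf <- make_cf_tables(spec)
  lib <- make_reference_library(spec, characterize_scanner(scanner))

  paths <- list(
    scanner = file.path(dir, "scanner.json"),
    dataset_csv = file.path(dir, "dataset.csv"),
    dataset_json = file.path(dir, "dataset.json"),
    cf_csv = file.path(dir, "cf_tables.csv"),
    library_csv = file.path(dir, "library.csv"),
    scheme_json = file.path(dir, "scheme.json"),
    manifest_json = file.path(dir, "manifest.json"))

  rt <- scanner$rel_ctdi_table
  jsonlite::write_json(list(
    name = scanner$name, seed = spec$seed,
    rel_ctdi = list(collimation_mm = rt$collimation_mm,
                    rel_ctdi = rt$rel_ctdi,
                    reference_collimation_mm = rt$reference_collimation_mm),
    measurements = lapply(scanner$measurements, function(m)
      list(kv = m$kv, head = list(c = m$ctdi100_c_head, p = m$ctdi100_p_head),
           body = list(c = m$ctdi100_c_body, p = m$ctdi100_p_body),
           air = m$ctdi_air))),
    paths$scanner, auto_unbox = TRUE, digits = NA)

  write_dose_dataset(fx$dataset, paths$dataset_csv, paths$dataset_json)

  cf_rows <- do.call(rbind, lapply(c("male", "female"), function(sx)
    do.call(rbind, lapply(EXAM_CATEGORIES, function(cat) {
      tab <- cf[[sx]][[cat]]
      data.frame(category = cat, sex = sx, organ = names(tab$cf),
                 cf = as.numeric(tab$cf))
    }))))
  utils::write.csv(cf_rows, paths$cf_csv, row.names = FALSE)

  utils::write.csv(lib$library$entries, paths$library_csv, row.names = FALSE)

  file.copy(system.file("extdata", "icrp103_weights.json", package = "ctdose",
                        mustWork = TRUE), paths$scheme_json, overwrite = TRUE)

  jsonlite::write_json(list(
    seed = spec$seed, planted_library_entry = lib$planted,
    cases = lapply(fx$manifest, function(m)
      list(protocol = unclass(m$protocol),
           expected_mGy = as.list(m$expected)))),
    paths$manifest_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(paths)
}
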