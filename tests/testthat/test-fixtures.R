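test_that("generators are pure functions of the seed", {
  sp <- fixture_spec(7, n_organs = 10)
  a <- make_dose_dataset(sp); b <- make_dose_dataset(sp)
  expect_identical(a$dataset$coeff, b$dataset$coeff)
  expect_identical(a$manifest[[1]]$expected, b$manifest[[1]]$expected)
  pa <- make_dose_profile(sp); pb <- make_dose_profile(sp)
  expect_identical(pa$profile$dose_mGy, pb$profile$dose_mGy)
  expect_identical(pa$analytic_integral, pb$analytic_integral)
  # a different seed changes the draw
  expect_false(identical(a$dataset$coeff,
                         make_dose_dataset(fixture_spec(8, n_organs = 10))$dataset$coeff))
})

test_that("profile fixtures carry a faithful closed-form integral", {
  # box of width 100, height 1: average over the central 100 mm is 1
  bx <- make_dose_profile(fixture_spec(1, profile_family = "box"),
                          amplitude = 1, width_mm = 100)
  expect_equal(analytic_ctdi100(bx, 100), 1.0)
  expect_equal(compute_ctdi100(bx$profile, beam_geometry(100, 1)), 1.0)

  for (seed in 1:10) {
    g <- make_dose_profile(fixture_spec(seed, profile_family = "gaussian"))
    A <- g$params$amplitude; s <- g$params$sigma_mm
    expect_equal(g$analytic_integral,
                 A * s * sqrt(2 * pi) * (pnorm(50 / s) - pnorm(-50 / s)))
    for (nt in c(16, 40, 100, 160))
      expect_equal(compute_ctdi100(g$profile, beam_geometry(nt, 1)),
                   analytic_ctdi100(g, nt), tolerance = 1e-3)
    m <- make_dose_profile(fixture_spec(seed, profile_family = "mixture"))
    expect_equal(compute_ctdi100(m$profile, beam_geometry(32, 1)),
                 analytic_ctdi100(m, 32), tolerance = 1e-3)
  }
})

test_that("dataset fixtures have localized nonnegative profiles and exact manifests", {
  sp <- fixture_spec(9, n_organs = 12)
  fx <- make_dose_dataset(sp)
  co <- fx$dataset$coeff
  expect_true(all(co >= 0))
  expect_equal(dim(co), c(12L, 208L))
  # finite support: each organ's profile occupies a contiguous minority of slabs
  support <- rowSums(co > 0)
  expect_true(all(support >= 1 & support < 208))
  # manifest doses reproduce under the engine for every catalogued protocol
  for (case in fx$manifest) {
    got <- organ_dose(fx$dataset, case$protocol, fx$scanner)$doses
    expect_equal(got, case$expected, tolerance = 1e-10)
  }
  # whole-range unit-scale protocol recovers row sums
  sc1 <- tiny_scanner(air120 = 1, rel32 = 1)
  p <- scan_protocol(120, 200, 0.5, 32, 1, 0, 208 * 5, "helical")
  expect_equal(unname(organ_dose(fx$dataset, p, sc1)$doses),
               unname(rowSums(co)), tolerance = 1e-10)
})

test_that("conversion-factor fixtures respect sex anatomy and the 13-category vocabulary", {
  sp <- fixture_spec(10, n_organs = length(FIXTURE_ORGANS))
  cf <- make_cf_tables(sp)
  expect_identical(names(cf$male), EXAM_CATEGORIES)
  expect_identical(names(cf$female), EXAM_CATEGORIES)
  for (cat in EXAM_CATEGORIES) {
    m <- cf$male[[cat]]$cf; f <- cf$female[[cat]]$cf
    expect_true(all(m >= 0.3 & m <= 2.0))
    expect_false(any(c("ovaries", "uterus") %in% names(m)))
    expect_false("testes" %in% names(f))
    expect_true("breasts" %in% names(f))
  }
  expect_true(all(cf$identity_male$cf == 1))
})

test_that("reference-library fixtures plant a recoverable best match", {
  for (seed in 1:20) {
    sp <- fixture_spec(seed)
    sc <- make_scanner(sp)
    fac <- characterize_scanner(sc)
    lib <- make_reference_library(sp, fac, n_entries = sample(10:30, 1))
    for (kv in fac$kv) {
      got <- match_scanner(fac, lib$library, kv)
      expect_identical(got$dataset_id, lib$planted)
      expect_lt(got$score, 0.011)
    }
    # shuffling entries leaves the winner unchanged
    ent <- lib$library$entries
    shuf <- reference_library(ent[sample(nrow(ent)), ])
    expect_identical(match_scanner(fac, shuf, 120)$dataset_id, lib$planted)
  }
})

test_that("fixture bundles round-trip through the file readers", {
  sp <- fixture_spec(33, n_organs = 10)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(sp, dir)
  expect_true(all(file.exists(unlist(paths))))

  sc <- read_scanner_json(paths$scanner)
  sc0 <- make_scanner(sp)
  expect_equal(characterize_scanner(sc), characterize_scanner(sc0))

  ds <- read_dose_dataset(paths$dataset_csv, paths$dataset_json)
  fx <- make_dose_dataset(sp, sc0)
  expect_equal(ds$coeff[rownames(fx$dataset$coeff), ], fx$dataset$coeff)

  tab <- read_cf_table(paths$cf_csv, "head", "male")
  cf0 <- make_cf_tables(sp)
  expect_equal(tab$cf[names(cf0$male[["head"]]$cf)], cf0$male[["head"]]$cf)

  lib <- read_reference_library(paths$library_csv)
  expect_identical(match_scanner(characterize_scanner(sc), lib, 120)$dataset_id,
                   sprintf("planted-%d", sp$seed))

  sch <- load_scheme_json(paths$scheme_json)
  expect_equal(sum(sch$weights) + sch$remainder_weight, 1.0)

  # manifest JSON is an external record of the same oracle values
  man <- jsonlite::read_json(paths$manifest_json, simplifyVector = TRUE)
  expect_equal(unlist(man$cases$expected_mGy[1, ]),
               fx$manifest[[1]]$expected, tolerance = 1e-12)
})
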