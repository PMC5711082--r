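test_that("the built-in ICRP 103 scheme satisfies the sum-to-one invariant", {
  sch <- icrp103_scheme()
  expect_s3_class(sch, "tissue_weighting_scheme")
  expect_equal(sum(sch$weights) + sch$remainder_weight, 1.0, tolerance = 1e-12)
  expect_true("gonads" %in% names(sch$weights))
  expect_length(sch$remainder_tissues, 14L)
  # a corrupted scheme is rejected at construction
  expect_error(tissue_weighting_scheme("bad", c(lung = 0.5), 0.4, "kidneys"),
               "sum to 1")
})

test_that("equivalent dose relabels photon doses and scales by W_R", {
  expect_equal(equivalent_dose(c(brain = 2.0)), c(brain = 2.0))
  expect_length(equivalent_dose(numeric(0)), 0L)
  expect_equal(equivalent_dose(c(x = 3), radiation_weighting(2)), c(x = 6))
  expect_error(equivalent_dose(c(x = -1)), ">= 0")
})

test_that("a uniform unit equivalent-dose field yields exactly 1 mSv", {
  sch <- icrp103_scheme()
  tissues <- c(names(sch$weights), sch$remainder_tissues)
  h <- stats::setNames(rep(1.0, length(tissues)), tissues)
  expect_equal(effective_dose(h, sch)$ed, 1.0)
  h0 <- stats::setNames(rep(0, length(tissues)), tissues)
  expect_equal(effective_dose(h0, sch)$ed, 0.0)
})

test_that("effective dose matches an independent brute-force weighted sum", {
  sch <- icrp103_scheme()
  all_tissues <- c(names(sch$weights), sch$remainder_tissues)
  set.seed(51)
  for (i in 1:500) {
    # random subsets exercise both missing named tissues and remainder gaps
    pick <- sample(all_tissues, sample(3:length(all_tissues), 1))
    h <- stats::setNames(runif(length(pick), 0, 30), pick)
    got <- suppressWarnings(effective_dose(h, sch))$ed
    expect_equal(got, brute_force_ed(h, sch))
  }
})

test_that("remainder tissues absent from the map are excluded from the mean, not zeroed", {
  sch <- tissue_weighting_scheme("toy", c(lung = 0.5, brain = 0.2), 0.3,
                                 c("kidneys", "spleen", "thymus"))
  h <- c(lung = 1, brain = 1, kidneys = 2)  # spleen/thymus unscored
  expect_warning(got <- effective_dose(h, sch), "spleen, thymus")
  expect_equal(got$ed, 0.5 + 0.2 + 0.3 * 2)  # mean over present = 2, not 2/3
})

test_that("organ-to-tissue mapping folds the sex-appropriate gonad organ", {
  d <- c(brain = 1, testes = 4, ovaries = 6, breast = 2)
  m <- map_organs_to_tissues(d, "male")
  f <- map_organs_to_tissues(d, "female")
  expect_equal(unname(m["gonads"]), 4)
  expect_false("ovaries" %in% names(m))
  expect_equal(unname(f["gonads"]), 6)
  expect_false("testes" %in% names(f))
  expect_true(all(c("breasts", "brain") %in% names(m)))
})

test_that("sex averaging halves single-sex contributions and averages shared tissues", {
  sch <- icrp103_scheme()
  hm <- c(lung = 2, gonads = 4, brain = 1)
  hf <- c(lung = 4, gonads = 8, brain = 1)
  em <- suppressWarnings(effective_dose(hm, sch, "male"))
  ef <- suppressWarnings(effective_dose(hf, sch, "female"))
  avg <- sex_averaged_ed(em, ef, sch)
  expect_identical(avg$sex, "averaged")
  expect_equal(unname(avg$h_t["lung"]), 3)
  expect_equal(unname(avg$h_t["gonads"]), 6)
  # identical inputs are a fixed point
  same <- sex_averaged_ed(em, em, sch)
  expect_equal(same$ed, em$ed)
  # all tissues shared: averaged ED = (a + b) / 2 by linearity
  expect_equal(avg$ed, (em$ed + ef$ed) / 2)
  # per-tissue averaging oracle over the union, absences at half weight
  hm2 <- c(lung = 2, prostate = 3); hf2 <- c(lung = 6, uterus = 5)
  em2 <- suppressWarnings(effective_dose(hm2, sch, "male"))
  ef2 <- suppressWarnings(effective_dose(hf2, sch, "female"))
  avg2 <- sex_averaged_ed(em2, ef2, sch)
  expect_equal(unname(avg2$h_t[c("lung", "prostate", "uterus")]),
               c(4, 1.5, 2.5))
  expect_error(sex_averaged_ed(em, structure(list(scheme = "other"),
                                             class = "effective_dose_result"),
                               sch), "same weighting scheme")
})

test_that("with identity factors the sexes differ only through the gonad term", {
  sp <- fixture_spec(61, n_organs = length(FIXTURE_ORGANS))
  fx <- make_dose_dataset(sp)
  # uterus is a female-only remainder tissue; exclude it so the organ sets
  # are sex-symmetric apart from the gonads themselves
  cf <- make_cf_tables(sp, organs = setdiff(FIXTURE_ORGANS, "uterus"))
  p <- fx$manifest[[1]]$protocol
  sch <- icrp103_scheme()
  rep <- full_pipeline(fx$scanner, fx$dataset, p,
                       cf$identity_male, cf$identity_female, sch)
  # zero the gonad weight (reassign it to lung to keep the sum at 1)
  w2 <- sch$weights[names(sch$weights) != "gonads"]
  w2["lung"] <- w2["lung"] + sch$weights[["gonads"]]
  sch0 <- tissue_weighting_scheme("no-gonad", w2, sch$remainder_weight,
                                  sch$remainder_tissues)
  em0 <- suppressWarnings(effective_dose(rep$ed_male$h_t, sch0, "male"))
  ef0 <- suppressWarnings(effective_dose(rep$ed_female$h_t, sch0, "female"))
  # male and female gonad doses differ (testes vs ovaries coefficients)...
  expect_false(isTRUE(all.equal(rep$ed_male$ed, rep$ed_female$ed)))
  # ...but removing the gonad weight removes the entire difference
  expect_equal(em0$ed, ef0$ed)
})

test_that("the full pipeline is linear in mA and zero at zero mAs", {
  sp <- fixture_spec(62, n_organs = 15)
  fx <- make_dose_dataset(sp)
  cf <- make_cf_tables(sp)
  mk <- function(ma) scan_protocol(120, ma, 0.5, 32, 1, 100, 300, "helical")
  r1 <- full_pipeline(fx$scanner, fx$dataset, mk(200),
                      cf$male[["chest"]], cf$female[["chest"]])
  r2 <- full_pipeline(fx$scanner, fx$dataset, mk(400),
                      cf$male[["chest"]], cf$female[["chest"]])
  expect_equal(r2$mird$doses, 2 * r1$mird$doses)
  expect_equal(r2$ed_male$ed, 2 * r1$ed_male$ed)
  expect_equal(r2$ed_averaged$ed, 2 * r1$ed_averaged$ed)
  expect_equal(r2$console$dlp, 2 * r1$console$dlp)
  r0 <- full_pipeline(fx$scanner, fx$dataset, mk(0),
                      cf$male[["chest"]], cf$female[["chest"]])
  expect_equal(unname(r0$mird$doses), rep(0, length(r0$mird$doses)))
  expect_equal(r0$ed_averaged$ed, 0)
})
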