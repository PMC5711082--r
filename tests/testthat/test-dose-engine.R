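test_that("slab coverage weights reflect full, partial and conserved overlap", {
  ph <- slab_phantom(208, 5, "organA")
  p <- scan_protocol(120, 200, 0.5, 32, 1, start_mm = 0, end_mm = 160,
                     mode = "helical")
  w <- slabs_covered(p, ph)
  expect_equal(w[1:32], rep(1, 32))
  expect_equal(w[33:208], rep(0, 176))

  p2 <- scan_protocol(120, 200, 0.5, 32, 1, start_mm = 0, end_mm = 2.5,
                      mode = "helical")
  w2 <- slabs_covered(p2, ph)
  expect_equal(w2[1], 0.5)
  expect_equal(sum(w2), 0.5)

  set.seed(31)
  for (i in 1:50) {
    a <- runif(1, 0, 1000); b <- a + runif(1, 1, 40)
    pr <- scan_protocol(120, 200, 0.5, 32, 1, start_mm = a, end_mm = b,
                        mode = "helical")
    expect_equal(sum(slabs_covered(pr, ph)), (b - a) / 5)
  }
  expect_error(slabs_covered(
    scan_protocol(120, 200, 0.5, 32, 1, 2000, 2100, "helical"), ph),
    "does not overlap")
})

test_that("organ dose resolves a single-slab coefficient at unit scale", {
  sc <- tiny_scanner(air120 = 1)  # CTDIair = 1 mGy per 100 mAs at 120 kV
  ds <- delta_dataset(slab = 11L, value = 1)
  # slab 11 (0-based 10) spans [50, 55) mm; 100 mAs total, rel_ctdi 1, pitch 1
  p <- scan_protocol(120, 200, 0.5, 32, 1, start_mm = 50, end_mm = 55,
                     mode = "helical")
  r <- organ_dose(ds, p, sc)
  expect_equal(unname(r$doses["organA"]), 1.0)
  expect_identical(r$phantom_label, "MIRD-5")

  # doubling mA doubles the dose
  p2 <- scan_protocol(120, 400, 0.5, 32, 1, 50, 55, "helical")
  expect_equal(organ_dose(ds, p2, sc)$doses, 2 * r$doses)
})

test_that("helical dose scales as 1/pitch at fixed per-rotation mAs", {
  set.seed(32)
  sp <- fixture_spec(101, n_organs = 8)
  fx <- make_dose_dataset(sp)
  for (i in 1:20) {
    a <- runif(1, 0, 800); b <- a + runif(1, 10, 200)
    p1 <- scan_protocol(120, 200, 0.5, 32, pitch = 1, a, b, "helical")
    p2 <- scan_protocol(120, 200, 0.5, 32, pitch = 2, a, b, "helical")
    expect_equal(organ_dose(fx$dataset, p2, fx$scanner)$doses,
                 organ_dose(fx$dataset, p1, fx$scanner)$doses / 2)
  }
})

test_that("organ doses are additive over split ranges and monotone in range", {
  sp <- fixture_spec(102, n_organs = 12)
  fx <- make_dose_dataset(sp)
  set.seed(33)
  for (i in 1:30) {
    a <- runif(1, 0, 700); c <- a + runif(1, 20, 300)
    b <- runif(1, a + 1, c - 1)
    dose <- function(lo, hi) organ_dose(
      fx$dataset,
      scan_protocol(120, 200, 0.5, 32, 1, lo, hi, "helical"),
      fx$scanner)$doses
    expect_equal(dose(a, c), dose(a, b) + dose(b, c))
    expect_true(all(dose(a, c) >= dose(a, b) - 1e-12))
  }
})

test_that("doses are linear in the coefficient matrix and vanish for a zero dataset", {
  ph <- slab_phantom(50, 5, c("x", "y"))
  co <- matrix(runif(100), 2, 50, dimnames = list(c("x", "y"), NULL))
  sc <- tiny_scanner()
  p <- scan_protocol(120, 200, 0.5, 32, 1, 30, 170, "helical")
  base <- organ_dose(dose_dataset(ph, co, 120), p, sc)$doses
  expect_equal(organ_dose(dose_dataset(ph, 3 * co, 120), p, sc)$doses, 3 * base)
  expect_equal(unname(organ_dose(dose_dataset(ph, 0 * co, 120), p, sc)$doses),
               c(0, 0))
})

test_that("contiguous axial and wide volume modes agree under equal relative CTDI", {
  sp <- fixture_spec(103, n_organs = 10)
  fx <- make_dose_dataset(sp, make_scanner(sp))
  # equal rel_ctdi: force both menu entries to 1.0
  sc_eq <- scanner_model("eq", fx$scanner$measurements,
                         rel_ctdi_table(c(16, 32, 160), c(1, 1, 1), 16))
  both <- compare_modes(fx$dataset, sc_eq, 100, 260, 32, 160)
  expect_equal(both$axial$doses, both$volume$doses)
  # 160 mm range with 32 mm collimation tiles in exactly 5 rotations
  expect_equal((260 - 100) / 32, 5)

  # unequal rel_ctdi factors out: volume = (rel160/rel32) * axial
  sc_ne <- scanner_model("ne", fx$scanner$measurements,
                         rel_ctdi_table(c(16, 32, 160), c(1, 1, 0.9), 16))
  both2 <- compare_modes(fx$dataset, sc_ne, 100, 260, 32, 160)
  expect_equal(both2$volume$doses, 0.9 * both2$axial$doses)
  expect_warning(compare_modes(fx$dataset, sc_eq, 100, 250, 32, 160),
                 "does not divide")
})

test_that("protocol and dataset consistency is enforced", {
  sc <- tiny_scanner()
  ds <- delta_dataset(kv = 120)
  expect_error(organ_dose(ds, scan_protocol(100, 200, 0.5, 32, 1, 0, 100,
                                            "helical"), sc),
               "does not match protocol kV")
  expect_error(organ_dose(ds, scan_protocol(120, 200, 0.5, 24, 1, 0, 100,
                                            "helical"), sc),
               "not in the table")
  expect_error(scan_protocol(120, 200, 0.5, 32, 1, 100, 100, "helical"),
               "end_mm")
  expect_error(scan_protocol(120, 200, 0.5, 32, 1, 0, 160, "volume_axial"),
               "cover the scan range")
})
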