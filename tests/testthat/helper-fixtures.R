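# Shared builders and independent oracles for the test suite.

flat_profile <- function(level = 1, span = 150, by = 1) {
  z <- seq(-span, span, by = by)
  dose_profile(z, rep(level, length(z)))
}

# minimal two-kV scanner with a trivial collimation menu; all measurements
# scale with the requested free-in-air value so the invariants always hold
tiny_scanner <- function(air120 = 10, rel32 = 1.0, rel160 = 1.0) {
  rc <- rel_ctdi_table(c(5, 16, 32, 160), c(1.2, 1.0, rel32, rel160), 16)
  k <- air120 / 10
  scanner_model("tiny", list(
    ctdi_measurement_set(120, 8 * k, 9 * k, 3 * k, 6 * k, air120),
    ctdi_measurement_set(100, 6, 7, 2.5, 5, 7)), rc)
}

# one-organ dataset with a single nonzero slab coefficient
delta_dataset <- function(slab = 11L, value = 1, n_slabs = 208L, kv = 120) {
  ph <- slab_phantom(n_slabs, 5, "organA")
  co <- matrix(0, 1, n_slabs, dimnames = list("organA", NULL))
  co[1, slab] <- value
  dose_dataset(ph, co, kv, "delta")
}

# Independent effective-dose oracle: explicit loops over named tissues and
# the remainder mean, coded without reference to effective_dose().
brute_force_ed <- function(h, scheme) {
  total <- 0
  for (t in names(scheme$weights)) {
    if (t %in% names(h)) total <- total + scheme$weights[[t]] * h[[t]]
  }
  rem <- c()
  for (t in scheme$remainder_tissues) {
    if (t %in% names(h)) rem <- c(rem, h[[t]])
  }
  if (length(rem) > 0 && scheme$remainder_weight > 0)
    total <- total + scheme$remainder_weight * sum(rem) / length(rem)
  total
}

# Brute-force library match: scan all rows at the kv, recompute scores.
brute_force_match <- function(target_row, entries, kv) {
  sub <- entries[entries$kv == kv, , drop = FALSE]
  best <- NULL; best_score <- Inf
  for (i in seq_len(nrow(sub))) {
    s <- abs(sub$imf_head[i] - target_row$imf_head) / target_row$imf_head +
         abs(sub$imf_body[i] - target_row$imf_body) / target_row$imf_body
    if (s < best_score) { best_score <- s; best <- sub$dataset_id[i] }
  }
  list(dataset_id = best, score = best_score)
}

random_dose_map <- function(organs, max = 20) {
  stats::setNames(stats::runif(length(organs), 0.01, max), organs)
}
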