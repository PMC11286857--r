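test_that("Bliss expectation follows 1 - (1-v)(1-w)", {
  expect_equal(bliss_ci(0, 0), 0)
  expect_equal(bliss_ci(1, 0.3), 1)  # absorbing at full effect
  # effects from 50.9% and 51.9% survival
  expect_equal(bliss_ci(0.491, 0.481), 0.735829, tolerance = 1e-6)
  expect_error(bliss_ci(1.2, 0.5), "\\[0, 1\\]")
})

test_that("Bliss expectation is symmetric, monotone and bounded", {
  set.seed(6)
  v <- stats::runif(30); w <- stats::runif(30)
  expect_equal(bliss_ci(v, w), bliss_ci(w, v))
  expect_true(all(bliss_ci(v, w) >= 0 & bliss_ci(v, w) <= 1))
  expect_true(all(bliss_ci(pmin(1, v + 0.1), w) >= bliss_ci(v, w)))
})

test_that("dose_response validates plate rows", {
  expect_error(dose_response(c(1, 0.5), c(0.9, 0.5)), "increasing")
  expect_error(dose_response(c(0, 1), c(0.9, 0.5)), "positive")
  expect_error(dose_response(c(1, 2), c(0.9, 1.8)), "1.5")
  expect_warning(dr <- dose_response(c(1, 2), c(1.1, 0.4)), "stimulation")
  expect_equal(dr$effect, c(0, 0.6))
})

test_that("EC_u interpolates log-linearly between measured points", {
  curve <- dose_response(c(1, 10), c(0.8, 0.2))  # effects 0.2, 0.8
  expect_equal(ec_u(curve, 0.5), 10^0.5, tolerance = 1e-10)
  # a measured effect returns the measured concentration
  expect_equal(ec_u(curve, 0.2), 1)
  expect_equal(ec_u(curve, 0.8), 10)
  # no extrapolation outside the observed effect range
  expect_error(ec_u(curve, 0.9), "outside")
})

test_that("EC_u inverts the interpolated curve and cleans non-monotone data", {
  curve <- dose_response(c(0.5, 1, 2, 4, 8), c(0.95, 0.8, 0.55, 0.3, 0.1))
  for (i in seq_len(nrow(curve))) {
    expect_equal(ec_u(curve, curve$effect[i]), curve$concentration[i])
  }
  # interior concentrations round-trip through effect_at
  cmid <- 2.7
  expect_equal(ec_u(curve, effect_at(curve, cmid)), cmid, tolerance = 1e-9)

  wobble <- dose_response(c(1, 2, 4, 8), c(0.8, 0.6, 0.65, 0.2))
  expect_warning(e <- ec_u(wobble, 0.5), "isotonic")
  expect_true(e > 1 && e < 8)
})

test_that("Loewe toxic unit behaves on the additivity line", {
  expect_equal(loewe_tu(2, 0, 2, 5), 1)          # single-drug consistency
  expect_equal(loewe_tu(1, 2.5, 2, 5), 1)        # matched half-potencies
  expect_equal(loewe_tu(0.5, 1.25, 2, 5), 0.5)   # synergy region
  expect_error(loewe_tu(1, 1, 0, 5), "positive")
  # linear in each concentration
  expect_equal(loewe_tu(2, 4, 3, 7) / 2, loewe_tu(1, 2, 3, 7))
})

test_that("an additive noise-free plate sits exactly on the Loewe line", {
  cfg <- synth_config(plate_noise_sd = 0, bliss_excess = 0.3)
  plate <- generate_plate(cfg, synergistic = FALSE, seed = 3)
  res <- plate_synergy(plate)
  expect_equal(res$ca, rep(1, nrow(res)), tolerance = 1e-9)
  # Bliss prediction matches the observation for the additive plant
  expect_equal(res$observed_effect, res$bliss_expected, tolerance = 1e-9)
})

test_that("a planted Bliss excess is detected by both models", {
  cfg <- synth_config(plate_noise_sd = 0, bliss_excess = 0.5)
  plate <- generate_plate(cfg, synergistic = TRUE, seed = 3)
  res <- plate_synergy(plate)
  expect_true(all(res$observed_effect > res$bliss_expected))
  expect_true(all(res$ia_synergy))
  expect_true(all(res$ca < 1))
})

test_that("plates are bit-reproducible under a fixed seed", {
  cfg <- synth_config()
  p1 <- generate_plate(cfg, TRUE, seed = 9)
  p2 <- generate_plate(cfg, TRUE, seed = 9)
  expect_identical(p1$combos, p2$combos)
  expect_identical(p1$curves[[1]]$survival, p2$curves[[1]]$survival)
  p3 <- generate_plate(cfg, TRUE, seed = 10)
  expect_false(identical(p1$combos$survival, p3$combos$survival))
})

test_that("synergy fractions reproduce the published validation summary", {
  tab <- cml_validation_table()
  summ <- classify_and_summarize(tab)
  expect_equal(summ$ca$n, 17L)          # three pairs excluded from validation
  expect_equal(summ$ca$n_synergistic, 13L)
  expect_equal(summ$ca$pct, 76.5)
  expect_equal(summ$ia$n, 17L)
  expect_equal(summ$ia$n_synergistic, 15L)
  expect_equal(summ$ia$pct, 88.2)
})

test_that("additive boundaries are not called synergistic", {
  s <- data.frame(ca = c(1, 0.99), ia_excess = c(0, 0.01))
  out <- classify_and_summarize(s)
  expect_equal(out$ca$n_synergistic, 1L)  # TU = 1 exactly is additive
  expect_equal(out$ia$n_synergistic, 1L)  # zero excess is additive
  expect_error(classify_and_summarize(data.frame(x = 1)), "columns")
})

test_that("additive plates rarely trip the CA synergy call under noise", {
  cfg <- synth_config(plate_noise_sd = 0.03)
  calls <- vapply(1:100, function(s) {
    res <- suppressWarnings(
      plate_synergy(generate_plate(cfg, synergistic = FALSE, seed = s)))
    # conservative plate-level call: every evaluable well below additivity
    ok <- !is.na(res$ca)
    any(ok) && all(res$ca_synergy[ok])
  }, logical(1))
  expect_lte(mean(calls), 0.10)
})
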