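test_that("sensitivity factors normalise to the batch mean", {
  expect_equal(sensitivity_factors(c(a = 100, b = 100, c = 100)),
               c(a = 1, b = 1, c = 1))
  expect_equal(sensitivity_factors(c(a = 90, b = 110)),
               c(a = 0.9, b = 1.1))
  set.seed(7)
  x <- stats::setNames(rlnorm(30, 5, 0.2), paste0("c", 1:30))
  f <- sensitivity_factors(x)
  expect_equal(mean(f), 1, tolerance = 1e-15)
  expect_error(sensitivity_factors(c(a = 1, b = 0)), "non-positive")
  expect_error(sensitivity_factors(c(a = 1)), "at least 2")
})

test_that("effective exposure time is the decay-weighted duration", {
  # 1 h against a 17 d half-life: barely below the wall-clock time
  expect_equal(effective_exposure_time(1, 17), 0.9991510, tolerance = 1e-7)
  # short-exposure limit: t_eff / T -> 1
  expect_equal(effective_exposure_time(1e-6, 17) / 1e-6, 1, tolerance = 1e-8)
  # exactly one half-life: t_eff = T_half / (2 ln 2)
  expect_equal(effective_exposure_time(17 * 24, 17) / 24,
               0.5 * 17 / log(2), tolerance = 1e-12)
  expect_equal(effective_exposure_time(17 * 24, 17) / 24, 12.2629,
               tolerance = 1e-5)
  expect_error(effective_exposure_time(0, 17), "> 0")
  expect_error(effective_exposure_time(1, -2), "> 0")
})

make_flat_experiment <- function(dose_per_sk, sk = 2, eps = 50,
                                 t_hours = 10, bkg = 4, n_rep = 3) {
  # deterministic forward model at positions (1, 90) and (2, 90)
  half <- 16.991
  t_eff <- effective_exposure_time(t_hours, half)
  pos <- data.frame(r = rep(c(1, 2), each = n_rep), theta = 90)
  dose <- dose_per_sk[match(pos$r, c(1, 2))] * sk
  ids <- sprintf("c%02d", seq_len(nrow(pos)))
  sens <- stats::setNames(rep(1, length(ids)), ids)
  reading <- bkg + dose * t_eff * eps
  list(readings = tld_reading_set(ids, pos$r, pos$theta, reading,
                                  rep(bkg, 4), exposure_hours = t_hours),
       cal = calibration_set(eps, sens), sk = sk)
}

test_that("reduction inverts the forward model exactly at zero noise", {
  ex <- make_flat_experiment(c(0.690, 0.30))
  out <- reduce_tld(ex$readings, ex$cal, sk = ex$sk)
  expect_equal(out$dose_per_sk, c(0.690, 0.30), tolerance = 1e-12)
  expect_equal(out$n, c(3, 3))
  expect_equal(out$type_a_pct, c(0, 0))
})

test_that("a reading equal to mean background reduces to zero dose silently", {
  ex <- make_flat_experiment(c(0.690, 0.30))
  rs <- ex$readings
  rs$readings$reading[1] <- mean(rs$background_readings)
  expect_silent(out <- reduce_tld(rs, ex$cal, sk = ex$sk))
  # that chip contributes 0 to its position mean
  expect_equal(out$dose_per_sk[out$r == 1], 0.690 * 2 / 3, tolerance = 1e-12)
})

test_that("below-background chips are clamped to zero with a warning", {
  ex <- make_flat_experiment(c(0.690, 0.30))
  rs <- ex$readings
  rs$readings$reading[1] <- 0
  expect_warning(out <- reduce_tld(rs, ex$cal, sk = ex$sk), "clamped")
  expect_true(all(out$dose_per_sk >= 0))
})

test_that("reduction is linear in the raw readings", {
  cfg <- simulator_config(random_seed = 11L)
  sim <- simulate_tld_experiment(cfg)
  out1 <- reduce_tld(sim$readings, sim$calibration, sk = sim$truth$sk_true)
  scaled <- sim$readings
  scaled$readings$reading <- scaled$readings$reading * 3
  scaled$background_readings <- scaled$background_readings * 3
  out3 <- reduce_tld(scaled, sim$calibration, sk = sim$truth$sk_true)
  expect_equal(out3$dose_per_sk, 3 * out1$dose_per_sk, tolerance = 1e-12)
  expect_equal(out3$type_a_pct, out1$type_a_pct, tolerance = 1e-10)
})

test_that("reduction is invariant to chip relabeling", {
  cfg <- simulator_config(random_seed = 12L)
  sim <- simulate_tld_experiment(cfg)
  out <- reduce_tld(sim$readings, sim$calibration, sk = sim$truth$sk_true)
  perm <- sample(nrow(sim$readings$readings))
  shuffled <- sim$readings
  shuffled$readings <- shuffled$readings[perm, ]
  out2 <- reduce_tld(shuffled, sim$calibration, sk = sim$truth$sk_true)
  expect_equal(out2, out, tolerance = 1e-12)
})

test_that("calibration errors are specific", {
  ex <- make_flat_experiment(c(0.690, 0.30))
  cal_missing <- calibration_set(50, c(c01 = 1, c02 = 1))
  expect_error(reduce_tld(ex$readings, cal_missing, sk = 2),
               "no sensitivity factor")
  er <- data.frame(r = 1, theta = 90, E = 1.02)
  cal_er <- calibration_set(50, ex$cal$sensitivity, energy_response = er)
  expect_error(reduce_tld(ex$readings, cal_er, sk = 2),
               "no energy-response entry")
  expect_error(calibration_set(50, c(a = 0.5, b = 0.6)), "batch mean 1")
  expect_error(calibration_set(-1, c(a = 1, b = 1)), "> 0")
})

test_that("an energy-response table rescales doses position-wise", {
  ex <- make_flat_experiment(c(0.690, 0.30))
  er <- data.frame(r = c(1, 2), theta = 90, E = c(1.05, 0.95))
  cal <- calibration_set(50, ex$cal$sensitivity, energy_response = er)
  out <- reduce_tld(ex$readings, cal, sk = ex$sk)
  expect_equal(out$dose_per_sk, c(0.690 / 1.05, 0.30 / 0.95),
               tolerance = 1e-12)
})

test_that("uncertainties combine in quadrature", {
  expect_equal(combine_uncertainty(3, 4)$combined, 5)
  expect_equal(combine_uncertainty(2.9, 0)$combined, 2.9)
  expect_equal(combine_uncertainty(2.9, 6.37)$combined, 7.0, tolerance = 1e-3)
  b <- combine_uncertainty(2.9, 6.37)
  expect_s3_class(b, "uncertainty_budget")
  expect_equal(b$combined^2, b$type_a^2 + b$type_b^2, tolerance = 1e-12)
  expect_error(combine_uncertainty(-1, 2), ">= 0")
})
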