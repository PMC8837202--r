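test_that("plateau centering subtracts the first-five mean and is idempotent", {
  expect_equal(center_plateau(rep(7, 20)), rep(0, 20))
  x <- c(1, 2, 3, 2, 2, 9, 9)
  expect_equal(center_plateau(x), x - 2)
  y <- rnorm(50) + 13
  expect_equal(center_plateau(center_plateau(y)), center_plateau(y))
  expect_error(center_plateau(1:4), "at least 5")
})

test_that("effective noise SD is the median sliding-window sd", {
  expect_identical(estimate_noise(rep(2, 30))$eSD, 0)
  expect_error(estimate_noise(rnorm(5), width = 10), "shorter")
  # Monte-Carlo oracle for the median of a 10-sample sd estimator
  set.seed(101)
  mc_median <- median(apply(matrix(rnorm(10 * 1e5), ncol = 10), 1, sd))
  set.seed(202)
  x <- rnorm(10000, sd = 2.5)
  expect_equal(estimate_noise(x)$eSD / 2.5, mc_median, tolerance = 0.02)
  # robustness: a single large step barely moves the estimate
  set.seed(303)
  y <- c(rnorm(5000), rnorm(5000, mean = 40))
  expect_equal(estimate_noise(y)$eSD, 1, tolerance = 0.1)
})

test_that("Viterbi decoding finds a noiseless step exactly and ignores pure noise", {
  esd <- 0.5
  seg <- c(rep(0, 120), rep(4 * esd, 80))
  path <- viterbi_decode(seg, esd)
  expect_identical(path$changepoint, 120L)
  expect_identical(path$first_unbound, 121L)
  expect_identical(path$states, c(rep(1L, 120), rep(2L, 80)))
  set.seed(11)
  quiet <- rnorm(500, 0, esd)
  expect_true(is.na(viterbi_decode(quiet, esd)$changepoint))
  expect_error(viterbi_decode(seg, 0), "eSD")
})

test_that("Viterbi equals the exhaustive single-changepoint scan on random plateaus", {
  set.seed(1234)
  for (i in 1:100) {
    pl <- random_plateau()
    esd <- 1
    got <- viterbi_decode(pl$segment, esd)$changepoint
    want <- oracle_changepoint(pl$segment, esd)
    expect_identical(got, want)
  }
})

test_that("decoding is invariant to joint scaling of segment and noise", {
  set.seed(21)
  pl <- random_plateau(n = 300)
  base <- viterbi_decode(pl$segment, 1)
  for (c_scale in c(0.01, 3, 250)) {
    scaled <- viterbi_decode(pl$segment * c_scale, c_scale)
    expect_identical(scaled$changepoint, base$changepoint)
    expect_identical(scaled$states, base$states)
  }
})

test_that("changepoint location is insensitive to the transition probability", {
  set.seed(31)
  for (i in 1:20) {
    pl <- random_plateau(p_step = 1, step_range = c(3, 6))
    cps <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2), function(p) {
      viterbi_decode(pl$segment, 1, p_trans = p)$changepoint
    }, integer(1))
    expect_true(all(cps == cps[1]))
  }
})

test_that("event extraction converts the changepoint to lifetime and step", {
  esd <- 1
  seg <- c(rep(0, 100), rep(5.5, 100))
  path <- viterbi_decode(seg, esd)
  ev <- extract_event(seg, path, sampling_rate = 200)
  expect_true(ev$accepted)
  expect_equal(ev$tau, 0.5)
  expect_equal(ev$delta_x, 5.5)
  expect_identical(ev$n_pre_samples, 100L)
  # too few bound samples
  seg2 <- c(rep(0, 3), rep(5.5, 60))
  path2 <- viterbi_decode(seg2, esd)
  ev2 <- extract_event(seg2, path2, 200)
  expect_false(ev2$accepted)
  expect_match(ev2$reason, "pre_samples")
  # no changepoint
  ev3 <- extract_event(seg, structure(list(changepoint = NA_integer_),
                                      class = "state_path"), 200)
  expect_false(ev3$accepted)
})

test_that("step estimate uses equal pre/post windows", {
  # 10 bound samples then a long drifting tail: equal windows limit the
  # drift influence to the 10 samples right after the step
  seg <- c(rep(0, 10), 4 + 0.01 * (0:189))
  path <- viterbi_decode(seg, 1)
  ev <- extract_event(seg, path, 200)
  expect_identical(ev$n_pre_samples, 10L)
  expect_equal(ev$delta_x, mean(4 + 0.01 * (0:9)))
})

test_that("drift screen truncates around the changepoint and rescues the step", {
  set.seed(41)
  esd <- 1
  n <- 1000
  cp <- 300
  drift <- 5 * esd * seq_len(n) / n # 5 eSD across the plateau
  seg <- center_plateau(rnorm(n, 0, esd) + drift +
                          c(rep(0, cp), rep(6, n - cp)))
  noise <- estimate_noise(seg)
  path <- viterbi_decode(seg, noise)
  tr <- truncate_for_drift(seg, path, noise, 200)
  expect_true(tr$truncated)
  # window always contains the changepoint
  cp_local <- path$changepoint - tr$offset
  expect_gte(cp_local, 1L)
  expect_lte(cp_local, length(tr$segment))
  loc <- structure(list(changepoint = cp_local), class = "state_path")
  ev <- extract_event(tr$segment, loc, 200)
  expect_equal(ev$delta_x, 6, tolerance = 0.6) # within 10% of truth
  # drift-free segment passes through unchanged
  flat <- center_plateau(c(rnorm(cp, 0, esd), rnorm(n - cp, 6, esd)))
  path_f <- viterbi_decode(flat, estimate_noise(flat))
  tr_f <- truncate_for_drift(flat, path_f, estimate_noise(flat), 200)
  expect_false(tr_f$truncated)
  expect_identical(tr_f$segment, flat)
})

test_that("detector recalls nearly all clean events at 4 eSD separation", {
  truth <- rsa4_truth()
  g <- geom55()
  # single force, no drift, no instrument response: step is exactly
  # delta_x; noise scaled so the step is 4 eSD
  dx <- predict_delta_x(6, g)
  cfg <- simulation_config(truth, constructs = 55, n_molecules = 1,
                           cycles_per_molecule = 150, high_forces = 6,
                           p_bind = 1, noise_sd = dx / 4, drift_sd = 0,
                           response_time_s = 0)
  dcfg <- detection_config(skip_initial_samples = 0)
  set.seed(51)
  tr <- simulate_session(cfg, 55, "clean")
  ev <- detect_events(tr, g, dcfg)
  gt <- tr$ground_truth
  m <- merge(ev, gt, by = "plateau_id", all = TRUE)
  eligible <- m$tau >= 5 / 200 & m$tau < 4.9
  recall <- mean(!is.na(m$tau_s[eligible]))
  expect_gte(recall, 0.95)
  # measured lifetimes track the truth closely
  hits <- m[eligible & !is.na(m$tau_s), ]
  expect_lt(median(abs(hits$tau_s - hits$tau)), 0.01)
})

test_that("no event shorter than the four-sample minimum is reported", {
  truth <- rsa4_truth()
  g <- geom55()
  cfg <- simulation_config(truth, constructs = 55, n_molecules = 1,
                           cycles_per_molecule = 60, high_forces = 12,
                           p_bind = 1, drift_sd = 0)
  dcfg <- detection_config(skip_initial_samples = 0)
  set.seed(61)
  tr <- simulate_session(cfg, 55, "fast")
  ev <- detect_events(tr, g, dcfg)
  if (nrow(ev) > 0) expect_true(all(ev$tau_s >= 4 / 200))
})

test_that("detection requires matching construct and valid schedule", {
  truth <- rsa4_truth()
  cfg <- simulation_config(truth, constructs = 55, n_molecules = 1,
                           cycles_per_molecule = 2)
  set.seed(71)
  tr <- simulate_session(cfg, 55, "m")
  expect_error(detect_events(tr, geom70()), "does not match")
})
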