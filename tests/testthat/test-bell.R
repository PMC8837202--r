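test_that("catch-slip lifetime has the right limits and chevron shape", {
  p <- rsa4_truth()
  expect_equal(catch_slip_lifetime(0, p), 1 / (5.3 + 0.01))
  # rises to a maximum then falls
  grid <- seq(0, 12, by = 0.01)
  tau <- catch_slip_lifetime(grid, p)
  imax <- which.max(tau)
  expect_gt(grid[imax], 0)
  expect_lt(grid[imax], 12)
  expect_true(all(diff(tau[1:imax]) > 0))
  expect_true(all(diff(tau[imax:length(tau)]) < 0))
  # lifetime at the closed-form critical force is the grid maximum
  # (agreement limited by the 0.01 pN grid spacing)
  expect_equal(catch_slip_lifetime(p$F_crit, p), max(tau),
               tolerance = 1e-4)
})

test_that("critical force closed form matches its algebraic special case", {
  # symmetric distances, rate ratio r: F* = kBT log(r) / (2 xs)
  r <- 40
  xs <- 3
  p <- bell_params(kc0 = r * 0.02, xc = -xs, ks0 = 0.02, xs = xs,
                   kBT = 4.09)
  expect_equal(critical_force(p), 4.09 * log(r) / (2 * xs))
})

test_that("critical force equals the numeric argmax for random valid parameters", {
  set.seed(13)
  grid <- seq(0.001, 20, by = 0.001)
  n_checked <- 0
  for (i in 1:100) {
    p <- tryCatch(
      bell_params(kc0 = 10^runif(1, -1, 1.5), xc = -runif(1, 0.5, 6),
                  ks0 = 10^runif(1, -3, -0.5), xs = runif(1, 0.5, 6)),
      error = function(e) NULL
    )
    if (is.null(p) || is.na(p$F_crit) || p$F_crit >= 20) next
    tau <- catch_slip_lifetime(grid, p)
    expect_lt(abs(p$F_crit - grid[which.max(tau)]), 0.01)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 50)
})

test_that("no interior maximum is flagged as such", {
  # catch pathway too weak to ever dominate
  expect_error(
    critical_force(structure(list(kc0 = 0.001, xc = -0.5, ks0 = 10,
                                  xs = 3, kBT = 4.09),
                             class = "bell_params")),
    class = "forcejump_no_interior_maximum"
  )
})

test_that("noiseless mean-lifetime data identify the parameters", {
  truth <- rsa4_truth()
  F <- 1:12
  groups <- data.frame(F_Load_pN = F,
                       mean_tau_s = catch_slip_lifetime(F, truth),
                       sem_tau_s = 0, n_events = 1)
  fit <- fit_catch_slip(groups)
  expect_equal(fit$kc0, truth$kc0, tolerance = 1e-4)
  expect_equal(fit$xc, truth$xc, tolerance = 1e-4)
  expect_equal(fit$ks0, truth$ks0, tolerance = 1e-4)
  expect_equal(fit$xs, truth$xs, tolerance = 1e-4)
  expect_equal(fit$F_crit, truth$F_crit, tolerance = 1e-4)
})

test_that("fit is equivariant under rescaling of all lifetimes", {
  truth <- rsa4_truth()
  F <- 1:12
  tau <- catch_slip_lifetime(F, truth)
  set.seed(23)
  noise <- rnorm(12, 1, 0.03)
  base <- fit_catch_slip(data.frame(F_Load_pN = F,
                                    mean_tau_s = tau * noise,
                                    sem_tau_s = 0.05 * tau,
                                    n_events = 30))
  c_scale <- 10
  scaled <- fit_catch_slip(data.frame(F_Load_pN = F,
                                      mean_tau_s = c_scale * tau * noise,
                                      sem_tau_s = c_scale * 0.05 * tau,
                                      n_events = 30))
  expect_equal(scaled$kc0, base$kc0 / c_scale, tolerance = 1e-3)
  expect_equal(scaled$ks0, base$ks0 / c_scale, tolerance = 1e-3)
  expect_equal(scaled$xc, base$xc, tolerance = 1e-3)
  expect_equal(scaled$xs, base$xs, tolerance = 1e-3)
  expect_equal(scaled$F_crit, base$F_crit, tolerance = 1e-3)
})

test_that("monotone lifetime data are flagged as branch-degenerate", {
  slip_only <- data.frame(F_Load_pN = 1:6,
                          mean_tau_s = exp(-(1:6)), sem_tau_s = 0.01,
                          n_events = 10)
  expect_error(fit_catch_slip(slip_only),
               class = "forcejump_degenerate_fit")
  catch_only <- data.frame(F_Load_pN = 1:6,
                           mean_tau_s = exp((1:6) / 3), sem_tau_s = 0.01,
                           n_events = 10)
  expect_error(fit_catch_slip(catch_only),
               class = "forcejump_degenerate_fit")
  expect_error(fit_catch_slip(data.frame(F_Load_pN = 1:3,
                                         mean_tau_s = c(1, 2, 1))),
               "at least 4")
})

test_that("confidence intervals achieve nominal-like coverage on synthetic refits", {
  truth <- rsa4_truth()
  FL <- sort(c(
    vapply(c(4, 6, 8, 10, 12), function(f)
      solve_bound_state(f, geom55())$F_Load, numeric(1)),
    vapply(c(4, 6, 8, 10, 12), function(f)
      solve_bound_state(f, geom70())$F_Load, numeric(1))
  ))
  tau_true <- catch_slip_lifetime(FL, truth)
  set.seed(2024)
  hits <- matrix(NA, 200, 4,
                 dimnames = list(NULL, c("kc0", "xc", "ks0", "xs")))
  for (r in 1:200) {
    groups <- data.frame(
      F_Load_pN = FL,
      t(vapply(tau_true, function(tm) {
        taus <- rexp(30, 1 / tm)
        c(mean_tau_s = mean(taus), sem_tau_s = sd(taus) / sqrt(30))
      }, numeric(2))),
      n_events = 30
    )
    fit <- tryCatch(fit_catch_slip(groups, multistart = 3),
                    error = function(e) NULL)
    if (is.null(fit)) next
    est <- c(fit$kc0, fit$xc, fit$ks0, fit$xs)
    ci <- unlist(fit$ci95[c("kc0", "xc", "ks0", "xs")])
    tr <- c(truth$kc0, truth$xc, truth$ks0, truth$xs)
    hits[r, ] <- abs(est - tr) <= ci
  }
  coverage <- colMeans(hits, na.rm = TRUE)
  expect_true(all(coverage >= 0.85))
})

test_that("binding isotherm fit recovers exact data and satisfies the half-saturation identity", {
  conc <- 40 / 2^(0:15)
  y <- 0.8 * conc / (5 + conc)
  fit <- fit_binding_isotherm(conc, y)
  expect_equal(fit$KD, 5, tolerance = 1e-6)
  expect_equal(fit$Ymax, 0.8, tolerance = 1e-6)
  # on the fitted curve, the response at [S] = KD is half-maximal
  expect_equal(fit$Ymax * fit$KD / (fit$KD + fit$KD), fit$Ymax / 2)
})

test_that("isotherm fit rejects degenerate titrations", {
  conc <- 40 / 2^(0:15)
  expect_error(fit_binding_isotherm(conc, 0.001 * conc),
               class = "forcejump_unidentifiable_kd")
  expect_error(fit_binding_isotherm(c(1, 2, 3, 4), c(1, 2, 3, 4) * 0.1),
               "at least 5")
  expect_error(fit_binding_isotherm(c(10, 11, 12, 13, 14),
                                    rep(0.5, 5)), "decade")
})
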