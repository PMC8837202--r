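#' Catch-slip Bell model parameters
#'
#' Two-pathway force-dependent dissociation kinetics. The off-rate is the
#' sum of a catch pathway that slows with force (distance parameter
#' `xc < 0`) and a slip pathway that accelerates with force (`xs > 0`):
#' \deqn{1/\bar\tau(F) = k_{c0} e^{F x_c / k_BT} + k_{s0} e^{F x_s / k_BT}}
#'
#' @param kc0 Zero-force catch-pathway rate, 1/s (> 0).
#' @param xc Catch distance parameter, nm (< 0).
#' @param ks0 Zero-force slip-pathway rate, 1/s (> 0).
#' @param xs Slip distance parameter, nm (> 0).
#' @param kBT Thermal energy, pN nm (default 4.09).
#' @param ci95 Optional named list of per-parameter 95% confidence
#'   half-widths (from a fit).
#'
#' @return An object of class `"bell_params"`, with `F_crit` (the
#'   critical force, pN) precomputed when an interior lifetime maximum
#'   exists and `NA` otherwise.
#' @export
#' @examples
#' rsa4 <- bell_params(kc0 = 5.3, xc = -2.0, ks0 = 0.01, xs = 4.1)
#' catch_slip_lifetime(c(1, 4, 8), rsa4)
bell_params <- function(kc0, xc, ks0, xs, kBT = 4.09, ci95 = NULL) {
  stopifnot(kc0 > 0, ks0 > 0, xc < 0, xs > 0, kBT > 0)
  p <- structure(
    list(kc0 = kc0, xc = xc, ks0 = ks0, xs = xs, kBT = kBT,
         ci95 = ci95, F_crit = NA_real_),
    class = "bell_params"
  )
  p$F_crit <- tryCatch(critical_force(p), error = function(e) NA_real_)
  p
}

#' @export
print.bell_params <- function(x, ...) {
  fmt <- function(name, val, unit) {
    ci <- if (!is.null(x$ci95) && !is.null(x$ci95[[name]])) {
      sprintf(" +/- %.2g", x$ci95[[name]])
    } else ""
    sprintf("  %-4s = %.3g%s %s\n", name, val, ci, unit)
  }
  cat("Catch-slip Bell model\n")
  cat(fmt("kc0", x$kc0, "1/s"))
  cat(fmt("xc", x$xc, "nm"))
  cat(fmt("ks0", x$ks0, "1/s"))
  cat(fmt("xs", x$xs, "nm"))
  if (!is.na(x$F_crit)) {
    cat(sprintf("  critical force = %.2f pN (kBT = %g pN nm)\n",
                x$F_crit, x$kBT))
  }
  invisible(x)
}

#' Mean bond lifetime under the catch-slip Bell model
#'
#' @param F Force on the bond, pN (vectorized, >= 0).
#' @param params A [bell_params()] object.
#' @return Mean lifetime in s.
#' @export
catch_slip_lifetime <- function(F, params) {
  stopifnot(inherits(params, "bell_params"), is.numeric(F), all(F >= 0))
  1 / (params$kc0 * exp(F * params$xc / params$kBT) +
         params$ks0 * exp(F * params$xs / params$kBT))
}

#' Critical force of a catch-slip bond
#'
#' The force at which the mean bond lifetime is maximal, in closed form:
#' \deqn{F^* = \frac{k_BT}{x_s - x_c}
#'       \ln\!\left(\frac{-k_{c0} x_c}{k_{s0} x_s}\right)}
#' An interior maximum exists only when the log argument is positive and
#' the resulting force is positive.
#'
#' @param params A [bell_params()] object.
#' @return Critical force in pN.
#' @export
critical_force <- function(params) {
  stopifnot(inherits(params, "bell_params"))
  arg <- -params$kc0 * params$xc / (params$ks0 * params$xs)
  if (arg <= 0) {
    stop(structure(
      class = c("forcejump_no_interior_maximum", "error", "condition"),
      list(message = "no interior lifetime maximum for these parameters",
           call = sys.call(-1))
    ))
  }
  f <- params$kBT * log(arg) / (params$xs - params$xc)
  if (f <= 0) {
    stop(structure(
      class = c("forcejump_no_interior_maximum", "error", "condition"),
      list(message = "lifetime maximum lies at zero force (pure slip behavior)",
           call = sys.call(-1))
    ))
  }
  f
}

#' Fit the catch-slip Bell model to mean lifetime versus load
#'
#' Weighted nonlinear least squares of mean bond lifetime against protein
#' load, with weights `1/SEM^2`. Because dwell times are exponential
#' under the model, the SEM used for weighting is floored at the
#' model-implied value `mean/sqrt(n)`: the empirical SEM of a group with
#' very few events can be arbitrarily small by chance and would otherwise
#' dominate the fit (single-event groups thereby get their model SEM,
#' i.e. their mean). Sign constraints (`xc < 0 < xs`) fix the pathway
#' identities, and a multi-start grid over the distance parameters avoids
#' the label-swap local minimum. 95% confidence intervals come from the
#' linearized covariance of the best fit.
#'
#' @param groups data.frame from [group_and_summarize()] (needs columns
#'   `F_Load_pN`, `mean_tau_s`, `sem_tau_s`).
#' @param kBT Thermal energy, pN nm.
#' @param multistart Number of starting points along each distance
#'   parameter axis (default 4; total starts = `multistart^2`).
#' @param truncation_s Shortest observable dwell of the upstream
#'   detector, s (default 0). Dissociation is memoryless, so discarding
#'   dwells shorter than `c` inflates every observed group mean by
#'   exactly `c`; the fit then uses the observation model
#'   `mean_obs(F) = c + tau_model(F)`, removing the truncation bias
#'   without touching the group summaries. Pass
#'   `(skip_initial_samples + min_pre_samples) / sampling_rate`.
#'
#' @return A [bell_params()] object with `ci95` filled in, plus
#'   attributes `rss`, `n_groups`, `fit` (the underlying `nls` object).
#' @export
fit_catch_slip <- function(groups, kBT = 4.09, multistart = 4,
                           truncation_s = 0) {
  stopifnot(is.data.frame(groups),
            all(c("F_Load_pN", "mean_tau_s") %in% names(groups)),
            truncation_s >= 0)
  g <- groups[order(groups$F_Load_pN), , drop = FALSE]
  if (length(unique(g$F_Load_pN)) < 4) {
    stop("need at least 4 distinct force levels to fit the catch-slip model",
         call. = FALSE)
  }
  F <- g$F_Load_pN
  tau <- g$mean_tau_s
  n_ev <- if ("n_events" %in% names(g)) g$n_events else rep(1, length(tau))
  sem <- if ("sem_tau_s" %in% names(g)) g$sem_tau_s else rep(0, length(tau))
  sem[is.na(sem)] <- 0
  sem_w <- pmax(sem, tau / sqrt(n_ev))
  w <- 1 / sem_w^2

  trunc_c <- truncation_s
  # strictly monotone mean lifetimes carry no information about one of
  # the two pathways; a noisy chevron is practically never strictly
  # monotone, so this only rejects genuinely one-branch data
  if (all(diff(tau) < 0)) {
    stop(structure(
      class = c("forcejump_degenerate_fit", "error", "condition"),
      list(message = paste(
        "lifetimes decrease monotonically with load:",
        "no rising branch, catch pathway unidentifiable"),
        call = sys.call(-1))
    ))
  }
  if (all(diff(tau) > 0)) {
    stop(structure(
      class = c("forcejump_degenerate_fit", "error", "condition"),
      list(message = paste(
        "lifetimes increase monotonically with load:",
        "no falling branch, slip pathway unidentifiable"),
        call = sys.call(-1))
    ))
  }

  xc_grid <- -exp(seq(log(0.5), log(8), length.out = multistart))
  xs_grid <- exp(seq(log(0.5), log(8), length.out = multistart))
  rate_lo <- 1 / tau[1]
  rate_hi <- 1 / tau[length(tau)]
  F_lo <- F[1]
  F_hi <- F[length(F)]

  best <- NULL
  best_rss <- Inf
  for (xc0 in xc_grid) {
    for (xs0 in xs_grid) {
      # initialize the rate prefactors from the endpoint off-rates,
      # where one pathway dominates
      kc0_0 <- max(rate_lo * exp(-F_lo * xc0 / kBT) / 2, 1e-6)
      ks0_0 <- max(rate_hi * exp(-F_hi * xs0 / kBT) / 2, 1e-8)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          tau ~ trunc_c +
            1 / (kc0 * exp(F * xc / kBT) + ks0 * exp(F * xs / kBT)),
          start = list(kc0 = kc0_0, xc = xc0, ks0 = ks0_0, xs = xs0),
          lower = c(kc0 = 1e-10, xc = -20, ks0 = 1e-12, xs = 1e-4),
          upper = c(kc0 = 1e6, xc = -1e-4, ks0 = 1e6, xs = 20),
          weights = w,
          control = minpack.lm::nls.lm.control(maxiter = 300)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2 * w)
      if (rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  if (is.null(best)) {
    stop("catch-slip fit failed to converge from any starting point",
         call. = FALSE)
  }
  co <- stats::coef(best)
  se <- tryCatch(sqrt(diag(stats::vcov(best))), error = function(e) {
    stats::setNames(rep(NA_real_, 4), names(co))
  })
  tq <- stats::qt(0.975, df = max(length(tau) - 4, 1))
  ci <- as.list(tq * se)
  params <- bell_params(
    kc0 = unname(co["kc0"]), xc = unname(co["xc"]),
    ks0 = unname(co["ks0"]), xs = unname(co["xs"]),
    kBT = kBT, ci95 = ci
  )
  attr(params, "rss") <- best_rss
  attr(params, "n_groups") <- length(tau)
  attr(params, "fit") <- best
  params
}

#' Fit a single-site binding isotherm
#'
#' Nonlinear least squares of the hyperbolic binding isotherm
#' `Y = Ymax * [S] / (KD + [S])` to a titration, as used for
#' thermophoresis dose-response data.
#'
#' @param conc Ligand concentrations, uM (>= 5 values spanning at least
#'   one decade).
#' @param response Response at each concentration (e.g. the magnitude of
#'   the normalized fluorescence change).
#'
#' @return A list of class `"isotherm_fit"`: `KD` (uM), `Ymax`, `ci95`
#'   (named list of 95% half-widths), `fitted`, `residuals`.
#' @export
fit_binding_isotherm <- function(conc, response) {
  stopifnot(is.numeric(conc), is.numeric(response),
            length(conc) == length(response))
  if (length(unique(conc)) < 5) {
    stop("need at least 5 distinct concentrations", call. = FALSE)
  }
  if (max(conc) / max(min(conc[conc > 0]), .Machine$double.eps) < 10) {
    stop("titration must span at least one decade of concentration",
         call. = FALSE)
  }
  ymax0 <- max(response)
  kd0 <- conc[which.min(abs(response - ymax0 / 2))]
  if (kd0 <= 0) kd0 <- stats::median(conc)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ Ymax * conc / (KD + conc),
      start = list(Ymax = ymax0, KD = kd0),
      lower = c(Ymax = 0, KD = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  unident <- function(msg) {
    stop(structure(
      class = c("forcejump_unidentifiable_kd", "error", "condition"),
      list(message = msg, call = sys.call(-2))
    ))
  }
  if (is.null(fit)) unident("isotherm fit failed to converge")
  co <- stats::coef(fit)
  if (co["KD"] > 50 * max(conc)) {
    unident("no saturation within the titration range: KD unidentifiable")
  }
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    stats::setNames(rep(NA_real_, 2), names(co))
  })
  tq <- stats::qt(0.975, df = max(length(conc) - 2, 1))
  structure(
    list(
      KD = unname(co["KD"]), Ymax = unname(co["Ymax"]),
      ci95 = list(KD = unname(tq * se["KD"]), Ymax = unname(tq * se["Ymax"])),
      fitted = stats::fitted(fit), residuals = stats::residuals(fit)
    ),
    class = "isotherm_fit"
  )
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("Binding isotherm fit: KD = %.3g +/- %.2g uM, Ymax = %.3g +/- %.2g\n",
              x$KD, x$ci95$KD, x$Ymax, x$ci95$Ymax))
  invisible(x)
}
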