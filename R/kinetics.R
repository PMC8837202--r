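#' Empirical survival curve of bond lifetimes
#'
#' The survival probability is one minus the empirical cumulative
#' distribution of the lifetimes, evaluated at each sorted lifetime. For
#' semilog plotting a copy is provided in which the final point is moved
#' from 0 to 0.01; fits must use the unadjusted values.
#'
#' @param lifetimes Numeric vector of bond lifetimes, s (>= 1 value).
#'
#' @return A list of class `"survival_curve"`: `time` (sorted lifetimes),
#'   `survival` (1 - ECDF at those times), `survival_plot` (same with the
#'   terminal 0 replaced by 0.01), `n`.
#' @export
survival_curve <- function(lifetimes) {
  stopifnot(is.numeric(lifetimes))
  if (length(lifetimes) < 1) stop("need at least one lifetime", call. = FALSE)
  t <- sort(lifetimes)
  n <- length(t)
  s <- 1 - stats::ecdf(t)(t)
  s_plot <- s
  s_plot[s_plot == 0] <- 0.01
  structure(list(time = t, survival = s, survival_plot = s_plot, n = n),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: %d lifetimes, range [%.3g, %.3g] s\n",
              x$n, min(x$time), max(x$time)))
  invisible(x)
}

#' Single-exponential fit to a survival curve
#'
#' Nonlinear least squares of `S = A * exp(b * t)` (free amplitude,
#' `b < 0` for decaying data) on the unadjusted survival points at the
#' observed lifetimes, unweighted. Residuals are returned so that
#' single- versus multi-exponential adequacy can be judged (systematic
#' sign runs in the residuals indicate a lifetime mixture).
#'
#' @param curve A [survival_curve()].
#'
#' @return A list of class `"exp_fit"`: `A`, `b` (1/s), `residuals`,
#'   `fitted`, `rss`, `converged`.
#' @export
fit_exponential_survival <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  t <- curve$time
  s <- curve$survival
  if (length(unique(t)) < 3) {
    stop("need at least 3 distinct lifetimes to fit", call. = FALSE)
  }
  b0 <- -1 / mean(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      s ~ A * exp(b * t),
      start = list(A = 1, b = b0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(A = NA_real_, b = NA_real_, residuals = NULL, fitted = NULL,
           rss = NA_real_, converged = FALSE,
           message = conditionMessage(fit)),
      class = "exp_fit"
    ))
  }
  co <- stats::coef(fit)
  structure(
    list(A = unname(co["A"]), b = unname(co["b"]),
         residuals = s - stats::fitted(fit), fitted = stats::fitted(fit),
         rss = sum(stats::residuals(fit)^2), converged = TRUE),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Single-exponential survival fit: did not converge\n")
  } else {
    cat(sprintf(
      "Single-exponential survival fit: S = %.3f * exp(%.3f t)  (tau = %.3f s)\n",
      x$A, x$b, -1 / x$b
    ))
  }
  invisible(x)
}

#' Group events and summarize lifetimes
#'
#' Pools events by construct and nominal plateau force (axis
#' `"F_Tot"`), or by protein load (axis `"F_Load"`), where lifetimes
#' measured on the two bridge constructs at the same trap force sample
#' different loads and may be pooled on the common load axis. For each
#' group the mean lifetime, its standard error, the number of events and
#' molecules, and the off-rate (inverse mean lifetime) are reported.
#'
#' @param events Event data.frame from [detect_events()] (columns
#'   `construct`, `F_Tot_pN`, `F_Load_pN`, `tau_s`, `molecule_id`).
#' @param axis `"F_Tot"` (separate constructs) or `"F_Load"` (constructs
#'   pooled on the load axis).
#' @param digits Forces are rounded to this many digits to form group
#'   keys (default 3).
#' @return A data.frame with one row per group: `construct` (`NA` when
#'   pooling on `F_Load`), `F_Tot_pN` (`NA` likewise), `F_Load_pN`,
#'   `n_events`, `n_molecules`, `mean_tau_s`, `sem_tau_s`,
#'   `off_rate_per_s`, `single_event` (flag: SEM reported as 0 by
#'   convention).
#' @export
group_and_summarize <- function(events, axis = c("F_Load", "F_Tot"),
                                digits = 3) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(events), nrow(events) >= 1)
  key <- if (axis == "F_Tot") {
    interaction(events$construct, round(events$F_Tot_pN, digits), drop = TRUE)
  } else {
    factor(round(events$F_Load_pN, digits))
  }
  groups <- split(seq_len(nrow(events)), key)
  rows <- lapply(groups, function(idx) {
    ev <- events[idx, , drop = FALSE]
    n <- nrow(ev)
    m <- mean(ev$tau_s)
    sem <- if (n > 1) stats::sd(ev$tau_s) / sqrt(n) else 0
    data.frame(
      construct = if (axis == "F_Tot") ev$construct[1] else NA_integer_,
      F_Tot_pN = if (axis == "F_Tot") ev$F_Tot_pN[1] else NA_real_,
      F_Load_pN = mean(ev$F_Load_pN),
      n_events = n,
      n_molecules = length(unique(ev$molecule_id)),
      mean_tau_s = m,
      sem_tau_s = sem,
      off_rate_per_s = 1 / m,
      single_event = n == 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$F_Load_pN), , drop = FALSE]
  rownames(out) <- NULL
  out
}
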