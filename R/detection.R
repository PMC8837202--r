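#' Detection configuration
#'
#' Tunable parameters of the plateau-level event detector.
#'
#' @param boxcar_width Sliding-window width, in samples, for the
#'   effective-noise estimate (default 10).
#' @param p_trans Per-sample bound-to-unbound transition probability of
#'   the one-way two-state hidden Markov model (default 1e-3). For
#'   well-separated states this sets the detection threshold, not the
#'   changepoint location.
#' @param mu_sep_esd Separation of the two emission centers, in units of
#'   the effective noise SD (default 4).
#' @param min_pre_samples Minimum number of bound samples for an event to
#'   be accepted (default 4).
#' @param min_post_samples Minimum number of unbound samples after the
#'   changepoint (default 4, symmetric with `min_pre_samples`): a step
#'   placed in the last few samples of a plateau rests on too few points
#'   for the level change to be estimated.
#' @param drift_slope_esd_per_s Post-rupture slope, in eSD per second,
#'   above which the drift screen triggers, provided the slope is also
#'   statistically resolvable at 3 standard errors (default 0.5).
#' @param drift_window_samples Half-width, in samples, of the window kept
#'   around the changepoint when the drift screen triggers (default 100).
#' @param max_transition_span Maximum number of consecutive samples
#'   allowed in the band between the two fitted levels at the transition;
#'   more indicates a gradual change (drift), not an instantaneous
#'   rupture, and the event is rejected (default 3).
#' @param skip_initial_samples Samples dropped from the start of each
#'   plateau before analysis, so that the instrument settling transient
#'   after the force jump (response time ~5-10 ms) does not contaminate
#'   the centering baseline (default 5, i.e. 25 ms at 200 Hz). The bond
#'   lifetime is still measured from the jump: the skipped duration is
#'   added back to the decoded bound stretch.
#' @param min_step_esd Minimum instantaneous level change at the
#'   changepoint, in eSD units, measured between short windows (5
#'   samples) immediately before and after the transition (default 2,
#'   half the emitter separation). Slow drift that crosses the decoding
#'   threshold produces no local step and is rejected by this screen;
#'   a genuine rupture changes the level within the instrument response
#'   time.
#'
#' @return A list of class `"detection_config"`.
#' @export
detection_config <- function(boxcar_width = 10, p_trans = 1e-3,
                             mu_sep_esd = 4, min_pre_samples = 4,
                             min_post_samples = 4,
                             drift_slope_esd_per_s = 0.5,
                             drift_window_samples = 100,
                             max_transition_span = 3,
                             skip_initial_samples = 5,
                             min_step_esd = 2) {
  stopifnot(
    boxcar_width >= 2, p_trans > 0, p_trans < 1, mu_sep_esd > 0,
    min_pre_samples >= 1, min_post_samples >= 1,
    drift_slope_esd_per_s > 0,
    drift_window_samples > 0, max_transition_span >= 1,
    skip_initial_samples >= 0, min_step_esd >= 0
  )
  structure(
    list(
      boxcar_width = as.integer(boxcar_width), p_trans = p_trans,
      mu_sep_esd = mu_sep_esd,
      min_pre_samples = as.integer(min_pre_samples),
      min_post_samples = as.integer(min_post_samples),
      drift_slope_esd_per_s = drift_slope_esd_per_s,
      drift_window_samples = as.integer(drift_window_samples),
      max_transition_span = as.integer(max_transition_span),
      skip_initial_samples = as.integer(skip_initial_samples),
      min_step_esd = min_step_esd
    ),
    class = "detection_config"
  )
}

#' Center a plateau segment
#'
#' Subtracts the mean of the first five samples from the whole segment,
#' placing the bound level near zero so that the emission model (centers
#' at 0 and a fixed multiple of the noise SD) applies.
#'
#' @param segment Numeric position series (>= 5 samples).
#' @return The centered series.
#' @export
center_plateau <- function(segment) {
  stopifnot(is.numeric(segment))
  if (length(segment) < 5) {
    stop("segment must have at least 5 samples to center", call. = FALSE)
  }
  segment - mean(segment[1:5])
}

#' Effective noise SD of a segment
#'
#' The median over all sliding windows (default width 10 samples) of the
#' within-window sample standard deviation. The median makes the estimate
#' robust to a single level change within the segment.
#'
#' @param segment Numeric series, length >= `width`.
#' @param width Window width in samples.
#' @return A list of class `"noise_estimate"`: `eSD` (same units as the
#'   segment) and `boxcar_width`.
#' @export
estimate_noise <- function(segment, width = 10) {
  stopifnot(is.numeric(segment), width >= 2)
  n <- length(segment)
  if (n < width) {
    stop("segment shorter than the boxcar width", call. = FALSE)
  }
  # rolling sd via cumulative sums
  s1 <- cumsum(c(0, segment))
  s2 <- cumsum(c(0, segment^2))
  i <- seq_len(n - width + 1L)
  win_sum <- s1[i + width] - s1[i]
  win_sq <- s2[i + width] - s2[i]
  v <- (win_sq - win_sum^2 / width) / (width - 1)
  esd <- stats::median(sqrt(pmax(v, 0)))
  structure(list(eSD = esd, boxcar_width = as.integer(width)),
            class = "noise_estimate")
}

#' Viterbi decoding of a one-way two-state plateau
#'
#' Decodes the maximum-likelihood state path of a hidden Markov model with
#' two Gaussian emitters — bound at 0 and unbound at `mu_sep_esd * eSD`,
#' both with SD one eSD — whose transition matrix allows only the
#' bound-to-unbound transition (the unbound state is absorbing) and whose
#' initial state is bound. With this structure the decoded path has at
#' most one changepoint.
#'
#' @param segment Centered position series.
#' @param noise A `"noise_estimate"` (or a positive scalar eSD).
#' @param p_trans Per-sample transition probability.
#' @param mu_sep_esd Emission-center separation in eSD units.
#'
#' @return A list of class `"state_path"`: `states` (integer vector, 1 =
#'   bound, 2 = unbound), `changepoint` (number of bound samples before
#'   the transition, or `NA` if no transition), `first_unbound` (index of
#'   the first unbound sample, or `NA`), `loglik`.
#' @export
viterbi_decode <- function(segment, noise, p_trans = 1e-3, mu_sep_esd = 4) {
  esd <- if (inherits(noise, "noise_estimate")) noise$eSD else noise
  stopifnot(is.numeric(segment), length(segment) >= 1,
            is.numeric(p_trans), p_trans > 0, p_trans < 1)
  if (!is.numeric(esd) || esd <= 0) {
    stop("degenerate emission model: eSD must be > 0", call. = FALSE)
  }
  n <- length(segment)
  em1 <- stats::dnorm(segment, 0, esd, log = TRUE)
  em2 <- stats::dnorm(segment, mu_sep_esd * esd, esd, log = TRUE)
  la_stay <- log1p(-p_trans)
  la_switch <- log(p_trans)

  # forward pass; state 2 is absorbing so only its backpointer matters
  d1 <- numeric(n)
  d2 <- numeric(n)
  switched_at <- logical(n)
  d1[1] <- em1[1]
  d2[1] <- -Inf # initial state is bound
  if (n > 1) {
    for (t in 2:n) {
      d1[t] <- d1[t - 1] + la_stay + em1[t]
      from1 <- d1[t - 1] + la_switch
      if (from1 > d2[t - 1]) {
        d2[t] <- from1 + em2[t]
        switched_at[t] <- TRUE
      } else {
        d2[t] <- d2[t - 1] + em2[t]
      }
    }
  }

  if (d2[n] > d1[n]) {
    states <- rep.int(1L, n)
    # backtrack: walk the absorbing state back to its entry point
    t <- n
    while (t > 1 && !switched_at[t]) t <- t - 1L
    t <- as.integer(t)
    states[t:n] <- 2L
    structure(
      list(states = states, changepoint = t - 1L,
           first_unbound = t, loglik = d2[n]),
      class = "state_path"
    )
  } else {
    structure(
      list(states = rep.int(1L, n), changepoint = NA_integer_,
           first_unbound = NA_integer_, loglik = d1[n]),
      class = "state_path"
    )
  }
}

#' Extract a binding event from a decoded plateau
#'
#' The bond lifetime is the duration of the bound stretch preceding the
#' state change; the step size is the difference in means between an
#' equal number of samples immediately before and after the changepoint
#' (the count set by the binding duration, limited by availability).
#' Events with fewer than `min_pre_samples` bound samples, or with no
#' post-change sample, are rejected.
#'
#' @param segment The (possibly centered) position series that was decoded.
#' @param path A `"state_path"` from [viterbi_decode()].
#' @param sampling_rate Sampling rate, Hz.
#' @param min_pre_samples Minimum bound samples to accept (default 4).
#'
#' @return A list with `accepted` (logical); when accepted: `tau` (s),
#'   `delta_x` (same units as the segment), `n_pre_samples`; when
#'   rejected: `reason`.
#' @export
extract_event <- function(segment, path, sampling_rate = 200,
                          min_pre_samples = 4) {
  stopifnot(inherits(path, "state_path"))
  if (is.na(path$changepoint)) {
    return(list(accepted = FALSE, reason = "no_changepoint"))
  }
  n_pre <- path$changepoint
  n <- length(segment)
  if (n_pre < min_pre_samples) {
    return(list(accepted = FALSE, reason = "too_few_pre_samples"))
  }
  n_post_avail <- n - n_pre
  if (n_post_avail < 1) {
    return(list(accepted = FALSE, reason = "no_post_samples"))
  }
  n_use <- min(n_pre, n_post_avail)
  pre <- segment[(n_pre - n_use + 1L):n_pre]
  post <- segment[(n_pre + 1L):(n_pre + n_use)]
  list(
    accepted = TRUE,
    tau = n_pre / sampling_rate,
    delta_x = mean(post) - mean(pre),
    n_pre_samples = n_pre
  )
}

# slope (units/s) and its standard error of a least-squares line fit
post_slope <- function(y, sampling_rate) {
  m <- length(y)
  if (m < 3) return(c(slope = 0, se = Inf))
  t <- seq_len(m) / sampling_rate
  fit <- stats::lm.fit(cbind(1, t), y)
  rss <- sum(fit$residuals^2)
  se <- sqrt(rss / (m - 2) / sum((t - mean(t))^2))
  c(slope = unname(fit$coefficients[2]), se = se)
}

#' Truncate a plateau around its changepoint when drift is present
#'
#' Slow stage drift inflates the apparent step size when the level means
#' are taken over long stretches. The screen fits a line to the
#' post-change samples; when the slope magnitude exceeds
#' `drift_slope_esd_per_s * eSD` per second and is statistically
#' resolvable (|slope| > 3 standard errors), the segment is cut down to a
#' window of `drift_window_samples` on each side of the changepoint. The
#' changepoint itself always stays inside the window.
#'
#' @param segment Centered position series.
#' @param path A `"state_path"` with a changepoint.
#' @param noise A `"noise_estimate"` for the segment.
#' @param sampling_rate Sampling rate, Hz.
#' @param config A [detection_config()].
#'
#' @return A list: `segment` (possibly truncated), `offset` (samples
#'   removed before the window start; 0 if untouched), `truncated`
#'   (logical), `slope` (fitted post-change slope, units/s).
#' @export
truncate_for_drift <- function(segment, path, noise, sampling_rate = 200,
                               config = detection_config()) {
  stopifnot(inherits(path, "state_path"))
  if (is.na(path$changepoint)) {
    return(list(segment = segment, offset = 0L, truncated = FALSE,
                slope = 0))
  }
  n <- length(segment)
  cp <- path$changepoint
  post <- segment[(cp + 1L):n]
  sl <- post_slope(post, sampling_rate)
  trigger <- abs(sl["slope"]) > config$drift_slope_esd_per_s * noise$eSD &&
    abs(sl["slope"]) > 3 * sl["se"]
  if (!trigger) {
    return(list(segment = segment, offset = 0L, truncated = FALSE,
                slope = unname(sl["slope"])))
  }
  w <- config$drift_window_samples
  lo <- max(1L, cp - w + 1L)
  hi <- min(n, cp + w)
  list(segment = segment[lo:hi], offset = lo - 1L, truncated = TRUE,
       slope = unname(sl["slope"]))
}

# level change between short windows flanking the changepoint; the
# first post sample is excluded when possible since it lies mid-response
local_step <- function(segment, cp, w = 5L) {
  n <- length(segment)
  pre <- segment[max(1L, cp - w + 1L):cp]
  post_from <- if (n - cp >= 2L) cp + 2L else cp + 1L
  post <- segment[post_from:min(n, post_from + w - 1L)]
  mean(post) - mean(pre)
}

# number of consecutive samples sitting between the two level bands at
# the transition; an instantaneous rupture crosses in <= a few samples
transition_span <- function(segment, cp, delta_x) {
  if (delta_x <= 0) return(0L)
  pre_lvl <- mean(segment[max(1, cp - 19):cp])
  lo <- pre_lvl + 0.25 * delta_x
  hi <- pre_lvl + 0.75 * delta_x
  span <- 0L
  i <- cp
  while (i >= 1 && segment[i] > lo && segment[i] < hi) {
    span <- span + 1L
    i <- i - 1L
  }
  i <- cp + 1L
  n <- length(segment)
  while (i <= n && segment[i] > lo && segment[i] < hi) {
    span <- span + 1L
    i <- i + 1L
  }
  span
}

#' Detect binding events in a force-jump trace
#'
#' Runs the full per-plateau analysis over every high-force plateau of a
#' trace: center on the first five samples, estimate the effective noise
#' SD, Viterbi-decode the one-way two-state model, screen for drift
#' (re-estimating the step in a truncated window when it triggers), and
#' apply the acceptance filters (minimum bound samples, at least one
#' post-change sample, near-instantaneous transition). Accepted events
#' are annotated with the protein load `F_Load` from the mechanical
#' circuit model.
#'
#' @param trace A [trace_record()].
#' @param geom A [tether_geometry()] matching the trace's construct.
#' @param config A [detection_config()].
#'
#' @return A data.frame of accepted events with columns `molecule_id`,
#'   `construct`, `plateau_id`, `F_Tot_pN`, `F_Load_pN`, `tau_s`,
#'   `delta_x_nm`, `n_pre_samples`, `flags`. Zero rows when nothing is
#'   detected.
#' @export
detect_events <- function(trace, geom, config = detection_config()) {
  stopifnot(inherits(trace, "trace_record"),
            inherits(geom, "tether_geometry"),
            inherits(config, "detection_config"))
  if (trace$construct != geom$bridge_nt) {
    stop(sprintf("trace construct (%s nt) does not match geometry (%s nt)",
                 trace$construct, geom$bridge_nt), call. = FALSE)
  }
  hp <- high_plateaus(trace)
  fload <- vapply(unique(hp$F_Tot), function(f) {
    solve_bound_state(f, geom)$F_Load
  }, numeric(1))
  names(fload) <- as.character(unique(hp$F_Tot))

  skip <- config$skip_initial_samples
  out <- vector("list", nrow(hp))
  for (i in seq_len(nrow(hp))) {
    if (hp$start[i] + skip > hp$end[i]) next
    seg_raw <- trace$data$position_nm[(hp$start[i] + skip):hp$end[i]]
    if (length(seg_raw) < max(5L, config$boxcar_width)) next
    seg <- center_plateau(seg_raw)
    noise <- estimate_noise(seg, config$boxcar_width)
    # a noiseless synthetic plateau has eSD 0; floor it so decoding
    # remains defined (relative location of the changepoint is unaffected)
    if (noise$eSD <= 0) noise$eSD <- 1e-9
    path <- viterbi_decode(seg, noise, config$p_trans, config$mu_sep_esd)
    if (is.na(path$changepoint)) next
    if (length(seg) - path$changepoint < config$min_post_samples) next

    flags <- character(0)
    tr <- truncate_for_drift(seg, path, noise, trace$sampling_rate, config)
    work <- seg
    work_path <- path
    if (tr$truncated) {
      flags <- c(flags, "drift_truncated")
      work <- tr$segment
      cp_local <- path$changepoint - tr$offset
      work_path <- structure(
        list(states = c(rep.int(1L, cp_local),
                        rep.int(2L, length(work) - cp_local)),
             changepoint = cp_local, first_unbound = cp_local + 1L,
             loglik = NA_real_),
        class = "state_path"
      )
    }
    # lifetime is measured from the force jump: decoded bound samples
    # plus the skipped settling window
    ev <- extract_event(work, work_path, trace$sampling_rate,
                        config$min_pre_samples)
    n_pre_full <- path$changepoint
    if (n_pre_full < config$min_pre_samples) next
    if (!isTRUE(ev$accepted)) next
    if (ev$delta_x < config$min_step_esd * noise$eSD) next
    if (local_step(work, work_path$changepoint) <
        config$min_step_esd * noise$eSD) next
    span <- transition_span(work, work_path$changepoint, ev$delta_x)
    if (span > config$max_transition_span) next

    out[[i]] <- data.frame(
      molecule_id = trace$molecule_id,
      construct = trace$construct,
      plateau_id = hp$plateau_id[i],
      F_Tot_pN = hp$F_Tot[i],
      F_Load_pN = unname(fload[as.character(hp$F_Tot[i])]),
      tau_s = (skip + n_pre_full) / trace$sampling_rate,
      delta_x_nm = ev$delta_x,
      n_pre_samples = n_pre_full,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(
      molecule_id = character(0), construct = integer(0),
      plateau_id = integer(0), F_Tot_pN = numeric(0),
      F_Load_pN = numeric(0), tau_s = numeric(0), delta_x_nm = numeric(0),
      n_pre_samples = integer(0), flags = character(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}
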