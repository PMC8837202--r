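# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately written from first principles (plain
# formulas, brute-force search) so it cannot share a bug with the
# package implementations it checks.

# plain WLC interpolation formula, written independently of wlc_force()
oracle_wlc <- function(x, Lp, Lc, kBT) {
  if (x < 0) return(0)
  r <- x / Lc
  kBT / Lp * (1 / (4 * (1 - r)^2) - 0.25 + r)
}

# bound-state loading extension by plain bisection on the summed
# force-extension curve (monotone), to an x-tolerance of 1e-12 nm
oracle_bound_x <- function(F_Tot, geom) {
  total <- function(x) {
    oracle_wlc(x + geom$L_prot, geom$persistence_length, geom$Lc_bridge,
               geom$kBT) +
      oracle_wlc(x, geom$persistence_length, geom$Lc_loading, geom$kBT)
  }
  lo <- 0
  hi <- min(geom$Lc_loading, geom$Lc_bridge - geom$L_prot) * 0.999
  if (total(lo) >= F_Tot) return(NA_real_) # slack loading strand
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (total(mid) < F_Tot) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# bridge-only extension by bisection
oracle_unbound_x <- function(F_Tot, geom) {
  if (F_Tot == 0) return(-geom$L_prot)
  f <- function(x) oracle_wlc(x, geom$persistence_length, geom$Lc_bridge,
                              geom$kBT)
  lo <- 0
  hi <- geom$Lc_bridge * (1 - 1e-9)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) < F_Tot) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 - geom$L_prot
}

# exhaustive single-changepoint maximum-likelihood scan: the one-way
# two-state chain admits exactly one transition, so Viterbi decoding
# must agree with brute force over every candidate changepoint
oracle_changepoint <- function(segment, esd, p_trans = 1e-3,
                               mu_sep_esd = 4) {
  n <- length(segment)
  em1 <- dnorm(segment, 0, esd, log = TRUE)
  em2 <- dnorm(segment, mu_sep_esd * esd, esd, log = TRUE)
  ll_null <- sum(em1) + (n - 1) * log1p(-p_trans)
  c1 <- cumsum(em1)
  c2 <- rev(cumsum(rev(em2)))
  # changepoint after sample k: k bound samples, then n - k unbound
  k <- seq_len(n - 1)
  ll_k <- c1[k] + (k - 1) * log1p(-p_trans) + log(p_trans) + c2[k + 1]
  if (max(ll_k) > ll_null) which.max(ll_k) else NA_integer_
}

# seeded random plateau: pure noise or noise plus one step, returns the
# segment along with the generating truth
random_plateau <- function(n = 400, esd = 1, p_step = 0.6,
                           step_range = c(2.5, 6)) {
  has_step <- runif(1) < p_step
  x <- rnorm(n, 0, esd)
  k <- NA_integer_
  if (has_step) {
    k <- sample(seq(10, n - 10), 1)
    h <- runif(1, step_range[1], step_range[2]) * esd
    x[(k + 1):n] <- x[(k + 1):n] + h
  }
  list(segment = x, true_k = k)
}

rsa4_truth <- function() bell_params(kc0 = 5.3, xc = -2.0, ks0 = 0.01,
                                     xs = 4.1)

geom55 <- function() tether_geometry(55)
geom70 <- function() tether_geometry(70)
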