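#' Simulation configuration for synthetic force-jump sessions
#'
#' Defines the study conditions emulated by the generator: force-jump
#' cycles alternating a 0.5 pN binding-permissive plateau with a 4-12 pN
#' loading plateau, 200 Hz sampling, Gaussian position noise, optional
#' per-molecule linear drift, a single-pole instrument response, and bond
#' lifetimes drawn from the catch-slip Bell law at the load given by the
#' mechanical circuit.
#'
#' @param bell Ground-truth [bell_params()].
#' @param constructs Bridge lengths to simulate, nt (default `c(55, 70)`).
#' @param n_molecules Molecules per construct (default 5).
#' @param cycles_per_molecule Low/high force-jump cycles per molecule
#'   (default 60; forces cycle round-robin through `high_forces`).
#' @param sampling_rate Hz (default 200).
#' @param low_force Low plateau force, pN (default 0.5).
#' @param high_forces High plateau forces, pN (default `c(4, 6, 8, 10, 12)`).
#' @param plateau_s Plateau duration, s (default 5; must be >= 5).
#' @param p_bind Probability that a bond has formed by the time of each
#'   jump to high force (default 0.3).
#' @param noise_sd Position noise SD, nm (default 1).
#' @param drift_sd Per-molecule drift rate SD, nm/s (default 0.5; each
#'   molecule gets one rate drawn from `N(0, drift_sd^2)`).
#' @param response_time_s Single-pole instrument response time constant,
#'   s (default 0.0075).
#' @param geom_args Extra arguments passed to [tether_geometry()]
#'   (besides `bridge_nt` and `kBT`, which come from `constructs` and
#'   `bell`).
#'
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(bell,
                              constructs = c(55, 70),
                              n_molecules = 5,
                              cycles_per_molecule = 60,
                              sampling_rate = 200,
                              low_force = 0.5,
                              high_forces = c(4, 6, 8, 10, 12),
                              plateau_s = 5,
                              p_bind = 0.3,
                              noise_sd = 1,
                              drift_sd = 0.5,
                              response_time_s = 0.0075,
                              geom_args = list()) {
  stopifnot(
    inherits(bell, "bell_params"),
    all(constructs > 0), n_molecules >= 1, cycles_per_molecule >= 1,
    sampling_rate > 0, low_force >= 0, all(high_forces > low_force),
    plateau_s >= 5, p_bind >= 0, p_bind <= 1, noise_sd >= 0,
    drift_sd >= 0, response_time_s >= 0
  )
  geoms <- lapply(constructs, function(nt) {
    do.call(tether_geometry,
            c(list(bridge_nt = nt, kBT = bell$kBT), geom_args))
  })
  names(geoms) <- as.character(constructs)
  structure(
    list(
      bell = bell, constructs = constructs, geoms = geoms,
      n_molecules = n_molecules,
      cycles_per_molecule = cycles_per_molecule,
      sampling_rate = sampling_rate, low_force = low_force,
      high_forces = high_forces, plateau_s = plateau_s,
      p_bind = p_bind, noise_sd = noise_sd, drift_sd = drift_sd,
      response_time_s = response_time_s
    ),
    class = "simulation_config"
  )
}

# single-pole low-pass with time constant tc (s); y[1] = x[1]
lowpass <- function(x, tc, dt) {
  if (tc <= 0) return(x)
  a <- exp(-dt / tc)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                           init = x[1] / 1))
}

#' Simulate one force-jump session
#'
#' Generates the position/force trace of one molecule: for each cycle a
#' low-force plateau followed by a high-force plateau (forces cycling
#' round-robin through the configured set). At each jump a bond is
#' present with probability `p_bind`; a present bond survives for an
#' exponentially distributed time with mean given by the catch-slip law
#' at the circuit-model load, then the position steps by the
#' circuit-model `delta_x`. Gaussian noise, the molecule's linear drift,
#' and the instrument low-pass are applied on top. Uses the current R
#' random number generator state; seed upstream for reproducibility.
#'
#' @param config A [simulation_config()].
#' @param construct Bridge length, nt (must be in `config$constructs`).
#' @param molecule_id Identifier string.
#' @param drift_rate Drift rate, nm/s; `NULL` draws one from
#'   `N(0, drift_sd^2)`.
#' @param tau_override If not `NULL`, every bound plateau ruptures at
#'   exactly this dwell time (s) instead of drawing from the
#'   exponential law; useful for noiseless round-trip checks.
#'
#' @return A [trace_record()] with a `ground_truth` data.frame attached
#'   (one row per high plateau: `plateau_id`, `bound`, `tau`, `delta_x`,
#'   `F_Tot`, `F_Load`).
#' @export
simulate_session <- function(config, construct = config$constructs[1],
                             molecule_id = "mol1", drift_rate = NULL,
                             tau_override = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            construct %in% config$constructs)
  geom <- config$geoms[[as.character(construct)]]
  fs <- config$sampling_rate
  dt <- 1 / fs
  n_pl <- round(config$plateau_s * fs)
  if (is.null(drift_rate)) drift_rate <- stats::rnorm(1, 0, config$drift_sd)

  # precompute mechanics per high force
  mech <- lapply(config$high_forces, function(f) {
    b <- solve_bound_state(f, geom)
    u <- solve_unbound_state(f, geom)
    list(F_Load = b$F_Load, x_bound = b$x, x_unbound = u$x,
         delta_x = max(u$x - b$x, 0),
         tau_mean = catch_slip_lifetime(b$F_Load, config$bell))
  })
  x_low <- solve_unbound_state(config$low_force, geom)$x

  n_cycles <- config$cycles_per_molecule
  force_idx <- rep_len(seq_along(config$high_forces), n_cycles)

  ideal <- numeric(0)
  force <- numeric(0)
  plateau_id <- integer(0)
  sched <- vector("list", 2 * n_cycles)
  gt <- vector("list", n_cycles)
  pos <- 0L
  pid <- 0L
  for (cy in seq_len(n_cycles)) {
    m <- mech[[force_idx[cy]]]
    F_hi <- config$high_forces[force_idx[cy]]

    # low plateau
    pid <- pid + 1L
    sched[[2 * cy - 1]] <- data.frame(
      plateau_id = pid, start = pos + 1L, end = pos + n_pl,
      level = "low", F_Tot = config$low_force
    )
    ideal <- c(ideal, rep.int(x_low, n_pl))
    force <- c(force, rep.int(config$low_force, n_pl))
    plateau_id <- c(plateau_id, rep.int(pid, n_pl))
    pos <- pos + n_pl

    # high plateau
    pid <- pid + 1L
    bound <- stats::runif(1) < config$p_bind
    if (bound) {
      tau <- if (is.null(tau_override)) {
        stats::rexp(1, rate = 1 / m$tau_mean)
      } else tau_override
      n_bound <- min(ceiling(tau * fs), n_pl)
      seg <- c(rep.int(m$x_bound, n_bound),
               rep.int(m$x_unbound, n_pl - n_bound))
      gt[[cy]] <- data.frame(
        plateau_id = pid, bound = TRUE, tau = tau, delta_x = m$delta_x,
        F_Tot = F_hi, F_Load = m$F_Load
      )
    } else {
      seg <- rep.int(m$x_unbound, n_pl)
      gt[[cy]] <- data.frame(
        plateau_id = pid, bound = FALSE, tau = NA_real_,
        delta_x = NA_real_, F_Tot = F_hi, F_Load = m$F_Load
      )
    }
    sched[[2 * cy]] <- data.frame(
      plateau_id = pid, start = pos + 1L, end = pos + n_pl,
      level = "high", F_Tot = F_hi
    )
    ideal <- c(ideal, seg)
    force <- c(force, rep.int(F_hi, n_pl))
    plateau_id <- c(plateau_id, rep.int(pid, n_pl))
    pos <- pos + n_pl
  }

  n <- length(ideal)
  time_s <- (seq_len(n) - 1L) * dt
  position <- lowpass(ideal, config$response_time_s, dt) +
    drift_rate * time_s
  if (config$noise_sd > 0) {
    position <- position + stats::rnorm(n, 0, config$noise_sd)
  }

  trace_record(
    data = data.frame(time_s = time_s, position_nm = position,
                      force_pN = force, plateau_id = plateau_id),
    schedule = do.call(rbind, sched),
    molecule_id = molecule_id,
    construct = construct,
    sampling_rate = fs,
    ground_truth = do.call(rbind, gt)
  )
}

#' Simulate a corpus of force-jump sessions
#'
#' Seeds the generator and simulates `n_molecules` sessions for each
#' configured construct.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list of [trace_record()]s, named `<construct>_<molecule>`.
#' @export
simulate_corpus <- function(config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  out <- list()
  for (nt in config$constructs) {
    for (m in seq_len(config$n_molecules)) {
      id <- sprintf("c%d_m%02d", nt, m)
      out[[id]] <- simulate_session(config, construct = nt,
                                    molecule_id = id)
    }
  }
  out
}

#' Simulate a thermophoresis titration
#'
#' A 1:2 serial dilution series (default 16 points from 40 uM final,
#' i.e. an 80 uM stock mixed 1:1 with the labeled partner) with a
#' hyperbolic single-site response plus Gaussian noise.
#'
#' @param KD Dissociation constant, uM.
#' @param Ymax Saturating response amplitude (default 1).
#' @param noise_frac Noise SD as a fraction of `Ymax` (default 0.05).
#' @param n_points Number of dilution points (default 16).
#' @param top_conc Highest final concentration, uM (default 40).
#'
#' @return data.frame with columns `conc_uM`, `response`, `truth`.
#' @export
simulate_mst <- function(KD, Ymax = 1, noise_frac = 0.05, n_points = 16,
                         top_conc = 40) {
  stopifnot(KD > 0, n_points >= 2, top_conc > 0)
  conc <- top_conc / 2^(seq_len(n_points) - 1)
  truth <- Ymax * conc / (KD + conc)
  response <- truth + stats::rnorm(n_points, 0, noise_frac * Ymax)
  data.frame(conc_uM = conc, response = response, truth = truth)
}

#' Write a deterministic synthetic fixture corpus
#'
#' Writes, under `out_dir`: a negative-control corpus (`p_bind = 0`),
#' a corpus whose catch-slip truth parameters are characteristic of the
#' MIDAS-Rsa4 bond, one characteristic of the weaker MIDAS-Ytm1 bond,
#' thermophoresis titration tables, and a
#' `manifest.json` listing every file with its MD5 hash. Byte-identical
#' across runs with the same seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param scale Multiplier on molecules per construct, to shrink or grow
#'   the corpus (default 1).
#' @return Invisibly, the manifest as a data.frame.
#' @export
make_fixture_suite <- function(out_dir, seed = 1, scale = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rsa4 <- bell_params(kc0 = 5.3, xc = -2.0, ks0 = 0.01, xs = 4.1)
  ytm1 <- bell_params(kc0 = 15.2, xc = -4.8, ks0 = 0.04, xs = 3.2)
  n_mol <- max(1L, round(5 * scale))

  corpora <- list(
    negative_control = simulation_config(
      rsa4, n_molecules = max(2L, round(2 * scale)),
      cycles_per_molecule = 50, p_bind = 0
    ),
    rsa4_like = simulation_config(rsa4, n_molecules = n_mol),
    ytm1_like = simulation_config(ytm1, n_molecules = n_mol)
  )

  files <- character(0)
  offset <- 0L
  for (name in names(corpora)) {
    sub <- file.path(out_dir, name)
    dir.create(sub, showWarnings = FALSE)
    traces <- simulate_corpus(corpora[[name]], seed = seed + offset)
    for (id in names(traces)) {
      f <- file.path(sub, paste0(id, ".tsv"))
      write_trace(traces[[id]], f)
      files <- c(files, f, paste0(f, ".json"))
    }
    offset <- offset + 1L
  }

  mst_dir <- file.path(out_dir, "mst")
  dir.create(mst_dir, showWarnings = FALSE)
  set.seed(seed + 100L)
  tit <- simulate_mst(KD = 6.9)
  f <- file.path(mst_dir, "titration_wt.csv")
  utils::write.csv(tit, f, row.names = FALSE)
  files <- c(files, f)

  manifest <- data.frame(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
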