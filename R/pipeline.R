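#' Default pipeline configuration
#'
#' A nested list mirroring the pipeline stages. All physical constants of
#' the assay (0.59 nm/nt, Lp = 1 nm, L_prot = 8 nm, 24-nt loading strand,
#' emitter separation 4 eSD, 4-sample minimum event) live here as
#' defaults, never hard-coded in the stages.
#'
#' @param data_dir Directory holding (or receiving) the trace corpus.
#' @param out_dir Directory for stage outputs (events, groups, report).
#' @param seed Integer seed used by the simulate stage.
#'
#' @return A list of class `"fj_config"`.
#' @export
fj_default_config <- function(data_dir = "data", out_dir = "out", seed = 1) {
  structure(list(
    version = 1L,
    seed = as.integer(seed),
    paths = list(data_dir = data_dir, out_dir = out_dir),
    geometry = list(
      loading_nt = 24, nm_per_nt = 0.59, L_prot = 8,
      persistence_length = 1, kBT = 4.09
    ),
    detection = list(
      boxcar_width = 10, p_trans = 1e-3, mu_sep_esd = 4,
      min_pre_samples = 4, min_post_samples = 4,
      drift_slope_esd_per_s = 0.5,
      drift_window_samples = 100, max_transition_span = 3,
      skip_initial_samples = 5, min_step_esd = 2
    ),
    grouping = list(axis = "F_Load"),
    fit = list(kBT = 4.09, multistart = 4),
    simulation = list(
      bell = list(kc0 = 5.3, xc = -2.0, ks0 = 0.01, xs = 4.1),
      constructs = c(55, 70), n_molecules = 5, cycles_per_molecule = 60,
      sampling_rate = 200, low_force = 0.5,
      high_forces = c(4, 6, 8, 10, 12), plateau_s = 5, p_bind = 0.3,
      noise_sd = 1, drift_sd = 0.5, response_time_s = 0.0075
    )
  ), class = "fj_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are an error; missing keys take their defaults.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file's.
#' @return A validated `"fj_config"` list.
#' @export
fj_read_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  def <- unclass(fj_default_config())
  merge_block <- function(d, u, prefix) {
    bad <- setdiff(names(u), names(d))
    if (length(bad) > 0) {
      stop(sprintf("unknown config key%s: %s",
                   if (length(bad) > 1) "s" else "",
                   paste0(prefix, bad, collapse = ", ")), call. = FALSE)
    }
    for (k in names(u)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(u[[k]])) {
        merge_block(d[[k]], u[[k]], paste0(prefix, k, "."))
      } else u[[k]]
    }
    d
  }
  cfg <- merge_block(def, user, "")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  structure(cfg, class = "fj_config")
}

fj_geom <- function(config, construct) {
  g <- config$geometry
  tether_geometry(
    bridge_nt = construct, loading_nt = g$loading_nt,
    nm_per_nt = g$nm_per_nt, L_prot = g$L_prot,
    persistence_length = g$persistence_length, kBT = g$kBT
  )
}

fj_detection_config <- function(config) {
  do.call(detection_config, config$detection)
}

fj_sim_config <- function(config) {
  s <- config$simulation
  bell <- bell_params(s$bell$kc0, s$bell$xc, s$bell$ks0, s$bell$xs,
                      kBT = config$fit$kBT)
  simulation_config(
    bell = bell, constructs = s$constructs, n_molecules = s$n_molecules,
    cycles_per_molecule = s$cycles_per_molecule,
    sampling_rate = s$sampling_rate, low_force = s$low_force,
    high_forces = s$high_forces, plateau_s = s$plateau_s,
    p_bind = s$p_bind, noise_sd = s$noise_sd, drift_sd = s$drift_sd,
    response_time_s = s$response_time_s,
    geom_args = config$geometry[c("loading_nt", "nm_per_nt", "L_prot",
                                  "persistence_length")]
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate stage: write a synthetic corpus
#'
#' Simulates the configured corpus into `paths$data_dir`: one TSV + JSON
#' sidecar per session plus a hashed `manifest.json`, and a
#' thermophoresis titration table under `mst/`.
#'
#' @param config An `"fj_config"` list.
#' @return Invisibly, the manifest data.frame.
#' @export
fj_simulate <- function(config) {
  stopifnot(inherits(config, "fj_config"))
  dir.create(config$paths$data_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- fj_sim_config(config)
  traces <- simulate_corpus(sim, seed = config$seed)
  files <- character(0)
  for (id in names(traces)) {
    f <- file.path(config$paths$data_dir, paste0(id, ".tsv"))
    write_trace(traces[[id]], f)
    files <- c(files, f, paste0(f, ".json"))
  }
  mst_dir <- file.path(config$paths$data_dir, "mst")
  dir.create(mst_dir, showWarnings = FALSE)
  set.seed(config$seed + 100L)
  tit <- simulate_mst(KD = 6.9)
  f <- file.path(mst_dir, "titration.csv")
  utils::write.csv(tit, f, row.names = FALSE)
  files <- c(files, f)
  manifest <- data.frame(
    file = basename(files), md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(
    manifest, file.path(config$paths$data_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  message(sprintf("simulate: wrote %d sessions to %s",
                  length(traces), config$paths$data_dir))
  invisible(manifest)
}

#' Detect stage: extract events from every trace in the corpus
#'
#' Reads every `*.tsv` trace (with JSON sidecar) under `paths$data_dir`,
#' runs [detect_events()] with the configured geometry and detection
#' settings, and writes the pooled event table to
#' `paths$out_dir/events.csv`.
#'
#' @param config An `"fj_config"` list.
#' @return The event data.frame, invisibly.
#' @export
fj_detect <- function(config) {
  stopifnot(inherits(config, "fj_config"))
  dir.create(config$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsvs <- list.files(config$paths$data_dir, pattern = "\\.tsv$",
                     full.names = TRUE, recursive = TRUE)
  if (length(tsvs) == 0) {
    stop("no trace files under ", config$paths$data_dir, call. = FALSE)
  }
  dcfg <- fj_detection_config(config)
  geoms <- list()
  ev <- lapply(tsvs, function(f) {
    tr <- read_trace(f)
    key <- as.character(tr$construct)
    if (is.null(geoms[[key]])) geoms[[key]] <<- fj_geom(config, tr$construct)
    detect_events(tr, geoms[[key]], dcfg)
  })
  events <- do.call(rbind, ev)
  out <- file.path(config$paths$out_dir, "events.csv")
  utils::write.csv(events, out, row.names = FALSE)
  message(sprintf("detect: %d events from %d sessions -> %s",
                  nrow(events), length(tsvs), out))
  invisible(events)
}

#' Fit stage: group lifetimes, fit the catch-slip model and isotherms
#'
#' Reads `events.csv` from the output directory, groups lifetimes on the
#' configured axis, fits the catch-slip Bell model (skipped with a flag
#' when fewer than four force levels are available), fits a binding
#' isotherm to every `mst/*.csv` titration in the data directory, and
#' writes a machine-readable `report.json`.
#'
#' @param config An `"fj_config"` list.
#' @return The report, invisibly (a list).
#' @export
fj_fit <- function(config) {
  stopifnot(inherits(config, "fj_config"))
  ev_file <- file.path(config$paths$out_dir, "events.csv")
  if (!file.exists(ev_file)) {
    stop("events.csv not found; run the detect stage first", call. = FALSE)
  }
  events <- utils::read.csv(ev_file)
  report <- list(
    package_version = as.character(utils::packageVersion("forcejump")),
    seed = config$seed,
    config_hash = config_hash(config),
    events_md5 = unname(tools::md5sum(ev_file)),
    n_events = nrow(events),
    timestamp = list(generated_at = format(Sys.time(), tz = "UTC"))
  )

  if (nrow(events) > 0) {
    groups <- group_and_summarize(events, axis = config$grouping$axis)
    utils::write.csv(groups,
                     file.path(config$paths$out_dir, "groups.csv"),
                     row.names = FALSE)
    report$groups <- groups
    if (length(unique(groups$F_Load_pN)) >= 4) {
      d <- config$detection
      trunc_s <- (d$skip_initial_samples + d$min_pre_samples) /
        config$simulation$sampling_rate
      fit <- tryCatch(
        fit_catch_slip(groups, kBT = config$fit$kBT,
                       multistart = config$fit$multistart,
                       truncation_s = trunc_s),
        error = function(e) e
      )
      if (inherits(fit, "bell_params")) {
        report$bell_fit <- list(
          kc0 = fit$kc0, xc = fit$xc, ks0 = fit$ks0, xs = fit$xs,
          kBT = fit$kBT, ci95 = fit$ci95, F_crit = fit$F_crit,
          rss = attr(fit, "rss"), n_groups = attr(fit, "n_groups")
        )
      } else {
        report$bell_fit <- list(skipped = TRUE,
                                reason = conditionMessage(fit))
      }
    } else {
      report$bell_fit <- list(skipped = TRUE,
                              reason = "fewer than 4 force levels")
    }
  } else {
    report$groups <- NULL
    report$bell_fit <- list(skipped = TRUE, reason = "no events")
  }

  mst_files <- list.files(file.path(config$paths$data_dir, "mst"),
                          pattern = "\\.csv$", full.names = TRUE)
  if (length(mst_files) > 0) {
    report$isotherms <- lapply(mst_files, function(f) {
      tab <- utils::read.csv(f)
      fit <- tryCatch(fit_binding_isotherm(tab$conc_uM, tab$response),
                      error = function(e) e)
      if (inherits(fit, "isotherm_fit")) {
        list(file = basename(f), KD_uM = fit$KD, Ymax = fit$Ymax,
             ci95 = fit$ci95)
      } else {
        list(file = basename(f), skipped = TRUE,
             reason = conditionMessage(fit))
      }
    })
  }

  out <- file.path(config$paths$out_dir, "report.json")
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  message("fit: report written to ", out)
  invisible(report)
}

#' Run the full pipeline: simulate, detect, fit
#'
#' @param config An `"fj_config"` list.
#' @return The final report, invisibly.
#' @export
fj_run_all <- function(config) {
  fj_simulate(config)
  fj_detect(config)
  fj_fit(config)
}
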