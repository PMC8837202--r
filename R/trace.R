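#' Construct a force-jump trace record
#'
#' A trace record holds one recording session on one molecule: uniformly
#' sampled time/position/force channels plus the plateau schedule that
#' says which stretches of the recording were held at the low
#' (binding-permissive) force and which at a high (bond-loading) force.
#'
#' @param data data.frame with columns `time_s`, `position_nm`,
#'   `force_pN`, `plateau_id` (integer; 0 marks samples outside any
#'   plateau).
#' @param schedule data.frame with columns `plateau_id`, `start`, `end`
#'   (1-based sample indices, inclusive), `level` (`"low"` or `"high"`),
#'   `F_Tot` (pN).
#' @param molecule_id Identifier for the molecule/session.
#' @param construct Bridge length in nucleotides (55 or 70).
#' @param sampling_rate Sampling rate in Hz (default 200).
#' @param ground_truth Optional data.frame of per-high-plateau truth for
#'   synthetic traces: `plateau_id`, `bound` (did a bond survive to the
#'   jump), `tau` (s), `delta_x` (nm), `F_Load` (pN).
#'
#' @return An object of class `"trace_record"`.
#' @export
trace_record <- function(data, schedule, molecule_id, construct,
                         sampling_rate = 200, ground_truth = NULL) {
  stopifnot(
    is.data.frame(data),
    all(c("time_s", "position_nm", "force_pN", "plateau_id") %in% names(data)),
    is.data.frame(schedule),
    all(c("plateau_id", "start", "end", "level", "F_Tot") %in% names(schedule)),
    all(schedule$level %in% c("low", "high")),
    all(schedule$start >= 1), all(schedule$end <= nrow(data)),
    all(schedule$end >= schedule$start),
    sampling_rate > 0
  )
  dt <- diff(data$time_s)
  if (length(dt) > 0 && (any(dt <= 0) || max(abs(dt - 1 / sampling_rate)) > 1e-6)) {
    stop("time channel must be uniform at the stated sampling rate", call. = FALSE)
  }
  structure(
    list(
      data = data, schedule = schedule, molecule_id = molecule_id,
      construct = construct, sampling_rate = sampling_rate,
      ground_truth = ground_truth
    ),
    class = "trace_record"
  )
}

#' @export
print.trace_record <- function(x, ...) {
  nh <- sum(x$schedule$level == "high")
  cat(sprintf(
    "Force-jump trace '%s' (%d nt bridge): %d samples at %g Hz, %d plateaus (%d high)%s\n",
    x$molecule_id, x$construct, nrow(x$data), x$sampling_rate,
    nrow(x$schedule), nh,
    if (is.null(x$ground_truth)) "" else " [synthetic, ground truth attached]"
  ))
  invisible(x)
}

#' Write a trace record to disk
#'
#' Writes the sample channels as a tab-separated table and the metadata
#' (molecule id, construct, sampling rate, plateau schedule, optional
#' ground truth) as a JSON sidecar next to it (`<path>.json`).
#'
#' @param trace A [trace_record()] object.
#' @param path Path of the TSV file to write.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_record"))
  utils::write.table(trace$data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(
    molecule_id = trace$molecule_id,
    construct = trace$construct,
    sampling_rate_hz = trace$sampling_rate,
    schedule = trace$schedule
  )
  if (!is.null(trace$ground_truth)) meta$ground_truth <- trace$ground_truth
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trace record from disk
#'
#' Counterpart of [write_trace()]: reads the TSV channel table and the
#' JSON sidecar `<path>.json`.
#'
#' @param path Path of the TSV file.
#' @return A [trace_record()] object.
#' @export
read_trace <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar, call. = FALSE)
  data <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  gt <- meta$ground_truth
  if (!is.null(gt)) gt <- as.data.frame(gt)
  trace_record(
    data = data,
    schedule = as.data.frame(meta$schedule),
    molecule_id = meta$molecule_id,
    construct = meta$construct,
    sampling_rate = meta$sampling_rate_hz,
    ground_truth = gt
  )
}

#' High-force plateaus of a trace
#'
#' @param trace A [trace_record()] object.
#' @return The rows of the schedule with `level == "high"`.
#' @keywords internal
high_plateaus <- function(trace) {
  trace$schedule[trace$schedule$level == "high", , drop = FALSE]
}
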