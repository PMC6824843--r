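#' Construct and validate a recording session
#'
#' A session bundles the trial table and per-neuron spike times for one
#' recorded hemisphere, with trials from both contexts (load applied to the
#' contralateral or ipsilateral limb) over the eight canonical load
#' combinations. Optional EMG and kinematic channels ride along untouched by
#' the spike pipeline.
#'
#' @param trials data frame with columns `trial_id`, `context` (`"contra"` or
#'   `"ipsi"`), `shoulder_torque_nm`, `elbow_torque_nm`, `perturb_time_ms`,
#'   `trial_end_ms`.
#' @param spikes data frame with columns `neuron_id`, `trial_id`,
#'   `spike_time_ms` (one row per spike, 1 ms resolution).
#' @param emg,kinematics optional long-format data frames
#'   (`channel`, `trial_id`, `time_ms`, `value`) with a `sampling_rate_hz`
#'   attribute.
#' @return An object of class `session`.
#' @export
session <- function(trials, spikes, emg = NULL, kinematics = NULL) {
  s <- structure(
    list(trials = trials, spikes = spikes, emg = emg, kinematics = kinematics),
    class = "session"
  )
  validate_session(s)
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf(
    "<session> %d trials, %d neurons, %d spikes\n",
    nrow(x$trials), length(unique(x$spikes$neuron_id)), nrow(x$spikes)
  ))
  tab <- table(x$trials$context)
  cat("  trials per context:", paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Validate the structural invariants of a session
#'
#' Checks context labels, canonical torques, hold-period and trial-length
#' constraints, referential integrity of the spike table, spike times within
#' their trial, and that every (context, load) cell has at least one trial.
#' Spike times are sorted within each trial.
#'
#' @param s a `session`.
#' @return The validated session (spikes sorted), invisibly usable.
#' @export
validate_session <- function(s) {
  trials <- s$trials
  spikes <- s$spikes
  need <- c("trial_id", "context", "shoulder_torque_nm", "elbow_torque_nm",
            "perturb_time_ms", "trial_end_ms")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop("trials table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  need_sp <- c("neuron_id", "trial_id", "spike_time_ms")
  missing_sp <- setdiff(need_sp, names(spikes))
  if (length(missing_sp)) {
    stop("spikes table is missing columns: ", paste(missing_sp, collapse = ", "))
  }
  if (anyDuplicated(trials$trial_id)) stop("duplicate trial_id in trials table")
  bad_ctx <- setdiff(unique(trials$context), c("contra", "ipsi"))
  if (length(bad_ctx)) {
    stop("context labels outside {contra, ipsi}: ", paste(bad_ctx, collapse = ", "))
  }
  trials$load_index <- match_load_index(trials$shoulder_torque_nm,
                                        trials$elbow_torque_nm)
  if (any(trials$perturb_time_ms < 500)) {
    stop("perturb_time_ms < 500 ms: trials ",
         paste(trials$trial_id[trials$perturb_time_ms < 500], collapse = ", "))
  }
  if (any(trials$trial_end_ms - trials$perturb_time_ms < 1300)) {
    bad <- trials$trial_id[trials$trial_end_ms - trials$perturb_time_ms < 1300]
    stop("trial_end_ms - perturb_time_ms < 1300 ms: trials ",
         paste(bad, collapse = ", "))
  }
  cells <- table(factor(trials$context, c("contra", "ipsi")),
                 factor(trials$load_index, 0:7))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty (context, load) cells: ",
         paste(sprintf("(%s, load %s)", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  if (nrow(spikes)) {
    unknown <- setdiff(unique(spikes$trial_id), trials$trial_id)
    if (length(unknown)) {
      stop("spikes reference unknown trial_id: ", paste(unknown, collapse = ", "))
    }
    end_ms <- trials$trial_end_ms[match(spikes$trial_id, trials$trial_id)]
    if (any(spikes$spike_time_ms < 0 | spikes$spike_time_ms > end_ms)) {
      stop("spike times outside [0, trial_end_ms] found")
    }
    o <- order(spikes$neuron_id, spikes$trial_id, spikes$spike_time_ms)
    spikes <- spikes[o, , drop = FALSE]
    rownames(spikes) <- NULL
  }
  s$trials <- trials
  s$spikes <- spikes
  s
}

#' Read a session from CSV files
#'
#' Expects `trials.csv` (`trial_id,context,shoulder_torque_nm,elbow_torque_nm,
#' perturb_time_ms,trial_end_ms`) and `spikes.csv`
#' (`neuron_id,trial_id,spike_time_ms`), UTF-8 with header rows. Optional EMG
#' and kinematics CSVs are long format `channel,trial_id,time_ms,value`; their
#' sampling rate is supplied by the caller.
#'
#' @param trials_path,spikes_path CSV paths.
#' @param emg_path,kin_path optional CSV paths.
#' @param emg_rate_hz,kin_rate_hz sampling rates for the optional channels.
#' @return A validated `session`.
#' @export
read_session <- function(trials_path, spikes_path,
                         emg_path = NULL, kin_path = NULL,
                         emg_rate_hz = 1000, kin_rate_hz = 1000) {
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  spikes <- utils::read.csv(spikes_path, stringsAsFactors = FALSE)
  if (nrow(spikes) == 0) {
    spikes <- data.frame(neuron_id = character(), trial_id = integer(),
                         spike_time_ms = numeric())
  }
  read_chan <- function(path, rate) {
    if (is.null(path)) return(NULL)
    x <- utils::read.csv(path, stringsAsFactors = FALSE)
    attr(x, "sampling_rate_hz") <- rate
    x
  }
  session(trials, spikes,
          emg = read_chan(emg_path, emg_rate_hz),
          kinematics = read_chan(kin_path, kin_rate_hz))
}

#' Write a session to CSV files
#'
#' @param s a `session`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(s, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             spikes = file.path(dir, "spikes.csv"))
  tr <- s$trials[, c("trial_id", "context", "shoulder_torque_nm",
                     "elbow_torque_nm", "perturb_time_ms", "trial_end_ms")]
  utils::write.csv(tr, paths["trials"], row.names = FALSE, quote = FALSE)
  utils::write.csv(s$spikes[, c("neuron_id", "trial_id", "spike_time_ms")],
                   paths["spikes"], row.names = FALSE, quote = FALSE)
  if (!is.null(s$emg)) {
    paths["emg"] <- file.path(dir, "emg.csv")
    utils::write.csv(s$emg, paths["emg"], row.names = FALSE, quote = FALSE)
  }
  if (!is.null(s$kinematics)) {
    paths["kin"] <- file.path(dir, "kin.csv")
    utils::write.csv(s$kinematics, paths["kin"], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Write an analysis report as JSON
#'
#' Statistics are stored nested by module, each entry carrying its value, a
#' null-distribution summary where one exists, and the seed used, so a rerun
#' with the same seeds reproduces every stochastic entry exactly.
#'
#' @param results a named list (module -> statistic -> entry).
#' @param path output path for the JSON report.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path) {
  bad <- report_unserializable(results)
  if (length(bad)) {
    stop("unserializable report entries: ", paste(bad, collapse = ", "))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

report_unserializable <- function(x, prefix = character()) {
  if (inherits(x, "data.frame")) return(character())
  if (is.list(x)) {
    out <- character()
    nm <- names(x)
    if (is.null(nm)) nm <- as.character(seq_along(x))
    for (i in seq_along(x)) {
      out <- c(out, report_unserializable(x[[i]], c(prefix, nm[i])))
    }
    return(out)
  }
  ok <- is.numeric(x) || is.character(x) || is.logical(x) || is.null(x) ||
    is.factor(x) || inherits(x, "data.frame") || is.matrix(x)
  if (ok) character() else paste(prefix, collapse = "$")
}
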