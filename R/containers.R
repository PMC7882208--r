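# S3 containers shared by all pipeline stages.

#' Construct an epoch set
#'
#' The central container of the pipeline: a `trials x channels(or nodes) x
#' samples` array with a time axis relative to stimulus onset, one condition
#' label per trial, and per-trial keep/reject bookkeeping.
#'
#' @param data numeric array, `trials x channels x samples`
#' @param fs sampling rate in Hz
#' @param time numeric vector of sample times in seconds relative to onset;
#'   defaults to a half-open window starting at `t0`
#' @param condition character vector, one label per trial
#' @param t0 start of the epoch window in seconds (used when `time` is NULL)
#' @param labels channel/node labels
#' @param onset_sample sample index of each trial's onset in the source
#'   recording (NA when the epochs were simulated directly)
#' @param level `"node"` for source-space data, `"sensor"` for channel data
#' @return an object of class `epoch_set`
#' @export
epoch_set <- function(data, fs, time = NULL, condition = NULL, t0 = -5,
                      labels = NULL, onset_sample = NULL, level = "node") {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0)
  n_trials <- dim(data)[1L]
  n_samp <- dim(data)[3L]
  if (is.null(time)) time <- t0 + (seq_len(n_samp) - 1L) / fs
  if (length(time) != n_samp) stop("time axis length must match sample count")
  if (is.null(condition)) condition <- rep("Social", n_trials)
  if (length(condition) != n_trials) stop("one condition label per trial required")
  if (is.null(labels)) labels <- sprintf("%s%03d", ifelse(level == "node", "node", "chan"),
                                         seq_len(dim(data)[2L]))
  structure(list(
    data = data, fs = fs, time = time, condition = condition,
    labels = labels,
    kept = rep(TRUE, n_trials),
    reason = rep(NA_character_, n_trials),
    max_fT = rep(NA_real_, n_trials),
    max_motion_mm = rep(NA_real_, n_trials),
    onset_sample = onset_sample %||% rep(NA_integer_, n_trials),
    level = level
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d %ss x %d samples @ %g Hz [%g, %g) s; %d kept\n",
              d[1L], d[2L], x$level, d[3L], x$fs, x$time[1L],
              x$time[length(x$time)] + 1 / x$fs, sum(x$kept)))
  invisible(x)
}

#' Number of kept trials in an epoch set
#' @param epochs an `epoch_set`
#' @return integer count
#' @export
n_kept <- function(epochs) sum(epochs$kept)

#' Construct a continuous sensor recording
#'
#' @param data numeric matrix `channels x samples`, in fT
#' @param fs sampling rate in Hz
#' @param events data.frame with columns `sample` (onset index) and `condition`
#' @param fiducials optional `3 points x 3 coords x samples` array of fiducial
#'   positions (nasion, left/right pre-auricular) in mm
#' @param leadfield optional `channels x sources` gain matrix carried along for
#'   beamformer tests
#' @return an object of class `continuous_recording`
#' @export
continuous_recording <- function(data, fs, events, fiducials = NULL,
                                 leadfield = NULL) {
  stopifnot(is.matrix(data), fs > 0)
  events <- as.data.frame(events)
  if (!all(c("sample", "condition") %in% names(events)))
    stop("events must have columns 'sample' and 'condition'")
  if (any(events$sample < 1L | events$sample > ncol(data)))
    stop("event sample indices must lie within the recording")
  if (!is.null(fiducials)) {
    stopifnot(length(dim(fiducials)) == 3L, dim(fiducials)[1L] == 3L,
              dim(fiducials)[2L] == 3L)
    if (dim(fiducials)[3L] != ncol(data))
      stop("fiducial track length must equal the data length")
  }
  structure(list(data = data, fs = fs, events = events,
                 fiducials = fiducials, leadfield = leadfield),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz; %d events%s\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events),
              if (is.null(x$fiducials)) "" else "; fiducials tracked"))
  invisible(x)
}
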