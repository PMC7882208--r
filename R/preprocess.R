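# Continuous-recording preprocessing: band-pass + notch filtering, epoching,
# and trial rejection by amplitude (2500 fT) and rigid-body head motion
# (10 mm from the median head position).

#' Band-pass and notch filter a continuous recording
#'
#' Per channel: remove the mean, apply a 4th-order Butterworth band-pass
#' (default 1-150 Hz) forward-backward (zero phase, preserving envelope
#' timing), and suppress line noise with a DFT notch that zeroes spectral bins
#' within `notch_width/2` of each notch frequency.
#'
#' @param rec a [continuous_recording]
#' @param band passband edges in Hz
#' @param order Butterworth order per edge
#' @param notch notch frequencies in Hz
#' @param notch_width full width of each spectral notch in Hz
#' @return the filtered recording
#' @export
bandpass_and_notch <- function(rec, band = c(1, 150), order = 4,
                               notch = c(60, 120), notch_width = 1) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (rec$fs <= 2 * band[2L])
    stop(sprintf("sampling rate %g Hz puts the %g Hz band edge at or above the Nyquist frequency %g Hz",
                 rec$fs, band[2L], rec$fs / 2))
  x <- rec$data - rowMeans(rec$data)
  bf <- signal::butter(order, band / (rec$fs / 2), "pass")
  for (ch in seq_len(nrow(x)))
    x[ch, ] <- signal::filtfilt(bf, x[ch, ])
  if (length(notch)) {
    n <- ncol(x)
    freqs <- (seq_len(n) - 1L) / n * rec$fs
    freqs <- pmin(freqs, rec$fs - freqs)  # two-sided
    kill <- rep(FALSE, n)
    for (f0 in notch) kill <- kill | abs(freqs - f0) <= notch_width / 2
    X <- stats::mvfft(t(x))
    X[kill, ] <- 0
    x <- t(Re(stats::mvfft(X, inverse = TRUE)) / n)
  }
  rec$data <- x
  rec
}

#' Epoch a continuous recording around its events
#'
#' Each trial holds the half-open window `[onset + window[1], onset +
#' window[2])` seconds. Events too close to the recording edges are skipped
#' with a warning rather than failing the run.
#'
#' @param rec a [continuous_recording]
#' @param window epoch limits in seconds relative to onset
#' @return an [epoch_set] at sensor level
#' @export
epoch_recording <- function(rec, window = c(-5, 17)) {
  stopifnot(inherits(rec, "continuous_recording"))
  fs <- rec$fs
  pre <- round(-window[1L] * fs)
  post <- round(window[2L] * fs)
  n_samp <- pre + post
  total <- ncol(rec$data)
  ok <- rec$events$sample - pre >= 1L & rec$events$sample + post - 1L <= total
  if (any(!ok))
    warning(sprintf("%d event(s) too close to the recording edge were skipped",
                    sum(!ok)))
  ev <- rec$events[ok, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no events fit inside the recording")
  dat <- array(0, c(nrow(ev), nrow(rec$data), n_samp))
  for (tr in seq_len(nrow(ev))) {
    rng <- (ev$sample[tr] - pre):(ev$sample[tr] + post - 1L)
    dat[tr, , ] <- rec$data[, rng]
  }
  epoch_set(dat, fs, time = window[1L] + (seq_len(n_samp) - 1L) / fs,
            condition = as.character(ev$condition),
            onset_sample = ev$sample, level = "sensor",
            labels = rownames(rec$data) %||%
              sprintf("chan%03d", seq_len(nrow(rec$data))))
}

#' Flag trials whose signal exceeds an amplitude threshold
#'
#' A trial is rejected iff its maximum absolute value over channels and samples
#' strictly exceeds the threshold (a sample at exactly the threshold is kept).
#'
#' @param epochs an [epoch_set] with data in fT
#' @param threshold_fT rejection threshold (default 2500 fT)
#' @return the epoch set with `kept`, `reason` and `max_fT` updated
#' @export
reject_amplitude <- function(epochs, threshold_fT = 2500) {
  stopifnot(inherits(epochs, "epoch_set"))
  mx <- apply(abs(epochs$data), 1L, max)
  epochs$max_fT <- mx
  bad <- mx > threshold_fT
  newly <- bad & is.na(epochs$reason)
  epochs$kept[newly] <- FALSE
  epochs$reason[newly] <- "amplitude"
  epochs
}

# Least-squares rigid-body (rotation + translation) fit of reference points to
# current points, reflection-guarded (Kabsch).
kabsch_displacement <- function(ref, cur) {
  cr <- colMeans(ref); cc <- colMeans(cur)
  H <- crossprod(ref - rep(cr, each = 3L), cur - rep(cc, each = 3L))
  s <- svd(H)
  dsign <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  moved <- (ref - rep(cr, each = 3L)) %*% t(R) + rep(cc, each = 3L)
  max(sqrt(rowSums((moved - ref)^2)))
}

#' Rigid-body head displacement from fiducial tracks
#'
#' The per-coordinate median fiducial position over the recording is the
#' reference head position. For each sample, the optimal rigid-body transform
#' from the reference triangle to the current fiducials is fitted by
#' least squares (Kabsch), and the displacement is the largest distance any of
#' the three fiducials is moved by that transform.
#'
#' @param fiducials `3 points x 3 coords x samples` array in mm
#' @return numeric vector of per-sample displacements (mm), with the reference
#'   positions in attribute `reference`
#' @export
head_motion_displacement <- function(fiducials) {
  stopifnot(length(dim(fiducials)) == 3L, dim(fiducials)[1L] == 3L,
            dim(fiducials)[2L] == 3L)
  ref <- apply(fiducials, c(1L, 2L), stats::median)
  spans <- svd(sweep(ref, 2L, colMeans(ref)))$d
  if (spans[2L] <= 1e-9 * max(spans[1L], 1))
    stop("fiducial reference positions are collinear; rigid-body tracking is degenerate")
  n <- dim(fiducials)[3L]
  disp <- numeric(n)
  for (t in seq_len(n))
    disp[t] <- kabsch_displacement(ref, fiducials[, , t])
  attr(disp, "reference") <- ref
  disp
}

#' Flag trials exceeding a head-motion threshold
#'
#' Uses the per-sample displacement of the source recording and each trial's
#' sample range (from `onset_sample`). Amplitude rejection takes precedence: a
#' trial already rejected for amplitude keeps that reason.
#'
#' @param epochs an [epoch_set] with `onset_sample` set (from
#'   [epoch_recording()])
#' @param displacement per-sample displacement from
#'   [head_motion_displacement()]
#' @param threshold_mm rejection threshold (default 10 mm)
#' @return the epoch set with motion flags updated
#' @export
reject_motion <- function(epochs, displacement, threshold_mm = 10) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (all(is.na(epochs$onset_sample)))
    stop("epochs carry no onset samples; motion rejection needs epochs cut from a recording")
  fs <- epochs$fs
  pre <- round(-epochs$time[1L] * fs)
  n_samp <- length(epochs$time)
  for (tr in seq_along(epochs$kept)) {
    rng <- (epochs$onset_sample[tr] - pre):(epochs$onset_sample[tr] - pre + n_samp - 1L)
    epochs$max_motion_mm[tr] <- max(displacement[rng])
  }
  bad <- epochs$max_motion_mm > threshold_mm
  newly <- bad & is.na(epochs$reason)
  epochs$kept[newly] <- FALSE
  epochs$reason[newly] <- "motion"
  epochs
}

#' Filter, epoch and reject trials of a continuous recording
#'
#' Convenience wrapper running the full preprocessing chain in the fixed
#' order: filtering on continuous data (avoiding edge transients inside
#' epochs), epoching, amplitude rejection, then head-motion rejection.
#'
#' @param rec a [continuous_recording]
#' @param window epoch window in seconds
#' @param amp_threshold_fT amplitude rejection threshold
#' @param motion_threshold_mm head-motion rejection threshold
#' @param band,notch filter settings passed to [bandpass_and_notch()]
#' @return an [epoch_set] with rejection flags set
#' @export
preprocess <- function(rec, window = c(-5, 17), amp_threshold_fT = 2500,
                       motion_threshold_mm = 10, band = c(1, 150),
                       notch = c(60, 120)) {
  filtered <- bandpass_and_notch(rec, band = band, notch = notch)
  epochs <- epoch_recording(filtered, window = window)
  epochs <- reject_amplitude(epochs, amp_threshold_fT)
  if (!is.null(rec$fiducials)) {
    disp <- head_motion_displacement(rec$fiducials)
    epochs <- reject_motion(epochs, disp, motion_threshold_mm)
  }
  epochs
}

#' Per-trial rejection report
#'
#' @param epochs an [epoch_set]
#' @return data.frame `trial, condition, kept, reason, max_fT, max_motion_mm`
#' @export
rejection_report <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  data.frame(trial = seq_along(epochs$kept), condition = epochs$condition,
             kept = epochs$kept, reason = epochs$reason,
             max_fT = epochs$max_fT, max_motion_mm = epochs$max_motion_mm,
             row.names = NULL)
}
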