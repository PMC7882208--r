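# Leakage-corrected, baselined amplitude-envelope correlation (AEC).
#
# Pipeline order is fixed: band-pass FIR filter -> symmetric orthogonalization
# (per trial, over the full epoch) -> Hilbert envelope -> windowed Pearson
# correlation (Fisher-z averaged over trials) -> fractional-change baselining
# against the pre-stimulus window.

#' Canonical frequency bands
#'
#' @return named list of `c(low, high)` band edges in Hz: theta (4-7),
#'   alpha (8-12), beta (13-29), gamma (30-55)
#' @export
canonical_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 29), gamma = c(30, 55))
}

#' Default analysis windows
#'
#' @return list with `baseline = c(-5, 0)` and task windows 0-5, 5-10, 10-15 s
#' @export
default_windows <- function() {
  list(baseline = c(-5, 0), `0-5` = c(0, 5), `5-10` = c(5, 10),
       `10-15` = c(10, 15))
}

resolve_band <- function(band) {
  if (is.character(band)) {
    bands <- canonical_bands()
    if (!band %in% names(bands))
      stop(sprintf("unknown band '%s'; use one of %s or c(low, high)",
                   band, paste(names(bands), collapse = ", ")))
    bands[[band]]
  } else {
    band <- as.numeric(band)
    if (length(band) != 2L || band[1L] <= 0 || band[1L] >= band[2L])
      stop("a numeric band must be c(low, high) with 0 < low < high")
    band
  }
}

#' Design a linear-phase band-pass FIR filter
#'
#' Hamming-windowed type-I FIR (odd length) sized so the transition width is
#' at most half the lower band edge, giving at least 40 dB of stopband
#' attenuation one octave outside the band.
#'
#' @param band band name or `c(low, high)` in Hz
#' @param fs sampling rate in Hz
#' @return numeric vector of filter coefficients
#' @export
design_band_fir <- function(band, fs) {
  band <- resolve_band(band)
  if (band[2L] >= fs / 2)
    stop(sprintf("band upper edge %g Hz is not below the Nyquist frequency %g Hz",
                 band[2L], fs / 2))
  transition <- band[1L] / 2
  n_order <- ceiling(3.3 * fs / transition)
  if (n_order %% 2L == 1L) n_order <- n_order + 1L
  n_order <- max(n_order, 30L)
  as.numeric(signal::fir1(n_order, band / (fs / 2), type = "pass"))
}

#' Band-pass filter source epochs
#'
#' Applies the zero-phase (group-delay-compensated) FIR band-pass per trial and
#' node, assuming zeros outside each epoch.
#'
#' @param x an [epoch_set] or a `nodes x samples` matrix
#' @param band band name or `c(low, high)` Hz
#' @param fs sampling rate (taken from the epoch set when omitted)
#' @return filtered object of the same shape
#' @export
band_filter <- function(x, band, fs = NULL) {
  if (inherits(x, "epoch_set")) {
    b <- design_band_fir(band, x$fs)
    out <- x
    for (tr in seq_len(dim(x$data)[1L]))
      out$data[tr, , ] <- fir_apply(x$data[tr, , , drop = TRUE], b)
    out
  } else {
    if (is.null(fs)) stop("fs is required for matrix input")
    fir_apply(x, design_band_fir(band, fs))
  }
}

#' Symmetric (leakage-correcting) orthogonalization
#'
#' Finds the closest matrix (least-squares, Frobenius norm) to the input whose
#' node series are exactly mutually orthogonal, treating all nodes equivalently
#' rather than regressing one out of another. The solution is a rank-preserving
#' alternation: given per-node scales, the nearest set of orthonormal series is
#' the Procrustes solution (polar rotation via SVD); given the series, the
#' optimal scales are their projections. Node series are mean-centred first, so
#' all pairwise zero-lag Pearson correlations of the output are zero to
#' numerical precision.
#'
#' @param x `nodes x samples` matrix with `samples > nodes` and full row rank
#' @param tol relative change in the Frobenius residual at which iteration
#'   stops
#' @param max_iter maximum number of alternations
#' @return matrix of the same shape with mutually orthogonal, zero-mean rows;
#'   attribute `iterations` records the count
#' @export
orthogonalize <- function(x, tol = 1e-10, max_iter = 100L) {
  stopifnot(is.matrix(x))
  n_nodes <- nrow(x)
  if (ncol(x) <= n_nodes)
    stop("orthogonalize needs more samples than nodes")
  D <- t(x)
  D <- sweep(D, 2L, colMeans(D))
  s0 <- svd(D, nu = 0L, nv = 0L)
  if (s0$d[n_nodes] <= 1e-10 * s0$d[1L])
    stop(sprintf("input is rank-deficient (relative smallest singular value %.2e); leakage correction is undefined",
                 s0$d[n_nodes] / s0$d[1L]))
  d <- sqrt(colSums(D^2))
  nrm <- sqrt(sum(D^2))
  prev <- Inf
  O <- NULL
  for (it in seq_len(max_iter)) {
    s <- svd(sweep(D, 2L, d, "*"))
    O <- s$u %*% t(s$v)
    d <- colSums(D * O)
    resid <- sqrt(sum((D - sweep(O, 2L, d, "*"))^2))
    if (resid <= 1e-12 * nrm ||
        (is.finite(prev) && abs(prev - resid) <= tol * max(resid, .Machine$double.eps))) {
      out <- t(sweep(O, 2L, d, "*"))
      attr(out, "iterations") <- it
      return(out)
    }
    prev <- resid
  }
  stop(sprintf("orthogonalization did not converge in %d iterations (residual %.6g)",
               max_iter, prev))
}

#' Amplitude envelope via the Hilbert transform
#'
#' @param x an [epoch_set], a `nodes x samples` matrix, or a vector
#' @return nonnegative envelope(s) of the same shape
#' @export
envelope <- function(x) {
  if (inherits(x, "epoch_set")) {
    out <- x
    for (tr in seq_len(dim(x$data)[1L]))
      out$data[tr, , ] <- Mod(analytic_signal(x$data[tr, , , drop = TRUE]))
    return(out)
  }
  Mod(analytic_signal(x))
}

clip_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' Windowed amplitude-envelope correlation matrices
#'
#' For each analysis window, computes the Pearson correlation of every node
#' pair's envelope samples within the window, per trial, then aggregates across
#' kept trials by Fisher z-transform, mean, and inverse transform.
#'
#' @param env_epochs an [epoch_set] of amplitude envelopes
#' @param windows named list of `c(start, end)` windows in seconds (half-open)
#' @param condition restrict to trials of this condition (NULL for all kept)
#' @return named list of symmetric `nodes x nodes` matrices (zero diagonal)
#' @export
windowed_aec <- function(env_epochs, windows = default_windows(),
                         condition = NULL) {
  stopifnot(inherits(env_epochs, "epoch_set"))
  use <- env_epochs$kept
  if (!is.null(condition)) use <- use & env_epochs$condition == condition
  if (!any(use)) stop("no kept trials to aggregate")
  n <- dim(env_epochs$data)[2L]
  out <- vector("list", length(windows))
  names(out) <- names(windows)
  for (w in seq_along(windows)) {
    idx <- which(env_epochs$time >= windows[[w]][1L] &
                 env_epochs$time < windows[[w]][2L])
    if (length(idx) < 10L)
      stop(sprintf("window '%s' holds fewer than 10 samples", names(windows)[w]))
    zsum <- matrix(0, n, n)
    for (tr in which(use)) {
      seg <- env_epochs$data[tr, , idx, drop = TRUE]
      sds <- apply(seg, 1L, stats::sd)
      flat <- sds == 0 | !is.finite(sds)
      if (any(flat)) {
        warning(sprintf("zero-variance envelope in window '%s' (trial %d); affected pairs set to 0",
                        names(windows)[w], tr))
        seg[flat, ] <- 0
      }
      C <- suppressWarnings(stats::cor(t(seg)))
      C[!is.finite(C)] <- 0
      diag(C) <- 0
      zsum <- zsum + clip_z(C)
    }
    m <- tanh(zsum / sum(use))
    diag(m) <- 0
    out[[w]] <- m
  }
  out
}

#' Fractional-change baselining of a connectivity matrix
#'
#' Entrywise `(task - baseline) / max(|baseline|, eps)` with the sign of the
#' baseline preserved in the denominator. Entries whose baseline magnitude
#' falls below `eps` are flagged in the `mask` attribute (and are guarded by
#' `eps` rather than dividing by ~0).
#'
#' @param task_aec,baseline_aec conformant symmetric matrices
#' @param eps guard for near-zero baselines
#' @return baselined matrix with logical attribute `mask`
#' @export
baseline_fractional_change <- function(task_aec, baseline_aec, eps = 1e-3) {
  stopifnot(all(dim(task_aec) == dim(baseline_aec)))
  sgn <- ifelse(baseline_aec < 0, -1, 1)
  denom <- sgn * pmax(abs(baseline_aec), eps)
  out <- (task_aec - baseline_aec) / denom
  mask <- abs(baseline_aec) < eps
  diag(out) <- 0
  diag(mask) <- FALSE
  attr(out, "mask") <- mask
  out
}

#' Band- and window-resolved AEC for one subject
#'
#' Runs the full connectivity pipeline on one subject's source epochs for one
#' frequency band: FIR band-pass, optional symmetric orthogonalization (per
#' trial, over the full epoch so baseline and task share one leakage
#' correction), Hilbert envelopes, windowed trial-aggregated AEC, and
#' fractional-change baselining of each task window against the baseline
#' window.
#'
#' @param epochs a source-level [epoch_set]
#' @param band band name or `c(low, high)` Hz
#' @param windows named window list; the entry named `baseline` is the
#'   reference
#' @param orthogonalize apply leakage correction (default TRUE)
#' @param eps baseline guard passed to [baseline_fractional_change()]
#' @param condition which condition's trials enter the matrices
#' @return object of class `aec_result`: list with `band`, `raw` (all
#'   windows), `baselined` (task windows, each carrying a `mask` attribute),
#'   `n_trials`
#' @export
compute_aec <- function(epochs, band, windows = default_windows(),
                        orthogonalize = TRUE, eps = 1e-3,
                        condition = "Social") {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!"baseline" %in% names(windows))
    stop("windows must include a 'baseline' entry")
  b <- design_band_fir(band, epochs$fs)
  env <- epochs
  use <- epochs$kept
  if (!is.null(condition)) use <- use & epochs$condition == condition
  for (tr in which(use)) {
    filt <- fir_apply(epochs$data[tr, , , drop = TRUE], b)
    if (orthogonalize) filt <- orthogonalize(filt)
    env$data[tr, , ] <- Mod(analytic_signal(filt))
  }
  env$kept <- use
  raw <- windowed_aec(env, windows, condition = NULL)
  task_names <- setdiff(names(windows), "baseline")
  baselined <- lapply(raw[task_names], baseline_fractional_change,
                      baseline_aec = raw$baseline, eps = eps)
  structure(list(band = band, windows = windows, raw = raw,
                 baselined = baselined, n_trials = sum(use)),
            class = "aec_result")
}

#' @export
print.aec_result <- function(x, ...) {
  cat(sprintf("<aec_result> band %s; %d trials; windows: %s\n",
              if (is.character(x$band)) x$band else paste(x$band, collapse = "-"),
              x$n_trials, paste(names(x$raw), collapse = ", ")))
  invisible(x)
}
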