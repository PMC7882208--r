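# Linearly constrained minimum variance (LCMV) beamforming with trace-scaled
# regularization, dominant-orientation projection, and noise-normalized output
# (the neural activity index).

#' Sensor covariance over kept trials
#'
#' Covariance of the concatenated kept-trial samples with the per-channel mean
#' removed; symmetric positive semi-definite by construction.
#'
#' @param epochs a sensor-level [epoch_set] with at least 2 kept trials
#' @return `channels x channels` covariance matrix
#' @export
sensor_covariance <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- which(epochs$kept)
  if (length(keep) < 2L) stop("at least 2 kept trials are required")
  n_chan <- dim(epochs$data)[2L]
  x <- matrix(aperm(epochs$data[keep, , , drop = FALSE], c(2L, 3L, 1L)), n_chan)
  if (ncol(x) < n_chan)
    warning("fewer samples than channels: covariance is rank-deficient; regularization will be needed")
  x <- x - rowMeans(x)
  C <- tcrossprod(x) / (ncol(x) - 1L)
  (C + t(C)) / 2
}

#' LCMV beamformer weights
#'
#' Regularizes the covariance as `Cr = C + reg_fraction * (tr(C)/n) * I`, then
#' per node computes the unit-gain minimum-variance spatial filter
#' `w = (l' Cr^-1 l)^-1 l' Cr^-1`. For free-orientation lead fields
#' (`channels x nodes x 3`) the dominant orientation is the principal
#' eigenvector of the 3x3 source-power matrix `(L' Cr^-1 L)^-1` (its sign fixed
#' so the largest-magnitude component is positive) and the lead field is
#' projected onto it first. The noise normalization `sqrt(w w')` used for the
#' neural activity index is returned alongside.
#'
#' @param leadfield `channels x nodes` gain matrix, or `channels x nodes x 3`
#'   for free orientation; columns must not be all zero
#' @param covariance symmetric `channels x channels` sensor covariance
#' @param reg_fraction diagonal loading as a fraction of mean sensor power
#' @return object of class `lcmv`: list with `weights` (nodes x channels,
#'   unit gain), `noise_norm` (per node), `orientation` (nodes x 3 or NULL),
#'   `reg_fraction`
#' @export
lcmv_weights <- function(leadfield, covariance, reg_fraction = 0.05) {
  stopifnot(reg_fraction >= 0)
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(abs(covariance)))
    stop("covariance must be symmetric")
  free <- length(dim(leadfield)) == 3L
  n_chan <- nrow(covariance)
  n_nodes <- if (free) dim(leadfield)[2L] else ncol(leadfield)
  Cr <- covariance + reg_fraction * (sum(diag(covariance)) / n_chan) * diag(n_chan)
  Cinv <- tryCatch(solve(Cr), error = function(e)
    stop("regularized covariance is singular; increase reg_fraction"))
  W <- matrix(0, n_nodes, n_chan)
  ori <- if (free) matrix(NA_real_, n_nodes, 3L) else NULL
  for (v in seq_len(n_nodes)) {
    if (free) {
      L3 <- leadfield[, v, ]
      if (all(L3 == 0)) stop(sprintf("lead-field column for node %d is all zero", v))
      A <- crossprod(L3, Cinv %*% L3)
      P <- tryCatch(solve(A), error = function(e)
        stop(sprintf("source-power matrix is singular at node %d", v)))
      u <- eigen((P + t(P)) / 2, symmetric = TRUE)$vectors[, 1L]
      # eigenvectors are sign-ambiguous; fix the convention for determinism
      if (u[which.max(abs(u))] < 0) u <- -u
      ori[v, ] <- u
      l <- drop(L3 %*% u)
    } else {
      l <- leadfield[, v]
      if (all(l == 0)) stop(sprintf("lead-field column for node %d is all zero", v))
    }
    cl <- drop(Cinv %*% l)
    denom <- sum(l * cl)
    if (!is.finite(denom) || abs(denom) < .Machine$double.eps)
      stop(sprintf("projected lead field at node %d yields a singular constraint", v))
    W[v, ] <- cl / denom
  }
  structure(list(weights = W, noise_norm = sqrt(rowSums(W^2)),
                 orientation = ori, reg_fraction = reg_fraction),
            class = "lcmv")
}

#' Project sensor epochs to source space
#'
#' Applies the beamformer weights per trial. With `nai = TRUE` (default for
#' `lcmv` objects) weights are divided by their norm so unit-variance sensor
#' noise maps to unit source variance — the neural activity index. A plain
#' matrix is applied as given.
#'
#' @param epochs a sensor-level [epoch_set]
#' @param weights an `lcmv` object or a `nodes x channels` matrix
#' @param nai noise-normalize the output (ignored for plain matrices)
#' @param labels optional node labels for the output
#' @return a node-level [epoch_set]
#' @export
project_to_sources <- function(epochs, weights, nai = TRUE, labels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  W <- if (inherits(weights, "lcmv")) {
    if (nai) weights$weights / weights$noise_norm else weights$weights
  } else weights
  if (ncol(W) != dim(epochs$data)[2L])
    stop(sprintf("weight matrix has %d channels but epochs have %d",
                 ncol(W), dim(epochs$data)[2L]))
  n_trials <- dim(epochs$data)[1L]
  n_samp <- dim(epochs$data)[3L]
  out_dat <- array(0, c(n_trials, nrow(W), n_samp))
  for (tr in seq_len(n_trials))
    out_dat[tr, , ] <- W %*% epochs$data[tr, , ]
  out <- epoch_set(out_dat, epochs$fs, time = epochs$time,
                   condition = epochs$condition,
                   onset_sample = epochs$onset_sample, level = "node",
                   labels = labels %||% sprintf("node%03d", seq_len(nrow(W))))
  out$kept <- epochs$kept
  out$reason <- epochs$reason
  out$max_fT <- epochs$max_fT
  out$max_motion_mm <- epochs$max_motion_mm
  out
}
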