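# Internal numerical helpers shared across modules.

#' Analytic signal via the one-sided spectrum
#'
#' Computes the analytic signal (signal + i * Hilbert transform) of each row of
#' a real matrix by doubling the positive-frequency half of the DFT. The
#' modulus of the result is the amplitude envelope.
#'
#' @param x numeric vector, or matrix with one series per row
#' @return complex vector/matrix of the same shape
#' @keywords internal
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  if (!all(is.finite(x))) stop("analytic_signal: input must be finite")
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  # mvfft works on columns; rows hold series here
  X <- t(stats::mvfft(t(x)))
  a <- t(stats::mvfft(t(X * rep(h, each = nrow(x))), inverse = TRUE)) / n
  if (vec) a <- drop(a)
  a
}

# Centered zero-phase application of a symmetric (linear-phase, odd-length)
# FIR filter to each row of x, assuming zeros outside the record. FFT overlap
# is avoided by zero-padding to length n + nb - 1.
fir_apply <- function(x, b) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  nb <- length(b)
  if (nb %% 2L != 1L) stop("fir_apply expects an odd-length (type-I) FIR filter")
  nfft <- stats::nextn(n + nb - 1L, 2L)
  B <- stats::fft(c(b, numeric(nfft - nb)))
  xp <- cbind(x, matrix(0, nrow(x), nfft - n))
  Y <- t(stats::mvfft(t(xp))) * rep(B, each = nrow(x))
  y <- Re(t(stats::mvfft(t(Y), inverse = TRUE))) / nfft
  delay <- (nb - 1L) / 2L
  out <- y[, (delay + 1L):(delay + n), drop = FALSE]
  if (vec) out <- drop(out)
  out
}

# Maximal connected-component extent (edge count) of an undirected graph given
# by parallel endpoint vectors, via union-find. Small enough to beat building a
# full graph object inside permutation loops; equivalence with
# igraph::components is asserted in the test suite.
max_extent_uf <- function(ei, ej) {
  m <- length(ei)
  if (m == 0L) return(0L)
  ids <- sort(unique(c(ei, ej)))
  ei <- match(ei, ids); ej <- match(ej, ids)
  parent <- seq_along(ids)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_len(m)) {
    ra <- find(ei[k]); rb <- find(ej[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(ids), find, integer(1L))
  edge_root <- roots[ei]
  max(tabulate(edge_root, nbins = length(ids)))
}

# Upper-triangle index pairs for an n-node symmetric matrix, column-major to
# match R's mat[upper.tri(mat)] ordering.
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[, c("row", "col"), drop = FALSE]
}

# Rebuild a symmetric matrix (zero diagonal) from its upper-triangle vector.
sym_from_upper <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
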