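# Shared fixtures and independent oracles, built in code at test time.

# Small synthetic spec with artefacts off; sizes chosen to keep the suite fast.
tiny_spec <- function(..., seed = 1L) {
  defaults <- list(n_nodes = 10L, n_subjects_per_group = 2L, n_trials = 2L,
                   fs = 150, epoch_window = c(-5, 17), band = "alpha",
                   artefact_rates = c(spike = 0, motion = 0), seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_spec, args)
}

# Independent time-domain Hilbert transformer: ideal odd-tap FIR, Hamming
# windowed. Used to cross-check the package's FFT analytic signal away from
# record edges.
oracle_envelope <- function(x, n_taps = 301L) {
  k <- -((n_taps - 1L) %/% 2L):((n_taps - 1L) %/% 2L)
  h <- ifelse(k %% 2L == 0L, 0, 2 / (pi * k))
  h <- h * (0.54 + 0.46 * cos(2 * pi * k / n_taps))
  xh <- stats::convolve(x, rev(h), type = "open")
  delay <- (n_taps - 1L) %/% 2L
  xh <- xh[(delay + 1L):(delay + length(x))]
  sqrt(x^2 + xh^2)
}

# Direct two-sample t statistic (pooled or Welch) written independently of the
# vectorized implementation under test.
oracle_t2 <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    (mean(x) - mean(y)) / sqrt(stats::var(x) / n1 + stats::var(y) / n2)
  }
}

# Brute-force maximal component extent via igraph, the reference for the
# union-find used in permutation loops.
oracle_max_extent <- function(edges, n_nodes) {
  if (nrow(edges) == 0L) return(0L)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  mem <- igraph::components(g)$membership
  max(table(mem[edges[, 1L]]))
}

# Epoch sets holding the given channels x samples matrix as 1 or 2 identical
# trials (sensor covariance needs at least two kept trials).
one_trial_epochs <- function(mat, fs = 150, t0 = 0, level = "node") {
  epoch_set(array(mat, c(1L, nrow(mat), ncol(mat))), fs, t0 = t0,
            condition = "Social", level = level)
}

two_trial_epochs <- function(mat, fs = 150, t0 = 0, level = "sensor") {
  arr <- array(0, c(2L, nrow(mat), ncol(mat)))
  arr[1L, , ] <- mat
  arr[2L, , ] <- mat
  epoch_set(arr, fs, t0 = t0, level = level)
}

# FIR magnitude response at given frequencies.
fir_response <- function(b, f, fs) {
  j <- seq_along(b) - 1L
  vapply(f, function(f0) Mod(sum(b * exp(-2i * pi * f0 * j / fs))), numeric(1L))
}
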