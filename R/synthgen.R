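# Synthetic two-group MEG-like datasets with known envelope-coupling structure.
#
# Generative model: each node carries band-limited Gaussian noise (the carrier)
# multiplied by a slow positive modulator m(t) = exp(sigma * z(t)), where z is
# low-pass (< 1 Hz) standardized Gaussian noise. Envelope coupling between
# nodes is planted by sharing a common slow factor between the z's of coupled
# nodes. For a lognormal modulator on a Rayleigh carrier envelope the mapping
# between the factor loading and the resulting envelope correlation is
# analytic, so coupling targets are calibrated in closed form.

#' Specification of a synthetic two-group dataset
#'
#' Defaults follow the study conditions the package emulates: 90 atlas nodes,
#' 600 Hz sampling, epochs spanning -5 to 17 s around stimulus onset, about 22
#' good trials per subject, and ~30 subjects per group.
#'
#' @param n_nodes number of source-space nodes
#' @param n_subjects_per_group subjects in each of groups A and B
#' @param n_trials trials per subject (alternating Social/Physical)
#' @param fs sampling rate, Hz
#' @param epoch_window epoch limits in seconds relative to onset, half-open
#' @param band frequency band: a name from [canonical_bands()] or `c(low, high)` Hz
#' @param planted_edges integer matrix with two columns (node pairs) or NULL
#' @param coupling_by_group named numeric, target task-window envelope
#'   correlation on planted edges for groups `A` and `B`; each in `[0, 1)` and
#'   below the feasibility cap of [coupling_to_loading()]
#' @param baseline_coupling target envelope correlation during the -5..0 s
#'   baseline (and throughout Physical trials)
#' @param mixing_strength zero-lag leakage coefficient in `[0, 1)`; 0 disables
#'   mixing
#' @param artefact_rates named numeric, per-trial probabilities of an amplitude
#'   `spike` and of a head-`motion` excursion
#' @param signal_scale_fT carrier scale so that clean data sit well below the
#'   2500 fT rejection threshold
#' @param spike_amplitude_fT amplitude of injected spikes (> 2500 fT)
#' @param modulator_cutoff_hz low-pass cutoff of the slow modulator
#' @param modulator_sigma2 variance of the log-modulator (sigma^2)
#' @param seed integer master seed; identical spec + seed reproduces identical
#'   output
#' @return an object of class `synth_spec`
#' @seealso [generate_source_dataset()]
#' @export
synth_spec <- function(n_nodes = 90L, n_subjects_per_group = 30L,
                       n_trials = 22L, fs = 600,
                       epoch_window = c(-5, 17), band = "beta",
                       planted_edges = NULL,
                       coupling_by_group = c(A = 0.15, B = 0.45),
                       baseline_coupling = 0,
                       mixing_strength = 0,
                       artefact_rates = c(spike = 0.04, motion = 0.04),
                       signal_scale_fT = 20,
                       spike_amplitude_fT = 3000,
                       modulator_cutoff_hz = 0.7,
                       modulator_sigma2 = 1,
                       seed = 1L) {
  band_hz <- resolve_band(band)
  if (band_hz[2L] >= fs / 2)
    stop(sprintf("band upper edge %g Hz is not below the Nyquist frequency %g Hz",
                 band_hz[2L], fs / 2))
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    storage.mode(planted_edges) <- "integer"
    if (ncol(planted_edges) != 2L) stop("planted_edges must have two columns")
    if (any(planted_edges < 1L | planted_edges > n_nodes))
      stop("planted edges reference nodes outside 1..n_nodes")
    if (any(planted_edges[, 1L] == planted_edges[, 2L]))
      stop("planted edges must join distinct nodes")
  }
  if (!all(c("A", "B") %in% names(coupling_by_group)))
    stop("coupling_by_group must name groups 'A' and 'B'")
  for (r in c(coupling_by_group, baseline = baseline_coupling)) {
    if (r < 0 || r >= 1) stop("coupling targets must lie in [0, 1)")
    coupling_to_loading(r, modulator_sigma2)  # errors if infeasible
  }
  if (mixing_strength < 0 || mixing_strength >= 1)
    stop("mixing_strength must lie in [0, 1)")
  if (any(artefact_rates < 0) || any(artefact_rates > 1))
    stop("artefact_rates must be probabilities")
  stopifnot(epoch_window[1L] < 0, epoch_window[2L] > 0)
  structure(list(
    n_nodes = as.integer(n_nodes),
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_trials = as.integer(n_trials), fs = fs,
    epoch_window = epoch_window, band = band, band_hz = band_hz,
    planted_edges = planted_edges,
    coupling_by_group = coupling_by_group,
    baseline_coupling = baseline_coupling,
    mixing_strength = mixing_strength,
    artefact_rates = artefact_rates,
    signal_scale_fT = signal_scale_fT,
    spike_amplitude_fT = spike_amplitude_fT,
    modulator_cutoff_hz = modulator_cutoff_hz,
    modulator_sigma2 = modulator_sigma2,
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("<synth_spec> %d nodes, %d+%d subjects, %d trials @ %g Hz, band %s [%g-%g Hz]\n",
              x$n_nodes, x$n_subjects_per_group, x$n_subjects_per_group,
              x$n_trials, x$fs, if (is.character(x$band)) x$band else "custom",
              x$band_hz[1L], x$band_hz[2L]))
  cat(sprintf("  planted edges: %d; coupling A=%.2f B=%.2f (baseline %.2f); mixing %.2f; seed %d\n",
              if (is.null(x$planted_edges)) 0L else nrow(x$planted_edges),
              x$coupling_by_group[["A"]], x$coupling_by_group[["B"]],
              x$baseline_coupling, x$mixing_strength, x$seed))
  invisible(x)
}

#' Map a target envelope correlation to a modulator factor loading
#'
#' For lognormal modulators `exp(sigma * z)` riding on independent Rayleigh
#' carrier envelopes, two nodes whose slow factors `z` correlate at `alpha`
#' show envelope correlation
#' `r = (pi/4) (exp(s2 * alpha) - 1) / (exp(s2) - pi/4)` with `s2 = sigma^2`.
#' This inverts that relation. Targets at or above the cap
#' `r_max = (pi/4)(exp(s2) - 1)/(exp(s2) - pi/4)` (about 0.70 for `s2 = 1`)
#' are infeasible under this generator and rejected.
#'
#' @param rho target envelope correlation in `[0, r_max)`
#' @param sigma2 variance of the log-modulator
#' @return factor correlation `alpha` in `[0, 1]`
#' @export
coupling_to_loading <- function(rho, sigma2 = 1) {
  k <- pi / 4
  r_max <- k * (exp(sigma2) - 1) / (exp(sigma2) - k)
  if (rho < 0 || rho >= r_max)
    stop(sprintf("envelope-correlation target %.3f outside feasible range [0, %.3f)",
                 rho, r_max))
  log(1 + rho * (exp(sigma2) - k) / k) / sigma2
}

# Gaussian noise with a prescribed magnitude response, synthesized in the
# frequency domain (circularly stationary, no edge transients), standardized
# per row.
shaped_noise <- function(n_series, n_samp, H) {
  keep <- which(H > 1e-4 * max(H))
  Z <- matrix(0i, n_samp, n_series)
  Z[keep, ] <- complex(real = stats::rnorm(length(keep) * n_series),
                       imaginary = stats::rnorm(length(keep) * n_series)) *
    H[keep]
  x <- t(Re(stats::mvfft(Z, inverse = TRUE)))
  x <- x - rowMeans(x)
  x / apply(x, 1L, stats::sd)
}

two_sided_freqs <- function(n_samp, fs) {
  f <- (seq_len(n_samp) - 1L) / n_samp * fs
  pmin(f, fs - f)
}

# Slow standardized Gaussian noise: 2nd-order low-pass magnitude response.
slow_noise <- function(n_series, n_samp, fs, cutoff) {
  f <- two_sided_freqs(n_samp, fs)
  shaped_noise(n_series, n_samp, 1 / sqrt(1 + (f / cutoff)^4))
}

# Band-limited unit-variance carriers matching the analysis FIR's magnitude
# response.
band_carriers <- function(n_series, n_samp, fs, band_hz) {
  b <- design_band_fir(band_hz, fs)
  H <- if (n_samp >= length(b)) {
    Mod(stats::fft(c(b, numeric(n_samp - length(b)))))
  } else {
    # DFT of b on the n_samp-point grid
    k <- seq_len(n_samp) - 1L
    j <- seq_along(b) - 1L
    Mod(exp(-2i * pi * outer(k / n_samp, j)) %*% b)[, 1L]
  }
  shaped_noise(n_series, n_samp, H)
}

#' Generate a two-group source-level dataset with known coupling
#'
#' Produces one [epoch_set] per subject (groups `A` then `B`) plus a
#' `synth_truth` record of the planted structure. Planted coupling is active
#' during the task portion (t >= 0) of Social trials; the baseline portion and
#' Physical trials couple at `baseline_coupling`. Nodes within one connected
#' component of the planted graph share a single slow factor, so for
#' node-disjoint planted edges coupling is exactly pairwise. When
#' `mixing_strength > 0` the node series are mixed by a zero-lag unit-diagonal
#' matrix after generation; amplitude-spike artefacts are injected after
#' mixing.
#'
#' @param spec a [synth_spec()]
#' @return a list of class `synth_dataset` with elements `subjects` (list of
#'   `epoch_set`), `group` (named vector), `truth` (`synth_truth`), `spec`
#' @export
generate_source_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  fs <- spec$fs
  n_samp <- round((spec$epoch_window[2L] - spec$epoch_window[1L]) * fs)
  time <- spec$epoch_window[1L] + (seq_len(n_samp) - 1L) / fs
  sigma <- sqrt(spec$modulator_sigma2)

  # component membership of the planted graph
  comp_of <- rep(NA_integer_, n)
  if (!is.null(spec$planted_edges) && nrow(spec$planted_edges) > 0L) {
    g <- igraph::graph_from_edgelist(spec$planted_edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    mem <- igraph::components(g)$membership
    involved <- sort(unique(as.integer(spec$planted_edges)))
    comp_of[involved] <- mem[involved]
  }
  n_comp <- if (all(is.na(comp_of))) 0L else max(comp_of, na.rm = TRUE)

  a_task <- sqrt(vapply(spec$coupling_by_group,
                        coupling_to_loading, numeric(1L),
                        sigma2 = spec$modulator_sigma2))
  a_base <- sqrt(coupling_to_loading(spec$baseline_coupling,
                                     spec$modulator_sigma2))

  # zero-lag leakage: unit diagonal, a couple of symmetric off-diagonal
  # couplings per node scaled by mixing_strength
  M <- diag(n)
  if (spec$mixing_strength > 0) {
    n_pairs <- n  # on average two leakage partners per node
    pi_ <- sample.int(n, n_pairs, replace = TRUE)
    pj_ <- sample.int(n, n_pairs, replace = TRUE)
    keep <- pi_ != pj_
    coef <- spec$mixing_strength * stats::runif(n_pairs, 0.6, 1)
    for (k in which(keep)) {
      M[pi_[k], pj_[k]] <- coef[k]
      M[pj_[k], pi_[k]] <- coef[k]
    }
    diag(M) <- 1
  }

  groups <- rep(c("A", "B"), each = spec$n_subjects_per_group)
  ids <- sprintf("S%02d", seq_along(groups))
  names(groups) <- ids
  conditions <- rep(c("Social", "Physical"), length.out = spec$n_trials)

  artefacts <- list()
  subjects <- vector("list", length(ids))
  names(subjects) <- ids

  for (s in seq_along(ids)) {
    grp <- groups[s]
    dat <- array(0, c(spec$n_trials, n, n_samp))
    for (tr in seq_len(spec$n_trials)) {
      carr <- band_carriers(n, n_samp, fs, spec$band_hz)
      own <- slow_noise(n, n_samp, fs, spec$modulator_cutoff_hz)
      z <- own
      if (n_comp > 0L) {
        shared <- slow_noise(n_comp, n_samp, fs, spec$modulator_cutoff_hz)
        a_on <- if (conditions[tr] == "Social") a_task[[grp]] else a_base
        a_vec <- ifelse(time < 0, a_base, a_on)
        for (v in which(!is.na(comp_of))) {
          g_c <- shared[comp_of[v], ]
          z[v, ] <- a_vec * g_c + sqrt(1 - a_vec^2) * own[v, ]
        }
      }
      m <- exp(sigma * z)
      x <- spec$signal_scale_fT * m * carr
      if (spec$mixing_strength > 0) x <- M %*% x
      dat[tr, , ] <- x
    }
    # artefact injection after mixing, before storage
    spike_tr <- which(stats::runif(spec$n_trials) < spec$artefact_rates[["spike"]])
    for (tr in spike_tr) {
      node <- sample.int(n, 1L)
      t0 <- sample.int(n_samp - 3L, 1L)
      dat[tr, node, t0:(t0 + 2L)] <- spec$spike_amplitude_fT * sample(c(-1, 1), 1L)
      artefacts[[length(artefacts) + 1L]] <-
        data.frame(subject = ids[s], trial = tr, type = "spike")
    }
    motion_tr <- which(stats::runif(spec$n_trials) < spec$artefact_rates[["motion"]])
    for (tr in motion_tr)
      artefacts[[length(artefacts) + 1L]] <-
        data.frame(subject = ids[s], trial = tr, type = "motion")
    subjects[[s]] <- epoch_set(dat, fs, time = time, condition = conditions,
                               level = "node")
  }

  realized <- NULL
  if (!is.null(spec$planted_edges) && nrow(spec$planted_edges) > 0L) {
    realized <- realized_coupling(spec, a_task, duration_s = 60)
  }

  truth <- structure(list(
    planted_edges = spec$planted_edges,
    component_of = comp_of,
    realized_coupling = realized,
    mixing = M,
    artefacts = if (length(artefacts)) do.call(rbind, artefacts) else NULL,
    seed = spec$seed
  ), class = "synth_truth")

  structure(list(subjects = subjects, group = groups, truth = truth,
                 spec = spec), class = "synth_dataset")
}

# Measured planted-edge envelope correlations per group on one noiseless,
# unmixed calibration realization in the task state.
realized_coupling <- function(spec, a_task, duration_s = 60) {
  n_samp <- round(duration_s * spec$fs)
  comp_nodes <- sort(unique(as.integer(spec$planted_edges)))
  idx <- match(seq_len(spec$n_nodes), comp_nodes)
  g <- igraph::graph_from_edgelist(spec$planted_edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, spec$n_nodes - igraph::vcount(g)))
  mem <- igraph::components(g)$membership
  sigma <- sqrt(spec$modulator_sigma2)
  out <- list()
  for (grp in c("A", "B")) {
    carr <- band_carriers(length(comp_nodes), n_samp, spec$fs, spec$band_hz)
    own <- slow_noise(length(comp_nodes), n_samp, spec$fs, spec$modulator_cutoff_hz)
    shared <- slow_noise(max(mem[comp_nodes]), n_samp, spec$fs,
                         spec$modulator_cutoff_hz)
    a <- a_task[[grp]]
    z <- a * shared[mem[comp_nodes], , drop = FALSE] + sqrt(1 - a^2) * own
    env <- Mod(analytic_signal(exp(sigma * z) * carr))
    r <- numeric(nrow(spec$planted_edges))
    for (e in seq_len(nrow(spec$planted_edges)))
      r[e] <- stats::cor(env[idx[spec$planted_edges[e, 1L]], ],
                         env[idx[spec$planted_edges[e, 2L]], ])
    out[[grp]] <- r
  }
  out
}

#' Project a source-level subject to sensors with a toy forward model
#'
#' Sensor data are a random unit-norm-column lead-field projection of the node
#' series plus white noise at the requested amplitude SNR, laid out as a
#' continuous recording with event markers, static fiducials, and optional
#' scripted rigid translations and sensor spikes. The lead field is stored with
#' the recording so beamformer tests can close the loop.
#'
#' @param epochs a source-level [epoch_set] (one subject)
#' @param n_channels number of sensors; must be at least the node count
#' @param snr amplitude signal-to-noise ratio (> 0)
#' @param motion_events optional data.frame `trial, dx, dy, dz` (mm): rigid
#'   translation of all fiducials during the trial
#' @param spike_events optional data.frame `trial, amplitude_fT`: one-sample
#'   sensor spike within the trial
#' @param gap_s silent gap between consecutive trials, seconds
#' @param seed integer seed
#' @return a [continuous_recording] with `leadfield` attached
#' @export
generate_sensor_dataset <- function(epochs, n_channels, snr,
                                    motion_events = NULL, spike_events = NULL,
                                    gap_s = 2, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (snr <= 0) stop("requested SNR must be positive")
  n_nodes <- dim(epochs$data)[2L]
  if (n_channels < n_nodes)
    stop("n_channels must be at least the number of source nodes")
  set.seed(seed)
  fs <- epochs$fs
  n_trials <- dim(epochs$data)[1L]
  n_samp <- dim(epochs$data)[3L]
  gap <- round(gap_s * fs)
  total <- n_trials * (n_samp + gap) + gap

  G <- matrix(stats::rnorm(n_channels * n_nodes), n_channels)
  G <- sweep(G, 2L, sqrt(colSums(G^2)), "/")

  sens <- matrix(0, n_channels, total)
  onset <- integer(n_trials)
  pre <- round(-epochs$time[1L] * fs)
  for (tr in seq_len(n_trials)) {
    start <- gap + (tr - 1L) * (n_samp + gap) + 1L
    sens[, start:(start + n_samp - 1L)] <- G %*% epochs$data[tr, , ]
    onset[tr] <- start + pre
  }
  sig_rms <- sqrt(mean(sens^2))
  sens <- sens + matrix(stats::rnorm(n_channels * total, sd = sig_rms / snr),
                        n_channels)

  fid0 <- rbind(nasion = c(0, 90, 0), lpa = c(-75, 0, 0), rpa = c(75, 0, 0))
  fid <- array(rep(fid0, total), c(3L, 3L, total))
  if (!is.null(motion_events)) {
    for (k in seq_len(nrow(motion_events))) {
      tr <- motion_events$trial[k]
      start <- gap + (tr - 1L) * (n_samp + gap) + 1L
      rng <- start:(start + n_samp - 1L)
      d <- c(motion_events$dx[k], motion_events$dy[k], motion_events$dz[k])
      fid[, , rng] <- fid[, , rng] + d[col(fid0)]
    }
  }
  if (!is.null(spike_events)) {
    for (k in seq_len(nrow(spike_events))) {
      tr <- spike_events$trial[k]
      start <- gap + (tr - 1L) * (n_samp + gap) + 1L
      at <- start + sample.int(n_samp, 1L) - 1L
      sens[sample.int(n_channels, 1L), at] <- spike_events$amplitude_fT[k]
    }
  }
  continuous_recording(sens, fs,
                       events = data.frame(sample = onset,
                                           condition = epochs$condition),
                       fiducials = fid, leadfield = G)
}

#' Generate behavioural error counts from network strengths
#'
#' Counts are a rounded, floored-at-zero linear function of each subject's mean
#' network strength with a group-specific slope plus Gaussian noise, emulating
#' scored description errors (vague references, misattributions, inconsistent
#' propositions).
#'
#' @param strengths numeric, one mean network strength per subject
#' @param group character/factor of group labels (`A`/`B`), same length
#' @param slope_by_group named numeric slopes for groups `A` and `B`
#' @param intercept common intercept
#' @param noise_sd standard deviation of the additive noise (>= 0)
#' @param seed integer seed
#' @return data.frame `subject, group, strength, errors`
#' @export
generate_behaviour <- function(strengths, group,
                               slope_by_group = c(A = -0.5, B = 0),
                               intercept = 2, noise_sd = 1, seed = 1L) {
  if (length(strengths) != length(group))
    stop("one strength per subject required")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  mu <- intercept + slope_by_group[as.character(group)] * strengths
  counts <- pmax(0, round(mu + stats::rnorm(length(strengths), sd = noise_sd)))
  data.frame(subject = names(strengths) %||% sprintf("S%02d", seq_along(strengths)),
             group = as.character(group), strength = as.numeric(strengths),
             errors = as.numeric(counts), row.names = NULL)
}
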