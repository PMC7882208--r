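test_that("band FIR filters pass and stop where specified", {
  fs <- 600
  t <- (0:(fs * 10 - 1)) / fs
  tone10 <- matrix(sin(2 * pi * 10 * t), 1L)
  mid <- 2000:4000
  in_alpha <- band_filter(tone10, "alpha", fs)
  expect_lt(abs(max(abs(in_alpha[1L, mid])) - 1), 0.05)
  in_theta <- band_filter(tone10, "theta", fs)
  expect_lt(max(abs(in_theta[1L, mid])), 0.10)
  expect_equal(max(abs(band_filter(matrix(0, 1L, 1000L), "beta", fs))), 0)
  expect_error(band_filter(tone10, c(200, 400), fs), "Nyquist")
  # >= 40 dB attenuation one octave outside each canonical band
  for (bn in names(canonical_bands())) {
    band <- canonical_bands()[[bn]]
    b <- design_band_fir(bn, fs)
    resp <- fir_response(b, c(band[1L] / 2, min(2 * band[2L], 290)), fs)
    expect_lt(20 * log10(max(resp)), -40)
    inband <- fir_response(b, mean(band), fs)
    expect_lt(abs(inband - 1), 0.05)
  }
})

test_that("symmetric orthogonalization zeroes all pairwise correlations", {
  set.seed(5)
  for (n in c(3L, 12L, 40L)) {
    x <- matrix(rnorm(n * 1500L), n)
    o <- orthogonalize(x)
    cc <- cor(t(o))
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  }
  # a leaked node is fully decorrelated from its source
  x1 <- rnorm(1000L)
  x2 <- rnorm(1000L)
  z <- 0.7 * x1 + 0.3 * rnorm(1000L)
  o <- orthogonalize(rbind(x1, x2, z))
  expect_lt(abs(cor(o[3L, ], o[1L, ])), 1e-8)
  # already-orthogonal zero-mean series are a fixed point up to scaling
  q <- qr.Q(qr(cbind(1, matrix(rnorm(500 * 3), 500L))))[, 2:4]
  xo <- t(q %*% diag(c(2, 5, 1)))
  oo <- orthogonalize(xo)
  for (k in 1:3) expect_gt(abs(cor(oo[k, ], xo[k, ])), 1 - 1e-8)
  expect_error(orthogonalize(matrix(rnorm(10), 5L, 2L)), "samples")
  expect_error(orthogonalize(rbind(x1, x1, x2)), "rank")
})

test_that("orthogonalization is near-optimal among orthogonal candidates", {
  set.seed(6)
  x <- matrix(rnorm(3 * 400L), 3L)
  o <- orthogonalize(x)
  d_opt <- sqrt(sum((sweep(x, 1L, rowMeans(x)) - o)^2))
  norms <- sqrt(rowSums(o^2))
  d_rand <- vapply(1:1000, function(k) {
    q <- qr.Q(qr(matrix(rnorm(400 * 3), 400L)))
    cand <- t(q %*% diag(norms))
    sqrt(sum((sweep(x, 1L, rowMeans(x)) - cand)^2))
  }, numeric(1L))
  expect_lte(d_opt, min(d_rand))
})

test_that("Hilbert envelopes demodulate amplitude correctly", {
  fs <- 600
  t <- (0:(fs * 5 - 1)) / fs
  mid <- 600:2400
  tone <- 3 * sin(2 * pi * 10 * t)
  env <- envelope(matrix(tone, 1L))
  expect_lt(abs(mean(env[1L, mid]) - 3) / 3, 0.02)
  # AM tone: envelope tracks the modulator
  mod_ <- 1 + 0.5 * sin(2 * pi * 0.3 * t)
  am <- mod_ * sin(2 * pi * 10 * t)
  env_am <- envelope(matrix(am, 1L))
  expect_gt(cor(env_am[1L, mid], mod_[mid]), 0.98)
  expect_equal(max(envelope(matrix(0, 2L, 100L))), 0)
  expect_true(all(env >= 0))
  # agreement with an independent time-domain Hilbert transformer
  x <- as.numeric(band_filter(matrix(rnorm(3000), 1L), "alpha", fs))
  e1 <- as.numeric(envelope(matrix(x, 1L)))
  e2 <- oracle_envelope(x)
  expect_lt(max(abs(e1[500:2500] - e2[500:2500])) / max(e1), 0.02)
})

test_that("windowed AEC aggregates trials symmetrically", {
  set.seed(8)
  fs <- 100
  n_samp <- 2200L
  env <- matrix(abs(rnorm(3L * n_samp)) + 0.5, 3L)
  env[2L, ] <- env[1L, ]  # identical envelopes
  ep <- epoch_set(array(env, c(1L, 3L, n_samp)), fs, t0 = -5)
  aec <- windowed_aec(ep, windows = list(baseline = c(-5, 0), task = c(0, 17)))
  expect_equal(aec$task[1L, 2L], 1, tolerance = 1e-6)
  expect_identical(aec$task, t(aec$task))
  expect_equal(diag(aec$task), rep(0, 3L))
  # independent white envelopes: null correlations are narrow
  big <- epoch_set(array(abs(matrix(rnorm(20L * 3000L), 20L)) + 0.2,
                         c(1L, 20L, 3000L)), 100, t0 = 0)
  null_aec <- windowed_aec(big, windows = list(all = c(0, 30)))$all
  vals <- abs(null_aec[upper.tri(null_aec)])
  expect_gte(mean(vals < 0.06), 0.95)
  # zero-variance envelope triggers the guarded warning
  flat <- env
  flat[3L, ] <- 1
  epf <- epoch_set(array(flat, c(1L, 3L, n_samp)), fs, t0 = -5)
  expect_warning(res <- windowed_aec(epf, windows = list(task = c(0, 17))),
                 "zero-variance")
  expect_equal(res$task[3L, 1L], 0)
})

test_that("fractional-change baselining guards near-zero references", {
  task <- matrix(c(0, 0.3, 0.3, 0), 2L)
  base <- matrix(c(0, 0.2, 0.2, 0), 2L)
  out <- baseline_fractional_change(task, base)
  expect_equal(out[1L, 2L], 0.5)
  same <- baseline_fractional_change(base, base)
  expect_equal(max(abs(same)), 0)
  # sign of a negative baseline is preserved
  neg <- baseline_fractional_change(matrix(c(0, 0.1, 0.1, 0), 2L),
                                    matrix(c(0, -0.2, -0.2, 0), 2L))
  expect_equal(neg[1L, 2L], (0.1 + 0.2) / -0.2)
  # tiny baseline: value hits the eps guard and the entry is masked
  tiny <- baseline_fractional_change(matrix(c(0, 0.2, 0.2, 0), 2L),
                                     matrix(c(0, 1e-9, 1e-9, 0), 2L),
                                     eps = 1e-3)
  expect_equal(tiny[1L, 2L], 200)
  expect_true(attr(tiny, "mask")[1L, 2L])
  expect_false(attr(out, "mask")[1L, 2L])
})

test_that("planted edges rank at the top of the AEC distribution", {
  hits <- vapply(1:20, function(k) {
    sp <- tiny_spec(n_nodes = 40L, n_subjects_per_group = 1L, n_trials = 1L,
                    epoch_window = c(-5, 17),
                    planted_edges = rbind(c(1L, 2L)),
                    coupling_by_group = c(A = 0.6, B = 0.6), seed = 400L + k)
    ds <- generate_source_dataset(sp)
    a <- compute_aec(ds$subjects[[1L]], "alpha",
                     windows = list(baseline = c(-5, 0), task = c(0, 17)),
                     orthogonalize = FALSE)
    m <- a$raw$task
    vals <- m[upper.tri(m)]
    rank_planted <- mean(vals >= m[1L, 2L])
    rank_planted <= 0.05
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})

test_that("the AEC pipeline runs filter, orthogonalize, envelope, window, baseline", {
  sp <- tiny_spec(n_nodes = 6L, n_subjects_per_group = 1L, n_trials = 4L,
                  seed = 9L, mixing_strength = 0.4)
  ds <- generate_source_dataset(sp)
  a <- compute_aec(ds$subjects[[1L]], "alpha")
  expect_s3_class(a, "aec_result")
  expect_named(a$raw, c("baseline", "0-5", "5-10", "10-15"))
  expect_named(a$baselined, c("0-5", "5-10", "10-15"))
  for (m in a$raw) {
    expect_identical(m, t(m))
    expect_true(all(abs(m[upper.tri(m)]) <= 1))
  }
  expect_true(is.matrix(attr(a$baselined[["0-5"]], "mask")))
  expect_equal(a$n_trials, 2L)  # Social trials only
})
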