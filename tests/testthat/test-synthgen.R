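test_that("spec validation rejects impossible settings", {
  expect_error(tiny_spec(band = c(30, 80), fs = 150), "Nyquist")
  expect_error(tiny_spec(coupling_by_group = c(A = 0.9, B = 0.2)), "feasible")
  expect_error(tiny_spec(planted_edges = rbind(c(1, 1))), "distinct")
  expect_error(tiny_spec(planted_edges = rbind(c(1, 99))), "outside")
  expect_error(tiny_spec(mixing_strength = 1.2), "mixing_strength")
  expect_error(generate_behaviour(1:3, c("A", "A", "B"), noise_sd = -1),
               "noise_sd")
})

test_that("identical spec and seed reproduce identical output", {
  sp <- tiny_spec(n_nodes = 6L, n_trials = 2L, seed = 33L,
                  planted_edges = rbind(c(1L, 2L)),
                  coupling_by_group = c(A = 0.3, B = 0.5),
                  mixing_strength = 0.3,
                  artefact_rates = c(spike = 0.3, motion = 0.3))
  d1 <- generate_source_dataset(sp)
  d2 <- generate_source_dataset(sp)
  expect_identical(d1$subjects[[1L]]$data, d2$subjects[[1L]]$data)
  expect_identical(d1$truth$mixing, d2$truth$mixing)
  expect_identical(d1$truth$artefacts, d2$truth$artefacts)
})

test_that("uncoupled, unmixed nodes have near-zero envelope correlations", {
  sp <- tiny_spec(n_nodes = 10L, n_subjects_per_group = 1L, n_trials = 5L,
                  epoch_window = c(-5, 17), seed = 21L)
  ds <- generate_source_dataset(sp)
  rs <- c()
  for (tr in 1:5) {
    env <- envelope(ds$subjects[[1L]]$data[tr, , ])
    cc <- cor(t(env))
    rs <- c(rs, cc[upper.tri(cc)])
  }
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("planted coupling is calibrated to its target", {
  # one planted edge, target 0.6, 120 s of task signal, replicated
  measured <- vapply(1:10, function(k) {
    sp <- tiny_spec(n_nodes = 2L, n_subjects_per_group = 1L, n_trials = 1L,
                    epoch_window = c(-5, 115),
                    planted_edges = rbind(c(1L, 2L)),
                    coupling_by_group = c(A = 0.6, B = 0.6), seed = 100L + k)
    ds <- generate_source_dataset(sp)
    task <- ds$subjects[[1L]]$time >= 0
    env <- envelope(ds$subjects[[1L]]$data[1L, , task])
    cor(env[1L, ], env[2L, ])
  }, numeric(1L))
  expect_gt(mean(measured), 0.5)
  expect_lt(mean(measured), 0.7)
  # truth records realized coupling near the target for both groups
  realized <- vapply(1:10, function(k) {
    sp <- tiny_spec(n_nodes = 4L, n_subjects_per_group = 1L, n_trials = 1L,
                    planted_edges = rbind(c(1L, 2L)),
                    coupling_by_group = c(A = 0.6, B = 0.3), seed = 500L + k)
    unlist(generate_source_dataset(sp)$truth$realized_coupling)
  }, numeric(2L))
  expect_lt(abs(mean(realized["A", ]) - 0.6), 0.1)
  expect_lt(abs(mean(realized["B", ]) - 0.3), 0.1)
})

test_that("zero-lag mixing leaks envelopes between non-planted pairs", {
  sp <- tiny_spec(n_nodes = 10L, n_subjects_per_group = 1L, n_trials = 2L,
                  mixing_strength = 0.5, seed = 3L)
  ds <- generate_source_dataset(sp)
  expect_equal(diag(ds$truth$mixing), rep(1, 10L))
  a <- compute_aec(ds$subjects[[1L]], "alpha", orthogonalize = FALSE,
                   condition = NULL)
  raw <- a$raw[["5-10"]]
  expect_gt(max(raw[upper.tri(raw)]), 0.3)
  # leakage is zero-lag: the strongest cross-correlation sits at lag 0
  pair <- which(ds$truth$mixing == max(ds$truth$mixing[upper.tri(ds$truth$mixing)]),
                arr.ind = TRUE)[1L, ]
  x <- ds$subjects[[1L]]$data[1L, pair[1L], ]
  y <- ds$subjects[[1L]]$data[1L, pair[2L], ]
  cc <- ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], 0)
})

test_that("sensor projection supports rejection and beamformer closure", {
  sp <- tiny_spec(n_nodes = 5L, n_subjects_per_group = 1L, n_trials = 4L,
                  epoch_window = c(-2, 4), seed = 8L)
  ds <- generate_source_dataset(sp)
  expect_error(generate_sensor_dataset(ds$subjects[[1L]], 20L, snr = -1),
               "SNR")
  expect_error(generate_sensor_dataset(ds$subjects[[1L]], 3L, snr = 10),
               "at least")
  rec <- generate_sensor_dataset(
    ds$subjects[[1L]], n_channels = 20L, snr = 1e6,
    motion_events = data.frame(trial = 2L, dx = 12, dy = 0, dz = 0),
    spike_events = data.frame(trial = 3L, amplitude_fT = 3000),
    seed = 9L)
  epochs <- epoch_recording(rec, window = c(-2, 4))
  epochs <- reject_amplitude(epochs)
  disp <- head_motion_displacement(rec$fiducials)
  epochs <- reject_motion(epochs, disp)
  expect_false(epochs$kept[2L])
  expect_identical(epochs$reason[2L], "motion")
  expect_false(epochs$kept[3L])
  expect_identical(epochs$reason[3L], "amplitude")
  expect_true(epochs$kept[1L])
  # near-noiseless beamformer reconstruction recovers the sources
  C <- sensor_covariance(epochs)
  w <- lcmv_weights(rec$leadfield, C, 0.05)
  src <- project_to_sources(epochs, w)
  r <- abs(cor(src$data[1L, 1L, ], ds$subjects[[1L]]$data[1L, 1L, ]))
  expect_gt(r, 0.95)
})

test_that("behavioural counts follow the group-specific linear model", {
  strengths <- c(1.2, 2.7, 3.5, 0.4)
  b <- generate_behaviour(strengths, c("A", "A", "B", "B"),
                          slope_by_group = c(A = 1, B = 1), intercept = 0,
                          noise_sd = 0, seed = 1L)
  expect_equal(b$errors, round(strengths))
  b2 <- generate_behaviour(rep(10, 4L), c("A", "A", "B", "B"),
                           slope_by_group = c(A = -1, B = 0), intercept = 2,
                           noise_sd = 0, seed = 1L)
  expect_equal(b2$errors, c(0, 0, 2, 2))  # floored at zero
})

test_that("a planted group slope is detected by the strength model", {
  # interaction information is capped near t ~ sqrt(n)/2 by count rounding,
  # so the power check runs at n = 60 per group
  set.seed(77)
  hits <- vapply(1:60, function(k) {
    g <- rep(c("A", "B"), each = 60L)
    s <- rnorm(120L, mean = 5, sd = 1)
    b <- generate_behaviour(s, g, slope_by_group = c(A = -1.5, B = 0),
                            intercept = 12, noise_sd = 1,
                            seed = sample.int(1e6, 1L))
    strength_glm(b$strength, b$group, b$errors)$p <= 0.05
  }, logical(1L))
  expect_gte(mean(hits), 0.8)
})
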