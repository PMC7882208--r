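sym_mats <- function(n_subj, n_nodes, f = function() rnorm(1)) {
  arr <- array(0, c(n_subj, n_nodes, n_nodes))
  ut <- upper.tri(matrix(0, n_nodes, n_nodes))
  for (s in seq_len(n_subj)) {
    m <- matrix(0, n_nodes, n_nodes)
    m[ut] <- replicate(sum(ut), f())
    arr[s, , ] <- m + t(m)
  }
  arr
}

test_that("edgewise t matches a direct formula evaluation", {
  set.seed(2)
  arr <- sym_mats(6L, 4L)
  gs <- group_sample(arr, rep(c("A", "B"), each = 3L))
  for (ve in c(TRUE, FALSE)) {
    tm <- edgewise_t(gs, var_equal = ve)
    for (e in list(c(1L, 2L), c(2L, 4L), c(3L, 4L))) {
      ref <- oracle_t2(arr[1:3, e[1L], e[2L]], arr[4:6, e[1L], e[2L]],
                       var_equal = ve)
      expect_equal(tm[e[1L], e[2L]], ref, tolerance = 1e-12)
      # and against stats::t.test
      ht <- t.test(arr[1:3, e[1L], e[2L]], arr[4:6, e[1L], e[2L]],
                   var.equal = ve)
      expect_equal(tm[e[1L], e[2L]], unname(ht$statistic), tolerance = 1e-10)
    }
    expect_identical(tm, t(tm))
  }
  # identical data in both groups -> exactly zero t
  arr0 <- array(0, c(4L, 3L, 3L))
  arr0[1L, , ] <- arr0[3L, , ] <- sym_mats(1L, 3L)[1L, , ]
  arr0[2L, , ] <- arr0[4L, , ] <- sym_mats(1L, 3L)[1L, , ]
  tm0 <- edgewise_t(group_sample(arr0, c("A", "A", "B", "B")))
  expect_lt(max(abs(tm0)), 1e-10)
  # zero variance in both groups -> 0 with a warning
  cst <- array(1, c(4L, 3L, 3L))
  for (s in 1:4) diag(cst[s, , ]) <- 0
  expect_warning(tc <- edgewise_t(group_sample(cst, c("A", "A", "B", "B"))),
                 "zero variance")
  expect_equal(max(abs(tc)), 0)
})

test_that("relabelling groups flips every edgewise t exactly", {
  set.seed(12)
  arr <- sym_mats(8L, 5L)
  g <- rep(c("A", "B"), each = 4L)
  t1 <- edgewise_t(group_sample(arr, g))
  t2 <- edgewise_t(group_sample(arr, ifelse(g == "A", "B", "A")))
  expect_equal(t1, -t2, tolerance = 1e-14)
})

test_that("supra-threshold components follow graph topology", {
  n <- 5L
  tm <- matrix(0, n, n)
  set_edge <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  tm <- set_edge(tm, 1L, 2L, 3.0)
  tm <- set_edge(tm, 2L, 3L, 2.8)
  tm <- set_edge(tm, 4L, 5L, 2.6)
  tm <- set_edge(tm, 1L, 4L, 1.0)
  comps <- supra_threshold_components(tm, tau = 2.5, direction = "A>B")
  expect_length(comps, 2L)
  expect_equal(vapply(comps, `[[`, integer(1L), "extent"), c(2L, 1L))
  expect_equal(comps[[1L]]$nodes, 1:3)
  # threshold boundary: t exactly at tau is kept
  expect_length(supra_threshold_components(tm, tau = 2.6), 2L)
  # direction B>A sees nothing here
  expect_length(supra_threshold_components(tm, tau = 2.5, direction = "B>A"), 0L)
  # empty result when nothing survives
  expect_length(supra_threshold_components(tm, tau = 10), 0L)
  # complete graph on 6 nodes -> one component of extent 15
  full <- matrix(5, 6L, 6L); diag(full) <- 0
  comps6 <- supra_threshold_components(full, tau = 2.7)
  expect_length(comps6, 1L)
  expect_equal(comps6[[1L]]$extent, 15L)
})

test_that("union-find max extent agrees with igraph components", {
  set.seed(20)
  for (k in 1:50) {
    n <- sample(4:15, 1L)
    m <- sample(0:12, 1L)
    if (m == 0L) {
      edges <- matrix(integer(0), 0L, 2L)
    } else {
      edges <- t(replicate(m, sample.int(n, 2L)))
    }
    uf <- aecnet:::max_extent_uf(edges[, 1L], edges[, 2L])
    expect_identical(as.integer(uf), as.integer(oracle_max_extent(edges, n)))
  }
})

test_that("monotonicity: raising tau never grows a component", {
  set.seed(31)
  arr <- sym_mats(12L, 8L)
  gs <- group_sample(arr, rep(c("A", "B"), each = 6L))
  tm <- edgewise_t(gs)
  taus <- c(1, 1.5, 2, 2.5, 3)
  max_ext <- vapply(taus, function(tau) {
    comps <- supra_threshold_components(tm, tau)
    if (length(comps)) comps[[1L]]$extent else 0L
  }, integer(1L))
  expect_true(all(diff(max_ext) <= 0L))
})

test_that("the permutation test controls its p-value floor and seeds", {
  set.seed(41)
  # strong planted difference: observed component p hits the 1/(P+1) floor
  arr <- sym_mats(12L, 6L)
  arr[1:6, 1L, 2L] <- arr[1:6, 2L, 1L] <- arr[1:6, 1L, 2L] + 10
  arr[1:6, 2L, 3L] <- arr[1:6, 3L, 2L] <- arr[1:6, 2L, 3L] + 10
  gs <- group_sample(arr, rep(c("A", "B"), each = 6L))
  res <- nbs_test(gs, tau = 2.7, n_perm = 100L, direction = "A>B", seed = 1L)
  s_obs <- res$components[[1L]]$extent
  expect_equal(res$components[[1L]]$fwe_p,
               (1 + sum(res$null_max_extent >= s_obs)) / 101)
  expect_gte(res$components[[1L]]$fwe_p, 1 / 101)
  expect_warning(nbs_test(gs, tau = 2.7, n_perm = 50L, seed = 1L),
                 "resolution")
  # identical seed reproduces the permutation null exactly
  r1 <- nbs_test(gs, tau = 2.7, n_perm = 200L, seed = 7L)
  r2 <- nbs_test(gs, tau = 2.7, n_perm = 200L, seed = 7L)
  expect_identical(r1$null_max_extent, r2$null_max_extent)
  # FWE p bounded within [1/(P+1), 1]
  expect_true(all(vapply(r1$components, `[[`, numeric(1L), "fwe_p") >= 1 / 201))
})

test_that("exchanging group labels swaps the two contrast directions", {
  set.seed(51)
  arr <- sym_mats(10L, 5L)
  g <- rep(c("A", "B"), each = 5L)
  gs <- group_sample(arr, g)
  gs_sw <- group_sample(arr, ifelse(g == "A", "B", "A"))
  a <- nbs_test(gs, tau = 1.5, n_perm = 1000L, direction = "A>B", seed = 3L)
  b <- nbs_test(gs_sw, tau = 1.5, n_perm = 1000L, direction = "B>A", seed = 3L)
  expect_equal(lapply(a$components, `[[`, "edges"),
               lapply(b$components, `[[`, "edges"))
  expect_equal(vapply(a$components, `[[`, integer(1L), "extent"),
               vapply(b$components, `[[`, integer(1L), "extent"))
  # the permutation nulls agree in distribution (complement subsets are drawn,
  # so draw-by-draw identity is not expected)
  ks <- suppressWarnings(ks.test(a$null_max_extent, b$null_max_extent))
  expect_gt(ks$p.value, 0.001)
})

test_that("run_all covers bands, windows and both directions", {
  set.seed(61)
  arr <- sym_mats(8L, 5L)
  gs <- group_sample(arr, rep(c("A", "B"), each = 4L))
  expect_error(nbs_run_all(list()), "empty")
  res <- nbs_run_all(list(alpha = list(`0-5` = gs)), tau = 2.7,
                     n_perm = 120L, seed = 2L)
  expect_named(res, "alpha")
  expect_named(res$alpha, "0-5")
  expect_length(res$alpha[["0-5"]], 2L)
  expect_named(res$alpha[["0-5"]], c("A>B", "B>A"))
  expect_warning(
    nbs_run_all(list(alpha = list(`0-5` = gs, `5-10` = NULL)),
                n_perm = 120L, seed = 2L),
    "skipped")
})
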