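# Network-Based Statistic: mass-univariate edgewise two-sample tests, strict
# supra-threshold component formation, and permutation family-wise error
# control via the maximal component extent.

#' Bundle per-subject connectivity matrices with group labels
#'
#' @param matrices `subjects x nodes x nodes` array, or list of symmetric
#'   matrices sharing one node ordering
#' @param group character/factor of labels `A`/`B`, one per subject
#' @return object of class `group_sample`
#' @export
group_sample <- function(matrices, group) {
  if (is.list(matrices)) {
    n <- nrow(matrices[[1L]])
    arr <- array(0, c(length(matrices), n, n))
    for (s in seq_along(matrices)) arr[s, , ] <- matrices[[s]]
    matrices <- arr
  }
  stopifnot(length(dim(matrices)) == 3L,
            dim(matrices)[2L] == dim(matrices)[3L])
  group <- as.character(group)
  if (length(group) != dim(matrices)[1L])
    stop("one group label per subject required")
  if (!all(group %in% c("A", "B")))
    stop("group labels must be 'A' or 'B'")
  if (min(table(factor(group, c("A", "B")))) < 2L)
    stop("at least 2 subjects per group are required")
  structure(list(matrices = matrices, group = group,
                 n_nodes = dim(matrices)[2L]), class = "group_sample")
}

# subjects x edges matrix of upper-triangle values
edge_matrix <- function(sample) {
  n <- sample$n_nodes
  ut <- upper.tri(matrix(0, n, n))
  t(apply(sample$matrices, 1L, function(m) m[ut]))
}

# Vectorized two-sample t statistics, one column per edge. `ind` is an
# n_subjects x n_perm 0/1 matrix selecting group A per permutation.
t_stats_block <- function(X, ind, n1, n2, var_equal) {
  SA <- crossprod(ind, X)
  SSA <- crossprod(ind, X^2)
  ST <- matrix(colSums(X), nrow(SA), ncol(X), byrow = TRUE)
  SST <- matrix(colSums(X^2), nrow(SA), ncol(X), byrow = TRUE)
  mA <- SA / n1
  mB <- (ST - SA) / n2
  vA <- pmax(0, (SSA - n1 * mA^2) / (n1 - 1L))
  vB <- pmax(0, ((SST - SSA) - n2 * mB^2) / (n2 - 1L))
  if (var_equal) {
    sp2 <- ((n1 - 1L) * vA + (n2 - 1L) * vB) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(vA / n1 + vB / n2)
  }
  (mA - mB) / se
}

#' Edgewise two-sample t statistics
#'
#' Per upper-triangle edge, the two-sample t statistic for group A minus group
#' B (pooled variance by default, Welch optional). Edges with zero variance in
#' both groups and equal means are set to 0 with a warning.
#'
#' @param sample a [group_sample()]
#' @param var_equal pooled-variance t (TRUE, default) or Welch
#' @return symmetric matrix of t values (zero diagonal); attribute `df` holds
#'   the pooled degrees of freedom when `var_equal = TRUE`
#' @export
edgewise_t <- function(sample, var_equal = TRUE) {
  stopifnot(inherits(sample, "group_sample"))
  X <- edge_matrix(sample)
  n1 <- sum(sample$group == "A")
  n2 <- sum(sample$group == "B")
  ind <- matrix(as.numeric(sample$group == "A"), ncol = 1L)
  tv <- drop(t_stats_block(X, ind, n1, n2, var_equal))
  if (anyNA(tv)) {
    warning(sprintf("%d edge(s) with zero variance in both groups; t set to 0",
                    sum(is.na(tv))))
    tv[is.na(tv)] <- 0
  }
  out <- sym_from_upper(tv, sample$n_nodes)
  attr(out, "df") <- if (var_equal) n1 + n2 - 2L else NA_integer_
  out
}

#' Supra-threshold connected components
#'
#' Keeps edges whose t statistic is at or above `tau` (direction `A>B`) or at
#' or below `-tau` (`B>A`) and returns the connected components of the
#' surviving edge graph, largest extent first.
#'
#' @param t_matrix symmetric edgewise t matrix
#' @param tau positive threshold (the study range is 2.5-3.0; default 2.7)
#' @param direction `"A>B"` or `"B>A"`
#' @return list of components, each a list with `edges` (2-column matrix),
#'   `nodes` (sorted integer vector), `extent` (edge count); empty list when no
#'   edge survives
#' @export
supra_threshold_components <- function(t_matrix, tau = 2.7,
                                       direction = c("A>B", "B>A")) {
  direction <- match.arg(direction)
  stopifnot(tau > 0)
  n <- nrow(t_matrix)
  s <- if (direction == "A>B") t_matrix else -t_matrix
  keep <- which(upper.tri(s) & s >= tau, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(list())
  g <- igraph::graph_from_edgelist(keep, directed = FALSE)
  mem <- igraph::components(g)$membership
  comp_ids <- sort(unique(mem[keep[, 1L]]))
  comps <- lapply(comp_ids, function(cid) {
    e <- keep[mem[keep[, 1L]] == cid, , drop = FALSE]
    list(edges = unname(e), nodes = sort(unique(as.integer(e))),
         extent = nrow(e))
  })
  comps[order(-vapply(comps, `[[`, integer(1L), "extent"))]
}

# Null distribution of the maximal supra-threshold component extent under
# random relabelling, in blocks to bound memory at full permutation counts.
perm_max_extents <- function(X, group, tau, n_perm, direction, var_equal,
                             pairs, block = 512L) {
  n <- length(group)
  n1 <- sum(group == "A")
  n2 <- n - n1
  sgn <- if (direction == "A>B") 1 else -1
  out <- integer(n_perm)
  done <- 0L
  while (done < n_perm) {
    p <- min(block, n_perm - done)
    ind <- matrix(0, n, p)
    for (k in seq_len(p)) ind[sample.int(n, n1), k] <- 1
    tt <- sgn * t_stats_block(X, ind, n1, n2, var_equal)
    tt[is.na(tt)] <- 0
    for (k in seq_len(p)) {
      idx <- which(tt[k, ] >= tau)
      out[done + k] <- if (length(idx)) {
        max_extent_uf(pairs[idx, 1L], pairs[idx, 2L])
      } else 0L
    }
    done <- done + p
  }
  out
}

#' Network-Based Statistic permutation test
#'
#' Computes the observed supra-threshold components for one contrast
#' direction, then re-runs the edgewise-t / threshold / components pipeline
#' under random exchanges of the group labels, recording the maximal component
#' extent of each permutation. The family-wise-error-corrected p-value of an
#' observed component of extent `s` is `(1 + #\{max extents >= s\}) / (1 + P)`,
#' so the smallest attainable p is `1/(P + 1)`.
#'
#' @param sample a [group_sample()]
#' @param tau edgewise t threshold
#' @param n_perm number of permutations (study value 5000); fewer than 100
#'   triggers a resolution warning
#' @param direction `"A>B"` or `"B>A"`
#' @param seed integer seed for the permutation stream
#' @param var_equal pooled-variance t (default) or Welch
#' @return object of class `nbs_result`: `components` (each with `fwe_p`),
#'   `null_max_extent`, plus the test parameters
#' @export
nbs_test <- function(sample, tau = 2.7, n_perm = 5000L,
                     direction = c("A>B", "B>A"), seed = NULL,
                     var_equal = TRUE) {
  direction <- match.arg(direction)
  stopifnot(inherits(sample, "group_sample"))
  if (n_perm < 100L) warning("fewer than 100 permutations gives poor p-value resolution")
  if (!is.null(seed)) set.seed(seed)
  tmat <- suppressWarnings(edgewise_t(sample, var_equal = var_equal))
  comps <- supra_threshold_components(tmat, tau, direction)
  X <- edge_matrix(sample)
  pairs <- upper_pairs(sample$n_nodes)
  null_max <- perm_max_extents(X, sample$group, tau, n_perm, direction,
                               var_equal, pairs)
  for (i in seq_along(comps))
    comps[[i]]$fwe_p <- (1 + sum(null_max >= comps[[i]]$extent)) / (1 + n_perm)
  structure(list(tau = tau, direction = direction, components = comps,
                 n_perm = n_perm, null_max_extent = null_max,
                 t_matrix = tmat, seed = seed,
                 n_by_group = table(factor(sample$group, c("A", "B")))),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %s, tau = %g, %d permutations\n",
              x$direction, x$tau, x$n_perm))
  if (!length(x$components)) {
    cat("  no supra-threshold component\n")
  } else {
    for (i in seq_along(x$components))
      cat(sprintf("  component %d: extent %d (%d nodes), FWE p = %.4g\n",
                  i, x$components[[i]]$extent,
                  length(x$components[[i]]$nodes), x$components[[i]]$fwe_p))
  }
  invisible(x)
}

#' Run the NBS over all band x window samples and both contrasts
#'
#' @param samples nested named list: `samples[[band]][[window]]` is a
#'   [group_sample()]; all samples must share one node count
#' @param tau,n_perm,var_equal passed to [nbs_test()]
#' @param seed master seed; each (band, window, direction) gets a derived seed
#'   recorded in its result
#' @return nested list `results[[band]][[window]][[direction]]` of
#'   `nbs_result` objects
#' @export
nbs_run_all <- function(samples, tau = 2.7, n_perm = 5000L, seed = 1L,
                        var_equal = TRUE) {
  if (!length(samples) || !any(vapply(samples, length, integer(1L)) > 0L))
    stop("empty input: supply samples[[band]][[window]] group samples")
  n_nodes <- NULL
  results <- list()
  counter <- 0L
  for (band in names(samples)) {
    for (win in names(samples[[band]])) {
      smp <- samples[[band]][[win]]
      if (is.null(smp)) {
        warning(sprintf("missing sample for band %s, window %s: skipped", band, win))
        next
      }
      if (is.null(n_nodes)) n_nodes <- smp$n_nodes
      if (smp$n_nodes != n_nodes)
        stop("all samples must share one atlas (node count differs)")
      for (dir in c("A>B", "B>A")) {
        counter <- counter + 1L
        sub_seed <- (seed + 7919L * counter) %% .Machine$integer.max
        results[[band]][[win]][[dir]] <-
          nbs_test(smp, tau = tau, n_perm = n_perm, direction = dir,
                   seed = sub_seed, var_equal = var_equal)
      }
    }
  }
  results
}
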