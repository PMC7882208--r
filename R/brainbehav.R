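# Brain-behaviour modelling: node strength within observed networks, Group x
# Error GLMs with FDR across networks and bands, and the demographic /
# behavioural statistics utilities (Welch t from summaries, 2x2 chi-square,
# Benjamini-Hochberg).

#' Node strength within an observed network component
#'
#' `strength(v)` is the sum of the connectivity values of the component edges
#' incident to `v`; the subject's mean network strength is the average of
#' strength over the component's node set (nodes with at least one incident
#' component edge).
#'
#' @param aec_matrix symmetric connectivity matrix
#' @param component_edges 2-column matrix of node pairs (an observed network)
#' @return list with `strength` (named by node index) and `mean_strength`
#' @export
node_strength <- function(aec_matrix, component_edges) {
  component_edges <- as.matrix(component_edges)
  if (nrow(component_edges) == 0L) stop("component has no edges")
  n <- nrow(aec_matrix)
  if (any(component_edges < 1L | component_edges > n))
    stop("component edges reference nodes outside the matrix")
  nodes <- sort(unique(as.integer(component_edges)))
  strength <- stats::setNames(numeric(length(nodes)), nodes)
  for (e in seq_len(nrow(component_edges))) {
    i <- component_edges[e, 1L]; j <- component_edges[e, 2L]
    w <- aec_matrix[i, j]
    strength[as.character(i)] <- strength[as.character(i)] + w
    strength[as.character(j)] <- strength[as.character(j)] + w
  }
  list(strength = strength, mean_strength = mean(strength))
}

#' Group x Error interaction model for one network
#'
#' Fits a Gaussian-identity GLM of mean network strength on group, error
#' count, and their interaction, and extracts the interaction term.
#'
#' @param strength numeric mean network strength per subject
#' @param group group labels (`A`/`B`), one per subject
#' @param errors numeric error counts, one per subject
#' @return list with `beta`, `se`, `p` for the interaction and the fitted
#'   `model`
#' @export
strength_glm <- function(strength, group, errors) {
  group <- factor(as.character(group), levels = c("A", "B"))
  if (min(table(group)) < 3L) stop("at least 3 subjects per group are required")
  dat <- data.frame(strength = strength, group = group, errors = errors)
  fit <- stats::glm(strength ~ group * errors, data = dat,
                    family = stats::gaussian())
  if (any(is.na(stats::coef(fit))))
    stop(sprintf("perfect collinearity among terms: %s",
                 paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                       collapse = ", ")))
  cm <- summary(fit)$coefficients
  row <- grep(":", rownames(cm))
  list(beta = unname(cm[row, 1L]), se = unname(cm[row, 2L]),
       p = unname(cm[row, 4L]), model = fit)
}

#' Brain-behaviour models across networks and bands with FDR
#'
#' Fits one [strength_glm()] per (network, band) cell and applies
#' Benjamini-Hochberg correction across all models of each error type.
#'
#' @param records data.frame with columns `network`, `band`, `subject`,
#'   `group`, `strength`, `errors` (and optionally `error_type`)
#' @return data.frame `network, band, error_type, beta, se, p, q`
#' @export
brain_behaviour <- function(records) {
  req <- c("network", "band", "subject", "group", "strength", "errors")
  if (!all(req %in% names(records)))
    stop(sprintf("records must have columns %s", paste(req, collapse = ", ")))
  if (!"error_type" %in% names(records)) records$error_type <- "errors"
  out <- list()
  for (et in unique(records$error_type)) {
    sub <- records[records$error_type == et, , drop = FALSE]
    cells <- unique(sub[, c("network", "band")])
    rows <- lapply(seq_len(nrow(cells)), function(k) {
      cell <- sub[sub$network == cells$network[k] & sub$band == cells$band[k], ]
      fit <- strength_glm(cell$strength, cell$group, cell$errors)
      data.frame(network = cells$network[k], band = cells$band[k],
                 error_type = et, beta = fit$beta, se = fit$se, p = fit$p)
    })
    tab <- do.call(rbind, rows)
    tab$q <- bh_fdr(tab$p)
    out[[et]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Welch t-test from group summaries
#'
#' Two-tailed independent-samples Welch statistic with Welch-Satterthwaite
#' degrees of freedom, computed from printed group means, SDs and sizes.
#'
#' @param mean1,sd1,n1 first group summary
#' @param mean2,sd2,n2 second group summary
#' @return list with `t` (group 1 minus group 2), `df`, `p`
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2L, n2 >= 2L)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tval <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1L) + v2^2 / (n2 - 1L))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Chi-square test for a 2x2 table
#'
#' Pearson chi-square with optional Yates continuity correction; errors on a
#' zero marginal, where the statistic is undefined.
#'
#' @param table 2x2 matrix of nonnegative integer counts
#' @param continuity apply the Yates correction (default FALSE)
#' @return list with `statistic`, `df` (= 1), `p`
#' @export
chi_square_2x2 <- function(table, continuity = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("a zero row or column marginal makes the chi-square statistic undefined")
  ht <- suppressWarnings(stats::chisq.test(table, correct = continuity))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; invariant to input order and
#' idempotent on already-adjusted monotone inputs.
#'
#' @param pvalues numeric vector in \[0, 1\]
#' @return q-values in the input order
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Percentage of flagged cases
#'
#' @param cases number of flagged subjects
#' @param n group size
#' @return percentage on the 0-100 scale
#' @export
percent_flagged <- function(cases, n) {
  stopifnot(cases >= 0, n > 0, cases <= n)
  100 * cases / n
}
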