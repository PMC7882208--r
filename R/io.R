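# File formats: atlas TSV, BrainNet-Viewer .node/.edge, matrix TSV, and the
# YAML pipeline configuration.

#' Read an atlas table
#'
#' Tab-separated file with columns `node_id`, `label`, `x_mm`, `y_mm`, `z_mm`
#' (MNI centroid coordinates). Row order defines the node indexing used by
#' every matrix downstream.
#'
#' @param path file path
#' @return data.frame of class `atlas_table`
#' @export
read_atlas <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("node_id", "label", "x_mm", "y_mm", "z_mm")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop(sprintf("atlas is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(tab) == 0L) stop("atlas has no nodes")
  if (anyDuplicated(tab$label))
    stop(sprintf("duplicated atlas label(s): %s",
                 paste(unique(tab$label[duplicated(tab$label)]), collapse = ", ")))
  if (!all(is.finite(as.matrix(tab[, c("x_mm", "y_mm", "z_mm")]))))
    stop("atlas coordinates must be finite")
  class(tab) <- c("atlas_table", "data.frame")
  tab
}

#' Deterministic synthetic atlas
#'
#' Node labels with centroids placed quasi-uniformly on an ellipsoidal shell
#' (a stand-in for anatomical centroids; purely synthetic).
#'
#' @param n_nodes number of nodes
#' @return an `atlas_table` data.frame
#' @export
synthetic_atlas <- function(n_nodes) {
  i <- seq_len(n_nodes)
  golden <- pi * (3 - sqrt(5))
  zu <- 1 - 2 * (i - 0.5) / n_nodes
  r <- sqrt(pmax(0, 1 - zu^2))
  tab <- data.frame(
    node_id = i,
    label = sprintf("node%03d", i),
    x_mm = round(70 * r * cos(golden * i), 1),
    y_mm = round(85 * r * sin(golden * i), 1),
    z_mm = round(60 * zu, 1)
  )
  class(tab) <- c("atlas_table", "data.frame")
  tab
}

#' Write a network component as BrainNet-Viewer files
#'
#' `.node`: whitespace-delimited `x y z color size label` rows for every atlas
#' node (component nodes sized by strength, colored 1; others 0). `.edge`:
#' full square matrix holding the component's edge weights, zeros elsewhere.
#'
#' @param component a component from [supra_threshold_components()] (list with
#'   `edges`)
#' @param atlas an `atlas_table` covering all component nodes
#' @param weights symmetric matrix of edge weights (e.g. baselined AEC or t)
#' @param node_path,edge_path output paths
#' @return invisibly, the two paths
#' @export
write_brainnet <- function(component, atlas, weights, node_path, edge_path) {
  if (is.null(component$edges) || nrow(component$edges) == 0L)
    stop("refusing to write an empty component")
  n <- nrow(atlas)
  if (any(component$edges > n))
    stop("component nodes missing from the atlas (no coordinates)")
  edge <- matrix(0, n, n)
  for (e in seq_len(nrow(component$edges))) {
    i <- component$edges[e, 1L]; j <- component$edges[e, 2L]
    edge[i, j] <- weights[i, j]
    edge[j, i] <- weights[i, j]
  }
  in_comp <- seq_len(n) %in% unique(as.integer(component$edges))
  size <- rowSums(abs(edge))
  node <- data.frame(x = atlas$x_mm, y = atlas$y_mm, z = atlas$z_mm,
                     color = as.integer(in_comp),
                     size = round(size, 6), label = atlas$label)
  utils::write.table(node, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(round(edge, 10), edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node = node_path, edge = edge_path))
}

#' Read a BrainNet `.edge` matrix
#'
#' @param path file path
#' @return square numeric matrix
#' @export
read_brainnet_edge <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop(".edge file must hold a square matrix")
  m
}

#' Write / read a labelled symmetric matrix as TSV
#'
#' @param m matrix with node labels
#' @param path file path
#' @param labels column/row labels (defaults to existing dimnames)
#' @return `write_matrix_tsv` returns the path invisibly; `read_matrix_tsv`
#'   the matrix
#' @export
write_matrix_tsv <- function(m, path, labels = NULL) {
  labels <- labels %||% colnames(m) %||% sprintf("node%03d", seq_len(ncol(m)))
  dimnames(m) <- list(labels, labels)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline, defaulting to the study values:
#' 2500 fT amplitude threshold, 10 mm motion threshold, 5% beamformer
#' regularization, canonical bands, -5..17 s epochs with 5 s analysis windows,
#' edgewise t threshold 2.7 (midpoint of the 2.5-3.0 range), 5000
#' permutations.
#'
#' @param n_nodes,n_subjects_per_group,n_trials,fs,epoch_window,planted_edges,coupling_by_group,baseline_coupling,mixing_strength,artefact_rates see [synth_spec()]
#' @param bands character vector of band names to analyse
#' @param amp_threshold_fT,motion_threshold_mm trial-rejection thresholds
#' @param reg_fraction beamformer regularization fraction
#' @param tau,n_perm NBS threshold and permutation count
#' @param eps baseline guard
#' @param alpha component significance level
#' @param seed master seed
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(n_nodes = 90L, n_subjects_per_group = 30L,
                            n_trials = 22L, fs = 600,
                            epoch_window = c(-5, 17),
                            bands = c("theta", "alpha", "beta", "gamma"),
                            planted_edges = NULL,
                            coupling_by_group = c(A = 0.15, B = 0.45),
                            baseline_coupling = 0,
                            mixing_strength = 0,
                            artefact_rates = c(spike = 0.04, motion = 0.04),
                            amp_threshold_fT = 2500,
                            motion_threshold_mm = 10,
                            reg_fraction = 0.05,
                            tau = 2.7, n_perm = 5000L, eps = 1e-3,
                            alpha = 0.05, seed = 1L) {
  cfg <- list(n_nodes = as.integer(n_nodes),
              n_subjects_per_group = as.integer(n_subjects_per_group),
              n_trials = as.integer(n_trials), fs = fs,
              epoch_window = as.numeric(epoch_window), bands = bands,
              planted_edges = if (is.null(planted_edges)) NULL else
                as.matrix(planted_edges),
              coupling_by_group = coupling_by_group,
              baseline_coupling = baseline_coupling,
              mixing_strength = mixing_strength,
              artefact_rates = artefact_rates,
              amp_threshold_fT = amp_threshold_fT,
              motion_threshold_mm = motion_threshold_mm,
              reg_fraction = reg_fraction, tau = tau,
              n_perm = as.integer(n_perm), eps = eps, alpha = alpha,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  req <- c("n_nodes", "n_subjects_per_group", "n_trials", "fs",
           "epoch_window", "bands", "coupling_by_group", "baseline_coupling",
           "mixing_strength", "artefact_rates", "amp_threshold_fT",
           "motion_threshold_mm", "reg_fraction", "tau", "n_perm", "eps",
           "alpha", "seed")
  missing_f <- setdiff(req, names(cfg))
  if (length(missing_f))
    stop(sprintf("config is missing field(s): %s",
                 paste(missing_f, collapse = ", ")))
  if (cfg$tau <= 0) stop("config field tau must be positive")
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_config(write_config(cfg, path))` equals
#' `cfg`.
#'
#' @param cfg a [pipeline_config()]
#' @param path file path
#' @return `write_config` the path invisibly; `read_config` the config
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  if (!is.null(out$planted_edges))
    out$planted_edges <- lapply(seq_len(nrow(out$planted_edges)),
                                function(i) as.integer(out$planted_edges[i, ]))
  out$coupling_by_group <- as.list(out$coupling_by_group)
  out$artefact_rates <- as.list(out$artefact_rates)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$planted_edges))
    raw$planted_edges <- do.call(rbind, lapply(raw$planted_edges, as.integer))
  raw$coupling_by_group <- unlist(raw$coupling_by_group)
  raw$artefact_rates <- unlist(raw$artefact_rates)
  raw$n_nodes <- as.integer(raw$n_nodes)
  raw$n_subjects_per_group <- as.integer(raw$n_subjects_per_group)
  raw$n_trials <- as.integer(raw$n_trials)
  raw$n_perm <- as.integer(raw$n_perm)
  raw$seed <- as.integer(raw$seed)
  raw$epoch_window <- as.numeric(raw$epoch_window)
  validate_config(raw)
  class(raw) <- "pipeline_config"
  raw
}
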