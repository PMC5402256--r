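#' Single-layer summary statistics
#'
#' Computes the five descriptive statistics used to characterise each layer:
#' mean degree over all nodes; mean local clustering coefficient (nodes of
#' degree < 2 contribute 0 and are included in the mean); degree
#' assortativity (Pearson correlation of degrees at edge endpoints, `NA`
#' when undefined); the fraction of nodes in the largest connected
#' component; and the mean shortest path length within that component.
#'
#' @param layer an igraph layer.
#' @return a one-row data frame with columns `mean_degree`,
#'   `mean_clustering`, `assortativity`, `conn_fraction`, `mean_path_lcc`.
#' @export
layer_summary <- function(layer) {
  n <- igraph::vcount(layer)
  stopifnot(n >= 2L)
  if (igraph::ecount(layer) == 0L) {
    return(data.frame(mean_degree = 0, mean_clustering = 0,
                      assortativity = NA_real_, conn_fraction = 1 / n,
                      mean_path_lcc = NA_real_))
  }
  deg <- igraph::degree(layer)
  cc <- igraph::transitivity(layer, type = "local", isolates = "zero")
  a <- suppressWarnings(igraph::assortativity_degree(layer))
  if (!is.finite(a)) a <- NA_real_
  comp <- igraph::components(layer)
  lcc <- igraph::induced_subgraph(
    layer, which(comp$membership == which.max(comp$csize)))
  mp <- if (igraph::vcount(lcc) >= 2L) igraph::mean_distance(lcc) else NA_real_
  data.frame(mean_degree = mean(deg), mean_clustering = mean(cc),
             assortativity = a, conn_fraction = max(comp$csize) / n,
             mean_path_lcc = mp)
}

#' Degree-preserving configuration-model ensemble
#'
#' Samples randomized counterparts of a layer by degree-preserving
#' double-edge swaps (the graph stays simple: no self-loops or multi-edges,
#' and the degree sequence is exactly preserved), then summarises the
#' ensemble with the per-sample [layer_summary()] statistics.
#'
#' @param layer an igraph layer.
#' @param n_samples number of randomized samples (default 100).
#' @param n_swaps_per_edge attempted swaps per edge per sample (default 10).
#' @param seed integer seed.
#' @return an object of class `null_ensemble`: list with `samples` (list of
#'   igraph graphs), `stats` (per-sample data frame), `stat_means`,
#'   `stat_sds`, `n_samples`, `seed`, `source_name`.
#' @export
configuration_model_ensemble <- function(layer, n_samples = 100L,
                                         n_swaps_per_edge = 10L, seed = 1L) {
  stopifnot(n_samples >= 1L)
  m <- igraph::ecount(layer)
  if (m < 2L)
    warning("layer has fewer than 2 edges; null samples equal the source")
  samples <- with_seed(seed, lapply(seq_len(n_samples), function(i) {
    if (m < 2L) return(layer)
    igraph::rewire(layer, igraph::keeping_degseq(niter = n_swaps_per_edge * m))
  }))
  stats <- do.call(rbind, lapply(samples, layer_summary))
  structure(list(samples = samples, stats = stats,
                 stat_means = colMeans(stats, na.rm = TRUE),
                 stat_sds = vapply(stats, stats::sd, 0, na.rm = TRUE),
                 n_samples = n_samples, seed = seed,
                 source_name = if (is.null(layer$name)) "layer" else layer$name),
            class = "null_ensemble")
}

#' Cross-layer degree correlations
#'
#' Pairwise Kendall tau-b rank correlations between the degree vectors of
#' all layer pairs over the shared vocabulary, with two-sided p-values.
#' Constant degree vectors yield `NA`.
#'
#' @param x an [mln] object with at least two layers.
#' @return list with `tau` and `pvalues`, both L x L symmetric matrices
#'   (unit diagonal for `tau`), dimnames the layer names.
#' @export
cross_layer_degree_correlation <- function(x) {
  stopifnot(inherits(x, "mln"), length(x$layers) >= 2L)
  L <- length(x$layers)
  degs <- vapply(x$layers, igraph::degree, numeric(n_words(x)))
  tau <- diag(1, L); p <- diag(0, L)
  dimnames(tau) <- dimnames(p) <- list(names(x$layers), names(x$layers))
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    xi <- degs[, i]; xj <- degs[, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      tau[i, j] <- tau[j, i] <- NA_real_
      p[i, j] <- p[j, i] <- NA_real_
    } else {
      ct <- suppressWarnings(
        stats::cor.test(xi, xj, method = "kendall", exact = FALSE))
      tau[i, j] <- tau[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(tau = tau, pvalues = p)
}

layer_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) return(character())
  pair_key(el[, 1L], el[, 2L])
}

#' Edge overlap (multiplexity) between layers
#'
#' Observed overlap between layers i and j is `|Ei intersect Ej| /
#' min(|Ei|, |Ej|)` (so a layer's overlap with itself is 1); with
#' `normalization = "jaccard"` the union replaces the minimum. When null
#' ensembles are supplied, the same quantity is recomputed between paired
#' null samples of the two layers (both randomized independently) to give a
#' null mean, sd and Z-score per pair.
#'
#' @param x an [mln] object.
#' @param nulls optional named list of [configuration_model_ensemble()]
#'   results, one per layer, all with the same `n_samples`.
#' @param normalization `"min"` (default) or `"jaccard"`.
#' @return list with matrices `observed` and, when nulls are given,
#'   `null_mean`, `null_sd`, `zscore`.
#' @export
edge_overlap <- function(x, nulls = NULL, normalization = c("min", "jaccard")) {
  stopifnot(inherits(x, "mln"))
  normalization <- match.arg(normalization)
  L <- length(x$layers); nm <- names(x$layers)
  keys <- lapply(x$layers, layer_edge_keys)
  ov <- function(ei, ej) {
    if (length(ei) == 0L || length(ej) == 0L) return(NA_real_)
    inter <- length(intersect(ei, ej))
    den <- if (normalization == "min") min(length(ei), length(ej)) else
      length(union(ei, ej))
    inter / den
  }
  obs <- matrix(NA_real_, L, L, dimnames = list(nm, nm))
  for (i in seq_len(L)) for (j in seq_len(L)) obs[i, j] <- ov(keys[[i]], keys[[j]])
  out <- list(observed = obs)
  if (!is.null(nulls)) {
    stopifnot(setequal(names(nulls), nm))
    ns <- nulls[[1L]]$n_samples
    null_mean <- null_sd <- z <- matrix(NA_real_, L, L, dimnames = list(nm, nm))
    for (i in seq_len(L)) for (j in seq_len(L)) {
      vals <- vapply(seq_len(ns), function(s) {
        ov(layer_edge_keys(nulls[[nm[i]]]$samples[[s]]),
           layer_edge_keys(nulls[[nm[j]]]$samples[[s]]))
      }, 0)
      null_mean[i, j] <- mean(vals); null_sd[i, j] <- stats::sd(vals)
      z[i, j] <- if (isTRUE(null_sd[i, j] > 0))
        (obs[i, j] - null_mean[i, j]) / null_sd[i, j] else NA_real_
    }
    out$null_mean <- null_mean; out$null_sd <- null_sd; out$zscore <- z
  }
  out
}
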