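#' Von Neumann entropy of a graph
#'
#' A graph is represented by the density matrix rho = L / tr(L), the
#' combinatorial Laplacian rescaled to unit trace. Its Von Neumann entropy is
#' `-sum(lambda * log(lambda))` over the eigenvalues of rho (with
#' `0 log 0 = 0`). The entropy is 0 only for a graph whose Laplacian has a
#' single nonzero eigenvalue and grows as structure spreads over many
#' eigenmodes.
#'
#' @param g an igraph graph with at least one edge, or a density matrix.
#' @return nonnegative entropy (natural log units).
#' @export
von_neumann_entropy <- function(g) {
  rho <- if (is.matrix(g)) g else density_matrix(g)
  lam <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-12]
  -sum(lam * log(lam))
}

density_matrix <- function(g) {
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  d <- rowSums(a)
  tr <- sum(d)
  if (tr <= 0) stop("entropy undefined for a layer with zero edges")
  (diag(d) - a) / tr
}

#' Jensen-Shannon divergence between two graph density matrices
#'
#' `JSD(rho_i, rho_j) = H((rho_i + rho_j)/2) - (H(rho_i) + H(rho_j))/2`,
#' where H is the Von Neumann entropy. Nonnegative, symmetric, and zero iff
#' the density matrices coincide; its square root is a metric used as the
#' layer-layer distance for the reducibility dendrogram.
#'
#' @param rho_i,rho_j density matrices (see [von_neumann_entropy()]).
#' @return nonnegative divergence.
#' @export
jensen_shannon_divergence <- function(rho_i, rho_j) {
  h_mix <- von_neumann_entropy((rho_i + rho_j) / 2)
  max(0, h_mix - (von_neumann_entropy(rho_i) + von_neumann_entropy(rho_j)) / 2)
}

# sum adjacency matrices of a set of layers and return the density matrix
aggregate_density <- function(layers) {
  a <- Reduce(`+`, lapply(layers, function(g)
    igraph::as_adjacency_matrix(g, sparse = FALSE)))
  d <- rowSums(a)
  tr <- sum(d)
  if (tr <= 0) stop("entropy undefined for a layer with zero edges")
  (diag(d) - a) / tr
}

#' Structural reducibility of a multiplex
#'
#' Tests whether layers can be aggregated without information loss. Each
#' layer is mapped to its Laplacian density matrix; pairwise Jensen-Shannon
#' divergences give a layer-layer distance (its square root), on which
#' Ward-linkage agglomerative clustering yields a merge sequence. Each
#' dendrogram cut defines a partition of the layers; groups are aggregated by
#' summing adjacency matrices, and the cut quality is the relative entropy of
#' the partition versus the fully aggregated network:
#' `q = 1 - mean(H(group)) / H(aggregate)`. The multiplex is declared
#' irreducible when quality is strictly maximal at the no-merge cut; ties
#' favour merging, so duplicate layers are reported reducible.
#'
#' @param x an [mln] object with at least two layers, each with >= 1 edge.
#' @return an object of class `reducibility_result`: list with `jsd` (L x L
#'   matrix), `distance` (sqrt-JSD `dist`), `hclust`, `merge_sequence`
#'   (list of layer-name groups merged at each step), `quality` (numeric,
#'   one value per cut, starting at 0 merges), `best_cut` (number of merges
#'   at the best cut) and `irreducible` (logical).
#' @export
reducibility_analysis <- function(x) {
  stopifnot(inherits(x, "mln"), length(x$layers) >= 2L)
  if (any(vapply(x$layers, igraph::ecount, numeric(1)) == 0L))
    stop("entropy undefined: every layer needs at least one edge")
  L <- length(x$layers); nm <- names(x$layers)
  rho <- lapply(x$layers, density_matrix)
  jsd <- matrix(0, L, L, dimnames = list(nm, nm))
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L)
    jsd[i, j] <- jsd[j, i] <- jensen_shannon_divergence(rho[[i]], rho[[j]])
  hc <- stats::hclust(stats::as.dist(sqrt(jsd)), method = "ward.D2")
  h_agg <- von_neumann_entropy(aggregate_density(x$layers))

  # walk the dendrogram: partition after m merges, m = 0 .. L-1
  groups <- as.list(nm)
  quality <- numeric(L)
  merge_sequence <- vector("list", L - 1L)
  part_quality <- function(groups) {
    hs <- vapply(groups, function(g)
      von_neumann_entropy(aggregate_density(x$layers[g])), 0)
    1 - mean(hs) / h_agg
  }
  quality[1L] <- part_quality(groups)
  node_members <- vector("list", L - 1L)
  for (m in seq_len(L - 1L)) {
    members <- function(k) if (k < 0) nm[-k] else node_members[[k]]
    merged <- c(members(hc$merge[m, 1L]), members(hc$merge[m, 2L]))
    node_members[[m]] <- merged
    merge_sequence[[m]] <- merged
    groups <- c(Filter(function(g) !any(g %in% merged), groups), list(merged))
    quality[m + 1L] <- part_quality(groups)
  }
  best <- which.max(rev(quality))         # ties favour more merges
  best_cut <- L - best                    # number of merges at the best cut
  structure(list(jsd = jsd, distance = stats::as.dist(sqrt(jsd)),
                 hclust = hc, merge_sequence = merge_sequence,
                 quality = quality, best_cut = best_cut,
                 irreducible = best_cut == 0L),
            class = "reducibility_result")
}

#' @export
print.reducibility_result <- function(x, ...) {
  cat("Structural reducibility analysis\n")
  cat("  quality by merges:",
      paste(sprintf("%d:%.4f", seq_along(x$quality) - 1L, x$quality),
            collapse = "  "), "\n")
  cat("  verdict:", if (x$irreducible) "irreducible" else
    sprintf("reducible (best at %d merge(s))", x$best_cut), "\n")
  invisible(x)
}

#' Export the reducibility dendrogram as Newick
#'
#' @param res a [reducibility_analysis()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reducibility_newick <- function(res, path) {
  hc <- res$hclust
  lab <- hc$labels
  node_str <- character(nrow(hc$merge))
  str_of <- function(k, h) {
    if (k < 0) sprintf("%s:%g", lab[-k], h) else
      sprintf("%s:%g", node_str[k], h - hc$height[k])
  }
  for (m in seq_len(nrow(hc$merge))) {
    h <- hc$height[m]
    node_str[m] <- sprintf("(%s,%s)", str_of(hc$merge[m, 1L], h),
                           str_of(hc$merge[m, 2L], h))
  }
  writeLines(paste0(node_str[nrow(hc$merge)], ";"), path)
  invisible(path)
}
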