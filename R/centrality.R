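word_scores <- function(scores, metric, scope) {
  stopifnot(!is.null(names(scores)), all(is.finite(scores)))
  structure(scores, metric = metric, scope = scope, class = "word_scores")
}

#' @export
print.word_scores <- function(x, ...) {
  cat(sprintf("Word scores: metric=%s scope=%s (%d words)\n",
              attr(x, "metric"), attr(x, "scope"), length(x)))
  print(utils::head(sort(unclass(x), decreasing = TRUE)))
  invisible(x)
}

#' Single-layer centrality word scores
#'
#' Word scores from one network layer. `degree` counts a word's links (on the
#' phonological layer this is its phonological neighbourhood size).
#' `closeness` is harmonic centrality normalized by N - 1: the mean
#' reciprocal shortest-path distance to all other words, with unreachable
#' pairs contributing 0 — well defined on the fragmented layers where the
#' classic variant is not. `betweenness` is normalized shortest-path
#' betweenness. `pagerank` is the stationary random-walk score with damping
#' 0.85 and uniform teleportation (isolated words receive teleport mass).
#'
#' @param layer an igraph layer.
#' @param metric one of `"degree"`, `"closeness"`, `"betweenness"`,
#'   `"pagerank"`.
#' @param closeness_variant `"harmonic"` (default) or `"classic"` (classic
#'   closeness within components, for sensitivity analysis).
#' @param damping PageRank damping factor (default 0.85).
#' @return a `word_scores` named numeric vector over all words of the layer.
#' @export
layer_centrality <- function(layer, metric = c("degree", "closeness",
                                               "betweenness", "pagerank"),
                             closeness_variant = c("harmonic", "classic"),
                             damping = 0.85) {
  metric <- match.arg(metric)
  closeness_variant <- match.arg(closeness_variant)
  n <- igraph::vcount(layer)
  s <- switch(metric,
    degree = igraph::degree(layer),
    closeness = if (closeness_variant == "harmonic") {
      igraph::harmonic_centrality(layer, normalized = TRUE)
    } else {
      cl <- suppressWarnings(igraph::closeness(layer, normalized = TRUE))
      cl[!is.finite(cl)] <- 0
      cl
    },
    betweenness = if (n > 2L)
      igraph::betweenness(layer, normalized = TRUE) else
        stats::setNames(rep(0, n), igraph::V(layer)$name),
    pagerank = igraph::page_rank(layer, damping = damping)$vector)
  names(s) <- igraph::V(layer)$name
  word_scores(s, metric, scope = if (is.null(layer$name)) "layer" else layer$name)
}

#' Multiplex centrality word scores
#'
#' Path-based multiplex metrics treat a hop on any layer as unit cost (layer
#' jumps are free): closeness and betweenness are computed on the unweighted
#' union graph, where an edge exists if present on any layer. Multiplex
#' PageRank uses the layer multiplicity of each edge as its weight, and
#' `multidegree` is the sum of per-layer degrees. With a single layer every
#' metric reduces exactly to [layer_centrality()].
#'
#' @param x an [mln] object.
#' @param metric one of `"multidegree"`, `"closeness"`, `"betweenness"`,
#'   `"pagerank"`.
#' @inheritParams layer_centrality
#' @return a `word_scores` named numeric vector over the vocabulary.
#' @export
multiplex_centrality <- function(x, metric = c("multidegree", "closeness",
                                               "betweenness", "pagerank"),
                                 closeness_variant = c("harmonic", "classic"),
                                 damping = 0.85) {
  stopifnot(inherits(x, "mln"))
  metric <- match.arg(metric)
  if (metric == "multidegree") {
    return(word_scores(as.numeric(multidegree(x)) |>
                         stats::setNames(x$vocab$word),
                       "multidegree", "multiplex"))
  }
  agg <- aggregate_graph(x, weighted = TRUE)
  s <- if (metric == "pagerank") {
    pr <- igraph::page_rank(agg, damping = damping,
                            weights = igraph::E(agg)$multiplicity)$vector
    stats::setNames(pr, igraph::V(agg)$name)
  } else {
    agg_u <- igraph::delete_edge_attr(agg, "weight")
    layer_centrality(agg_u, metric, closeness_variant = closeness_variant)
  }
  word_scores(as.numeric(s) |> stats::setNames(igraph::V(agg)$name),
              metric, "multiplex")
}

#' Word-attribute scores
#'
#' Non-relational word scores: raw child-directed-speech frequency
#' (more frequent words rank first) or negative character length (shorter
#' words rank first when sorting by descending score).
#'
#' @param vocab vocabulary data frame with the needed column (`frequency` or
#'   `length`).
#' @param attribute `"frequency"` or `"neg_length"`.
#' @return a `word_scores` named numeric vector.
#' @export
attribute_score <- function(vocab, attribute = c("frequency", "neg_length")) {
  attribute <- match.arg(attribute)
  col <- if (attribute == "frequency") "frequency" else "length"
  if (is.null(vocab[[col]]) || anyNA(vocab[[col]]))
    stop("attribute '", col, "' missing for word(s): ",
         paste(utils::head(vocab$word[is.na(vocab[[col]])], 10), collapse = ", "))
  s <- if (attribute == "frequency") as.numeric(vocab$frequency) else
    -as.numeric(vocab$length)
  word_scores(stats::setNames(s, vocab$word), attribute, "attribute")
}
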