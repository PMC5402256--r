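#' Edge-coloured multiplex lexical networks
#'
#' An `mln` object represents a mental lexicon as an edge-coloured multiplex:
#' one shared vocabulary of words and an ordered list of undirected simple
#' graph layers, each encoding a different word-word relationship
#' (free association, feature sharing, co-occurrence, phonological
#' similarity, or any custom relation). There are no inter-layer links;
#' layer membership acts as an edge colour.
#'
#' @param layers named list of undirected [igraph::graph] objects sharing an
#'   identical vertex name set. Self-loops and multi-edges are not allowed.
#' @param vocabulary optional data frame describing the words, with a `word`
#'   column and optional `frequency`, `length`, `ipa` (space-separated phoneme
#'   tokens) and `pos` columns. Defaults to a bare table of the vertex names.
#' @return an object of class `mln` with elements `vocab` (data frame) and
#'   `layers` (named list of igraph graphs, vertices ordered as `vocab$word`).
#' @export
mln <- function(layers, vocabulary = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  if (is.null(names(layers)) || anyNA(names(layers)) || any(names(layers) == ""))
    stop("layers must be a named list")
  if (anyDuplicated(names(layers))) stop("layer names must be unique")
  for (nm in names(layers)) {
    g <- layers[[nm]]
    if (!igraph::is_igraph(g)) stop("layer '", nm, "' is not an igraph graph")
    if (igraph::is_directed(g)) stop("layer '", nm, "' must be undirected")
    if (any(igraph::which_loop(g)) || any(igraph::which_multiple(g)))
      stop("layer '", nm, "' must be a simple graph")
    if (is.null(igraph::V(g)$name)) stop("layer '", nm, "' must have vertex names")
  }
  ref <- sort(igraph::V(layers[[1L]])$name)
  if (anyDuplicated(ref)) stop("duplicate word ids in layer vertex set")
  for (nm in names(layers)) {
    if (!identical(sort(igraph::V(layers[[nm]])$name), ref))
      stop("all layers must share the identical node set (layer '", nm, "' differs)")
  }
  if (is.null(vocabulary)) {
    vocabulary <- data.frame(word = ref, stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(vocabulary), "word" %in% names(vocabulary))
    vocabulary$word <- as.character(vocabulary$word)
    if (anyDuplicated(vocabulary$word)) stop("duplicate word ids in vocabulary")
    if (!setequal(vocabulary$word, ref))
      stop("vocabulary words must match the layers' shared node set")
    if (!is.null(vocabulary$length) &&
        any(!is.na(vocabulary$length) & vocabulary$length < 1))
      stop("word length must be >= 1 where set")
  }
  # fix one canonical vertex ordering across all layers
  ord <- vocabulary$word
  layers <- lapply(layers, function(g) {
    igraph::permute(g, match(igraph::V(g)$name, ord))
  })
  structure(list(vocab = vocabulary, layers = layers), class = "mln")
}

#' @export
print.mln <- function(x, ...) {
  cat(sprintf("Multiplex lexical network: %d words, %d layers\n",
              nrow(x$vocab), length(x$layers)))
  for (nm in names(x$layers))
    cat(sprintf("  %-14s %6d edges\n", nm, igraph::ecount(x$layers[[nm]])))
  invisible(x)
}

n_words <- function(x) nrow(x$vocab)

#' Build a layer graph from an edge list
#'
#' @param edges two-column matrix or data frame of word-id pairs (character),
#'   or NULL/empty for an edgeless layer. Self-loops are rejected; duplicate
#'   and reversed pairs are collapsed.
#' @param words character vector of all vocabulary word ids.
#' @param name layer name stored as the graph's `name` attribute.
#' @return undirected simple igraph graph on all `words`.
#' @export
make_layer <- function(edges, words, name = "layer") {
  stopifnot(is.character(words), !anyDuplicated(words))
  g <- igraph::make_empty_graph(n = length(words), directed = FALSE)
  igraph::V(g)$name <- words
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    mode(edges) <- "character"
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    bad <- !(edges %in% words)
    if (any(bad)) stop("edge endpoints not in vocabulary: ",
                       paste(unique(edges[bad]), collapse = ", "))
    key <- pair_key(edges[, 1L], edges[, 2L])
    edges <- edges[!duplicated(key), , drop = FALSE]
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  g$name <- name
  g
}

#' Aggregate a multiplex into a single graph
#'
#' The aggregate graph has an edge wherever at least one layer has that edge.
#' With `weighted = TRUE` each edge carries a `multiplicity` attribute (and a
#' `weight` alias) counting the layers containing it; otherwise all
#' multiplicities are 1.
#'
#' @param x an [mln] object.
#' @param weighted logical; keep layer multiplicities as edge weights?
#' @return an undirected simple igraph graph on the full vocabulary with edge
#'   attributes `multiplicity` and `weight`.
#' @export
aggregate_graph <- function(x, weighted = FALSE) {
  stopifnot(inherits(x, "mln"))
  words <- x$vocab$word
  el <- do.call(rbind, lapply(x$layers, function(g) igraph::as_edgelist(g)))
  g <- igraph::make_empty_graph(n = length(words), directed = FALSE)
  igraph::V(g)$name <- words
  if (!is.null(el) && nrow(el) > 0L) {
    key <- pair_key(el[, 1L], el[, 2L])
    mult <- as.integer(table(key)[unique(key)])
    el1 <- el[!duplicated(key), , drop = FALSE]
    g <- igraph::add_edges(g, as.vector(t(el1)))
    igraph::E(g)$multiplicity <- if (weighted) mult else rep(1L, nrow(el1))
    igraph::E(g)$weight <- igraph::E(g)$multiplicity
  }
  g$name <- "aggregate"
  g
}

#' Multidegree of words
#'
#' The multidegree of a word is the sum of its degrees over all layers.
#'
#' @param x an [mln] object.
#' @param words word ids to score (default: the whole vocabulary).
#' @return named integer vector of multidegrees.
#' @export
multidegree <- function(x, words = NULL) {
  stopifnot(inherits(x, "mln"))
  if (is.null(words)) words <- x$vocab$word
  unknown <- setdiff(words, x$vocab$word)
  if (length(unknown))
    stop("unknown word id(s): ", paste(unknown, collapse = ", "))
  degs <- vapply(x$layers, function(g) igraph::degree(g)[words],
                 numeric(length(words)))
  if (length(words) == 1L) degs <- matrix(degs, nrow = 1L)
  out <- as.integer(rowSums(degs))
  names(out) <- words
  out
}

#' Is the multiplex connected?
#'
#' TRUE iff every pair of words is joined by a path in the (unweighted)
#' aggregate graph, i.e. a path that may exploit different relationship
#' types on different hops.
#'
#' @param x an [mln] object.
#' @return logical scalar.
#' @export
is_connected_multiplex <- function(x) {
  igraph::is_connected(aggregate_graph(x, weighted = FALSE))
}

# ---- serialization ---------------------------------------------------------

#' Read and write multiplex edge lists
#'
#' The interchange format is a UTF-8 text file with one edge per line:
#' `layer_name<TAB>word1<TAB>word2`. Lines starting with `#` are skipped.
#' Isolated words do not appear in the edge list, so `read_mln_edges` accepts
#' an optional vocabulary to reinstate them.
#'
#' @param x an [mln] object.
#' @param path file path.
#' @param vocabulary optional vocabulary data frame (see [mln]); words present
#'   in it but absent from the file become isolated vertices on every layer.
#' @param layer_order optional character vector fixing the layer order on read.
#' @return `read_mln_edges` returns an [mln]; `write_mln_edges` returns `path`
#'   invisibly.
#' @export
write_mln_edges <- function(x, path) {
  stopifnot(inherits(x, "mln"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(x$layers)) {
    el <- igraph::as_edgelist(x$layers[[nm]])
    if (nrow(el))
      writeLines(paste(nm, el[, 1L], el[, 2L], sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_mln_edges
#' @export
read_mln_edges <- function(path, vocabulary = NULL, layer_order = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("malformed edge line(s) in ", path)
  tab <- do.call(rbind, parts)
  words <- if (is.null(vocabulary)) sort(unique(c(tab[, 2L], tab[, 3L]))) else
    as.character(vocabulary$word)
  lnames <- if (is.null(layer_order)) unique(tab[, 1L]) else layer_order
  layers <- lapply(lnames, function(nm) {
    make_layer(tab[tab[, 1L] == nm, 2:3, drop = FALSE], words, nm)
  })
  names(layers) <- lnames
  mln(layers, vocabulary = vocabulary)
}

#' Export each layer as GraphML
#'
#' @param x an [mln] object.
#' @param dir output directory; one `<layer>.graphml` file per layer.
#' @return invisible character vector of written paths.
#' @export
write_mln_graphml <- function(x, dir) {
  stopifnot(inherits(x, "mln"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(x$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".graphml"))
    igraph::write_graph(x$layers[[nm]], p, format = "graphml")
    p
  }, character(1))
  invisible(paths)
}

#' Read and write vocabulary attribute tables
#'
#' CSV with columns `word`, and optionally `frequency`, `length`, `ipa`
#' (space-separated phoneme tokens) and `pos`.
#'
#' @param vocab vocabulary data frame.
#' @param path file path.
#' @return `read_vocabulary` returns the data frame; `write_vocabulary`
#'   returns `path` invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.csv(vocab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("word" %in% names(v))
  v$word <- as.character(v$word)
  v
}
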