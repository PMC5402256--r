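#' Specification for a synthetic multiplex lexicon dataset
#'
#' Describes the statistical structure the generator plants: per-layer
#' degree models (exponential-like for the feature and phonological layers,
#' heavy-tailed for the association and co-occurrence layers, with mean
#' degrees matching the empirical scales), a target cross-layer degree
#' correlation matrix realized through a latent Gaussian copula, pairwise
#' edge-overlap boosts, per-layer triadic-closure boosts, and a planted
#' acquisition mechanism: production norms whose onset months follow a
#' convex combination of per-layer word scores.
#'
#' @param N vocabulary size (default 529).
#' @param layers named list of degree models; each element is
#'   `list(model = "exponential", mean = ...)` or
#'   `list(model = "powerlaw", exponent = ..., mean = ...)` (exponent > 2).
#' @param degree_correlation L x L symmetric matrix of target Kendall tau
#'   cross-layer degree correlations (achieved values are approximate and
#'   should always be measured on the generated instance).
#' @param overlap_boost L x L symmetric matrix in `[0, 1]`: fraction of each
#'   layer's edges copied into the partner layer.
#' @param clustering_boost per-layer triadic-closure intensity (closure
#'   attempts as a fraction of the layer's edge count).
#' @param planted_weights convex layer weights driving acquisition onsets.
#' @param planted_metric per-layer score planted: `"degree"` or
#'   `"closeness"`.
#' @param aoa_noise_sd sd (months) of Gaussian noise on onset months.
#' @param months reporting months (default 16:30).
#' @param logistic_slope slope (per month) of the logistic production curves.
#' @param zipf_exponent exponent of the Zipfian word-frequency law.
#' @param length_range integer range of word lengths.
#' @param seed integer master seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(N = 529L,
                           layers = list(
                             association = list(model = "powerlaw",
                                                exponent = 2.5, mean = 9.3),
                             feature = list(model = "exponential", mean = 9.0),
                             cooccurrence = list(model = "powerlaw",
                                                 exponent = 2.5, mean = 8.1),
                             phonological = list(model = "exponential",
                                                 mean = 1.31)),
                           degree_correlation = NULL,
                           overlap_boost = NULL,
                           clustering_boost = NULL,
                           planted_weights = NULL,
                           planted_metric = c("degree", "closeness"),
                           aoa_noise_sd = 0.5,
                           months = 16:30,
                           logistic_slope = 2,
                           zipf_exponent = 1,
                           length_range = c(2L, 10L),
                           seed = 1L) {
  L <- length(layers); nm <- names(layers)
  stopifnot(N >= 2L, L >= 2L, !is.null(nm), logistic_slope > 0,
            aoa_noise_sd >= 0, zipf_exponent > 0)
  for (ly in layers) {
    stopifnot(ly$mean > 0)
    if (ly$model == "powerlaw") stopifnot(ly$exponent > 2)
  }
  named_mat <- function(m, default) {
    if (is.null(m)) m <- default
    stopifnot(isSymmetric(m))
    dimnames(m) <- list(nm, nm)
    m
  }
  # defaults mirror the qualitative empirical pattern: mildly coupled
  # semantic layers, anticorrelated feature/co-occurrence degrees,
  # positively correlated co-occurrence/phonological degrees
  dc <- diag(1, L)
  if (L == 4L && identical(nm, c("association", "feature", "cooccurrence",
                                 "phonological"))) {
    dc[1, 2] <- dc[2, 1] <- 0.20
    dc[1, 3] <- dc[3, 1] <- 0.20
    dc[2, 3] <- dc[3, 2] <- -0.16
    dc[3, 4] <- dc[4, 3] <- 0.27
  }
  ob <- matrix(0, L, L)
  if (L == 4L && identical(nm, c("association", "feature", "cooccurrence",
                                 "phonological"))) {
    ob[1, 2] <- ob[2, 1] <- 0.05
    ob[1, 3] <- ob[3, 1] <- 0.05
    ob[2, 3] <- ob[3, 2] <- 0.05
  }
  cb <- if (L == 4L) c(0.15, 0.35, 0.10, 0.20) else rep(0.15, L)
  pw <- if (L == 4L) c(0.6, 0.2, 0.2, 0.0) else rep(1 / L, L)
  names(cb) <- names(pw) <- nm
  if (!is.null(clustering_boost)) { cb[] <- clustering_boost }
  if (!is.null(planted_weights)) {
    pw <- planted_weights[nm]
    stopifnot(all(pw >= 0), abs(sum(pw) - 1) <= 1e-9)
  }
  structure(list(N = as.integer(N), layers = layers,
                 degree_correlation = named_mat(degree_correlation, dc),
                 overlap_boost = named_mat(overlap_boost, ob),
                 clustering_boost = cb, planted_weights = pw,
                 planted_metric = match.arg(planted_metric),
                 aoa_noise_sd = aoa_noise_sd, months = as.integer(months),
                 logistic_slope = logistic_slope,
                 zipf_exponent = zipf_exponent,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# marginal transform: copula quantile u -> integer degree
degree_from_quantile <- function(u, model, N) {
  k <- switch(model$model,
    exponential = stats::qexp(u, rate = 1 / model$mean),
    powerlaw = {
      xm <- model$mean * (model$exponent - 2) / (model$exponent - 1)
      xm * (1 - u)^(-1 / (model$exponent - 1))
    },
    stop("unknown degree model: ", model$model))
  pmin(as.integer(round(k)), N - 1L)
}

# repair a non-graphical degree sequence by shaving the largest entries
make_graphical <- function(k) {
  attempts <- 0L
  while (!igraph::is_graphical(k)) {
    attempts <- attempts + 1L
    if (attempts > 100L) stop("could not repair degree sequence")
    k[which.max(k)] <- k[which.max(k)] - 1L
    if (sum(k) %% 2L == 1L) {
      i <- which.max(k)
      k[i] <- max(k[i] - 1L, 0L)
    }
  }
  k
}

#' Generate a synthetic multiplex lexical network
#'
#' Samples correlated per-word degree propensities from a latent Gaussian
#' copula (targeting the spec's cross-layer Kendall correlations), maps them
#' through each layer's marginal degree model, realizes every layer as a
#' simple graph with that degree sequence followed by randomizing
#' double-edge swaps, adds triangles by random wedge closure (clustering
#' boost), and finally copies a fraction of edges between layer pairs
#' (overlap boost). Clustering and overlap boosts add edges, so realized
#' mean degrees exceed the marginal targets when boosts are nonzero;
#' achieved correlations and overlaps should be measured on the instance.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (default: the spec's).
#' @return an [mln] on words `w001 ... wN`.
#' @export
generate_multiplex <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$N; L <- length(spec$layers); nm <- names(spec$layers)
  words <- sprintf("w%0*d", nchar(N), seq_len(N))
  with_seed(seed, {
    # latent Gaussian with Pearson rho = sin(pi * tau / 2)
    rho <- sin(pi * spec$degree_correlation / 2)
    diag(rho) <- 1
    ev <- eigen(rho, symmetric = TRUE)
    ev$values <- pmax(ev$values, 1e-8)
    rho <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
    rho <- stats::cov2cor(rho)
    z <- matrix(stats::rnorm(N * L), N, L) %*% chol(rho)
    u <- stats::pnorm(z)
    layers <- vector("list", L); names(layers) <- nm
    for (l in seq_len(L)) {
      k <- degree_from_quantile(u[, l], spec$layers[[l]], N)
      if (sum(k) %% 2L == 1L) {
        i <- sample.int(N, 1L)
        k[i] <- if (k[i] < N - 1L) k[i] + 1L else k[i] - 1L
      }
      k <- make_graphical(k)
      g <- igraph::realize_degseq(k)
      if (igraph::ecount(g) >= 2L)
        g <- igraph::rewire(g, igraph::keeping_degseq(
          niter = 10L * igraph::ecount(g)))
      igraph::V(g)$name <- words
      # triadic closure: close random wedges
      n_close <- round(spec$clustering_boost[l] * igraph::ecount(g))
      if (n_close > 0L) {
        deg <- igraph::degree(g)
        hubs <- which(deg >= 2L)
        adj <- igraph::as_adj_list(g)
        new_edges <- character(0)
        for (i in seq_len(n_close)) {
          if (!length(hubs)) break
          v <- hubs[sample.int(length(hubs), 1L)]
          nb <- adj[[v]]
          pick <- sample.int(length(nb), 2L)
          new_edges <- c(new_edges, words[as.integer(nb[pick])])
        }
        if (length(new_edges)) {
          em <- matrix(new_edges, ncol = 2L, byrow = TRUE)
          em <- em[em[, 1L] != em[, 2L], , drop = FALSE]
          if (nrow(em)) {
            g <- igraph::add_edges(g, as.vector(t(em)))
            g <- igraph::simplify(g)
          }
        }
      }
      g$name <- nm[l]
      layers[[l]] <- g
    }
    # overlap injection: copy a fraction of each layer's edges to partners
    add <- replicate(L, NULL, simplify = FALSE)
    for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
      b <- spec$overlap_boost[i, j]
      if (b <= 0) next
      eli <- igraph::as_edgelist(layers[[i]])
      elj <- igraph::as_edgelist(layers[[j]])
      pick_i <- eli[sample.int(nrow(eli), round(b * nrow(eli))), , drop = FALSE]
      pick_j <- elj[sample.int(nrow(elj), round(b * nrow(elj))), , drop = FALSE]
      add[[j]] <- rbind(add[[j]], pick_i)
      add[[i]] <- rbind(add[[i]], pick_j)
    }
    for (l in seq_len(L)) {
      if (!is.null(add[[l]]) && nrow(add[[l]])) {
        layers[[l]] <- igraph::simplify(
          igraph::add_edges(layers[[l]], as.vector(t(add[[l]]))))
        layers[[l]]$name <- nm[l]
      }
    }
    mln(layers)
  })
}

#' Generate word attributes
#'
#' Zipfian frequencies over a random frequency rank, and integer word
#' lengths negatively rank-correlated with frequency (frequent words tend to
#' be short).
#'
#' @param words character vector of word ids.
#' @param zipf_exponent Zipf exponent (default 1).
#' @param length_range integer length range (default 2-10).
#' @param seed integer seed.
#' @return data frame with columns `word`, `frequency`, `length`.
#' @export
generate_attributes <- function(words, zipf_exponent = 1,
                                length_range = c(2L, 10L), seed = 1L) {
  stopifnot(zipf_exponent > 0)
  n <- length(words)
  with_seed(seed, {
    rk <- sample.int(n)
    freq <- 1e4 / rk^zipf_exponent
    base <- length_range[1L] +
      (length_range[2L] - length_range[1L]) * (rk - 1) / max(n - 1, 1)
    len <- as.integer(round(pmin(pmax(base + stats::rnorm(n, 0, 1),
                                      length_range[1L]), length_range[2L])))
    data.frame(word = words, frequency = freq, length = len,
               stringsAsFactors = FALSE)
  })
}

#' Generate CDI-like production norms with a planted mechanism
#'
#' Computes the planted combined word score (convex combination of per-layer
#' degree or closeness scores), maps the score ranking monotonically onto
#' acquisition-onset months spread across the reporting range (highest score
#' earliest), perturbs onsets with Gaussian noise, and emits logistic
#' production curves `p_w(m) = plogis((m - onset_w) * slope)`. Onsets are
#' confined to at most `3/slope` months before the final month, so every
#' curve reaches at least 0.95 production (and crosses the 0.5 threshold) by
#' the final month.
#'
#' @param x an [mln] object.
#' @param spec a [synthetic_spec()] providing planted weights, metric, noise,
#'   months and slope.
#' @param seed integer seed (default: the spec's, shifted).
#' @return list with `norms` (a [cdi_norms]) and `ground_truth` (list with
#'   `planted_weights`, `planted_scores`, `onset_months`).
#' @export
generate_cdi_norms <- function(x, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(x, "mln"), inherits(spec, "synthetic_spec"))
  words <- x$vocab$word
  scores <- per_layer_metric_scores(x, spec$planted_metric)
  s <- combined_score(scores, spec$planted_weights)
  lo <- min(spec$months)
  hi <- max(spec$months) - 3 / spec$logistic_slope
  rk <- rank(-unclass(s), ties.method = "first")
  onset <- lo + (hi - lo) * (rk - 1) / max(length(words) - 1, 1)
  onset <- with_seed(seed, onset + stats::rnorm(length(onset), 0,
                                                spec$aoa_noise_sd))
  onset <- pmin(pmax(onset, lo), hi)
  prod <- vapply(spec$months, function(m)
    stats::plogis((m - onset) * spec$logistic_slope), numeric(length(words)))
  rownames(prod) <- words
  list(norms = cdi_norms(prod, spec$months),
       ground_truth = list(planted_weights = spec$planted_weights,
                           planted_scores = s,
                           onset_months = stats::setNames(onset, words)))
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_multiplex()], [generate_attributes()] and
#' [generate_cdi_norms()] with seeds derived from the spec's master seed and
#' assembles the result, with the attributes attached to the multiplex
#' vocabulary.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer master seed (default: the spec's).
#' @return a list of class `synthetic_dataset` with elements `mln`, `norms`,
#'   `attributes`, `ground_truth`.
#' @export
generate_dataset <- function(spec, seed = spec$seed) {
  seeds <- split_seed(seed, 3L)
  x <- generate_multiplex(spec, seed = seeds[1L])
  attrs <- generate_attributes(x$vocab$word, spec$zipf_exponent,
                               spec$length_range, seed = seeds[2L])
  x <- mln(x$layers, vocabulary = attrs)
  gen <- generate_cdi_norms(x, spec, seed = seeds[3L])
  structure(list(mln = x, norms = gen$norms, attributes = attrs,
                 ground_truth = gen$ground_truth),
            class = "synthetic_dataset")
}
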