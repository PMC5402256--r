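#' Convex layer weights
#'
#' Validates a vector of layer influences: nonnegative, summing to 1
#' (tolerance 1e-9).
#'
#' @param w named numeric vector of weights.
#' @return the validated weights.
#' @export
layer_weights <- function(w) {
  stopifnot(is.numeric(w), !is.null(names(w)), all(w >= 0),
            abs(sum(w) - 1) <= 1e-9)
  w
}

# map unconstrained nonnegative coordinates onto the simplex
simplex_normalize <- function(x) {
  s <- sum(x)
  if (s <= 0) stop("weights must have positive sum")
  x / s
}

#' Normalize a score vector
#'
#' Per-layer scores are brought to a common scale before they are combined:
#' `"minmax"` rescales to `[0, 1]` (a constant vector maps to all zeros);
#' `"rank"` uses average ranks rescaled to `[0, 1]`; `"zscore"` centres and
#' scales to unit sd. Without this step, raw scales of different metrics
#' (degree around 9, closeness around 0.3) would make weights meaningless.
#'
#' @param s numeric vector.
#' @param method `"minmax"`, `"rank"` or `"zscore"`.
#' @return normalized numeric vector (names preserved).
#' @export
normalize_scores <- function(s, method = c("minmax", "rank", "zscore")) {
  method <- match.arg(method)
  switch(method,
    minmax = {
      r <- range(s)
      if (r[2L] == r[1L]) rep(0, length(s)) |> stats::setNames(names(s)) else
        (s - r[1L]) / (r[2L] - r[1L])
    },
    rank = (rank(s, ties.method = "average") - 1) / max(length(s) - 1, 1),
    zscore = {
      sd <- stats::sd(s)
      if (sd == 0) rep(0, length(s)) |> stats::setNames(names(s)) else
        (s - mean(s)) / sd
    })
}

#' Combined word score from weighted layers
#'
#' The weighted-multiplex word score is the convex combination
#' `s_w = sum over layers of weight_layer * normalized score_layer(w)`,
#' where each layer's scores are first normalized (see
#' [normalize_scores()]).
#'
#' @param per_layer_scores named list of named numeric score vectors, one per
#'   layer, all covering the same vocabulary.
#' @param weights named nonnegative weights covering exactly those layers
#'   (normalized to sum 1 internally).
#' @param normalization per-layer normalization scheme (default `"minmax"`).
#' @return a `word_scores` named numeric vector.
#' @export
combined_score <- function(per_layer_scores, weights,
                           normalization = c("minmax", "rank", "zscore")) {
  normalization <- match.arg(normalization)
  stopifnot(is.list(per_layer_scores), length(per_layer_scores) >= 1L)
  if (!setequal(names(weights), names(per_layer_scores)))
    stop("weights must cover exactly the provided layers")
  weights <- simplex_normalize(weights[names(per_layer_scores)])
  words <- names(per_layer_scores[[1L]])
  s <- rep(0, length(words)) |> stats::setNames(words)
  for (nm in names(per_layer_scores)) {
    v <- per_layer_scores[[nm]]
    stopifnot(setequal(names(v), words))
    s <- s + weights[[nm]] * normalize_scores(unclass(v)[words], normalization)
  }
  word_scores(s, paste0("combined_", normalization), "multiplex")
}

# Precompute everything the DE objective needs for one evaluation problem:
# normalized per-layer scores (matrix), reference positions, the per-word
# fraction of references reached by each window t, and the analytic random
# baseline over the window.
make_objective_context <- function(per_layer_scores, ref_ensemble, window,
                                   normalization = "minmax",
                                   n_window_points = 25L) {
  words <- names(per_layer_scores[[1L]])
  n <- length(words)
  S <- vapply(per_layer_scores, function(v)
    normalize_scores(unclass(v)[words], normalization), numeric(n))
  refs <- ref_ensemble$trajectories
  qmat <- vapply(refs, function(r) traj_positions(r)[words], numeric(n))
  lo <- max(1L, window[1L]); hi <- min(n, window[2L])
  if (hi < lo) stop("empty evaluation window")
  ts <- unique(round(seq(lo, hi, length.out = min(hi - lo + 1L, n_window_points))))
  Fmat <- vapply(ts, function(t) rowMeans(qmat <= t), numeric(n))
  list(words = words, n = n, S = S, ts = ts, Fmat = Fmat,
       base_mean = ts^2 / n)
}

# mean normalized gain over the window for raw (unnormalized) weights
objective_value <- function(ctx, raw_weights) {
  if (sum(raw_weights) <= 1e-12) return(-Inf)
  w <- raw_weights / sum(raw_weights)
  s <- drop(ctx$S %*% w)
  ord <- order(s, decreasing = TRUE)
  sv <- s[ord]
  lens <- rle(sv)$lengths
  starts <- cumsum(c(1L, lens[-length(lens)]))
  a_pos <- rep.int(starts, lens)
  sz_pos <- rep.int(lens, lens)
  aw <- sw <- numeric(ctx$n)
  aw[ord] <- a_pos; sw[ord] <- sz_pos
  Tm <- matrix(ctx$ts, ctx$n, length(ctx$ts), byrow = TRUE)
  P <- pmin(1, pmax(0, (Tm - aw + 1) / sw))
  Eo <- colSums(P * ctx$Fmat)
  mean((Eo - ctx$base_mean) / ctx$ts)
}

#' Objective: mean normalized word gain of a weighted combination
#'
#' Evaluates a candidate weight vector: builds the combined-score predicted
#' trajectory (exact expected tie handling) and returns the mean
#' vocabulary-normalized word gain over the inventory-size window, averaged
#' over the reference ensemble. When `holdout` names words, those words are
#' removed from the problem (scores and references are restricted and the
#' window rescaled proportionally), which is how the Monte Carlo robustness
#' analysis evaluates candidate weights on 80% subsets.
#'
#' @param weights named nonnegative layer weights.
#' @param per_layer_scores named list of per-layer score vectors.
#' @param ref_ensemble reference `trajectory_ensemble`.
#' @param window length-2 inventory-size range `c(lo, hi)`.
#' @param holdout optional character vector of word ids to remove.
#' @param normalization per-layer score normalization (default `"minmax"`).
#' @return mean normalized gain (numeric scalar).
#' @export
objective <- function(weights, per_layer_scores, ref_ensemble, window,
                      holdout = NULL, normalization = "minmax") {
  if (is.null(names(weights))) {
    stopifnot(length(weights) == length(per_layer_scores))
    names(weights) <- names(per_layer_scores)
  } else if (!setequal(names(weights), names(per_layer_scores))) {
    stop("weight names must match the layer-score names")
  }
  if (!is.null(holdout) && length(holdout) > 0L) {
    res <- restrict_problem(per_layer_scores, ref_ensemble, window, holdout)
    per_layer_scores <- res$scores; ref_ensemble <- res$refs
    window <- res$window
  }
  ctx <- make_objective_context(per_layer_scores, ref_ensemble, window,
                                normalization,
                                n_window_points = .Machine$integer.max)
  objective_value(ctx, unname(weights[names(per_layer_scores)]))
}

# drop held-out words from scores and references; rescale the t window
restrict_problem <- function(per_layer_scores, ref_ensemble, window, holdout) {
  words <- names(per_layer_scores[[1L]])
  retained <- setdiff(words, holdout)
  frac <- length(retained) / length(words)
  scores <- lapply(per_layer_scores, function(v) unclass(v)[retained])
  refs <- trajectory_ensemble(lapply(ref_ensemble$trajectories, function(tr)
    new_trajectory(as.character(tr)[as.character(tr) %in% retained],
                   attr(tr, "label"))))
  win <- pmax(1L, pmin(length(retained), round(window * frac)))
  list(scores = scores, refs = refs, window = win, retained = retained)
}

#' Differential evolution over box constraints
#'
#' A classic rand/1/bin differential-evolution optimizer (maximization),
#' used to search the layer-weight simplex: each candidate is a vector of
#' nonnegative box-bounded coordinates that the objective normalizes to sum
#' one, so the simplex constraint never has to be handled by the optimizer
#' itself. Mutation factors are dithered uniformly in `[0.5, 1]` per
#' generation. Converges when the population's fitness spread falls below
#' `tol * (|mean fitness| + tol)` or after `max_generations`.
#'
#' @param fn objective to maximize, taking a numeric vector.
#' @param n_dim dimensionality.
#' @param lower,upper box bounds (scalars).
#' @param pop_size population size (default `15 * n_dim`).
#' @param recombination crossover probability CR (default 0.7).
#' @param max_generations generation cap (default 200).
#' @param tol convergence tolerance (default 1e-6).
#' @param init optional matrix of initial candidates (rows), e.g. to seed a
#'   known point into the population.
#' @param seed integer seed.
#' @return list with `par`, `value`, `generations`, `converged`.
#' @export
de_optimize <- function(fn, n_dim, lower = 0, upper = 1,
                        pop_size = 15L * n_dim, recombination = 0.7,
                        max_generations = 200L, tol = 1e-6,
                        init = NULL, seed = 1L) {
  with_seed(seed, {
    pop <- matrix(stats::runif(pop_size * n_dim, lower, upper),
                  pop_size, n_dim)
    if (!is.null(init)) {
      init <- matrix(init, ncol = n_dim)
      pop[seq_len(min(nrow(init), pop_size)), ] <- init[seq_len(min(nrow(init), pop_size)), ]
    }
    fit <- apply(pop, 1L, fn)
    gen <- 0L; converged <- FALSE
    while (gen < max_generations) {
      gen <- gen + 1L
      f_mut <- stats::runif(1L, 0.5, 1)
      for (i in seq_len(pop_size)) {
        r <- sample(setdiff(seq_len(pop_size), i), 3L)
        mutant <- pop[r[1L], ] + f_mut * (pop[r[2L], ] - pop[r[3L], ])
        mutant <- pmin(upper, pmax(lower, mutant))
        jrand <- sample.int(n_dim, 1L)
        cross <- stats::runif(n_dim) < recombination
        cross[jrand] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        f_trial <- fn(trial)
        if (f_trial >= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- f_trial
        }
      }
      fin <- fit[is.finite(fit)]
      if (length(fin) == pop_size &&
          stats::sd(fin) <= tol * (abs(mean(fin)) + tol)) {
        converged <- TRUE
        break
      }
    }
    best <- which.max(fit)
    list(par = pop[best, ], value = fit[best], generations = gen,
         converged = converged)
  })
}

#' Optimization configuration
#'
#' Collects the knobs of the layer-influence optimization: the per-layer
#' metric, the inventory-size window the mean normalized gain is averaged
#' over, the Monte Carlo hold-out scheme (by default 50 random removals of
#' 20% of the words) and the differential-evolution parameters.
#'
#' @param metric per-layer word score: `"degree"`, `"closeness"`,
#'   `"betweenness"` or `"clustering"`.
#' @param window length-2 inventory-size range.
#' @param holdout_fraction fraction of words removed per configuration
#'   (default 0.2).
#' @param n_holdout_configs number of random hold-out configurations
#'   (default 50).
#' @param holdout_mode `"masked"` (default: full-network scores, with the
#'   held-out words removed from the predicted and reference trajectories —
#'   the hold-out operates on subsets of word trajectories) or `"induced"`
#'   (per-layer scores recomputed on the subnetwork induced by the retained
#'   words; answers a different robustness question and biases parameter
#'   recovery on planted data).
#' @param normalization per-layer score normalization (default `"minmax"`).
#' @param drop_layers optional layer names excluded from the combination.
#' @param n_window_points number of window grid points used by the DE
#'   objective (default 25).
#' @param de list of DE parameters (see [de_optimize()]).
#' @param seed integer master seed.
#' @return a list of class `optimization_config`.
#' @export
optimization_config <- function(metric = c("degree", "closeness",
                                           "betweenness", "clustering"),
                                window, holdout_fraction = 0.2,
                                n_holdout_configs = 50L,
                                holdout_mode = c("masked", "induced"),
                                normalization = "minmax",
                                drop_layers = NULL,
                                n_window_points = 25L,
                                de = list(recombination = 0.7,
                                          max_generations = 200L,
                                          tol = 1e-6),
                                seed = 1L) {
  stopifnot(holdout_fraction >= 0, holdout_fraction < 1,
            n_holdout_configs >= 1L, length(window) == 2L)
  structure(list(metric = match.arg(metric), window = as.integer(window),
                 holdout_fraction = holdout_fraction,
                 n_holdout_configs = as.integer(n_holdout_configs),
                 holdout_mode = match.arg(holdout_mode),
                 normalization = normalization, drop_layers = drop_layers,
                 n_window_points = as.integer(n_window_points),
                 de = de, seed = as.integer(seed)),
            class = "optimization_config")
}

# per-layer word scores for the optimization metric, on one graph
metric_scores <- function(layer, metric) {
  if (metric == "clustering") {
    s <- igraph::transitivity(layer, type = "local", isolates = "zero")
    stats::setNames(s, igraph::V(layer)$name)
  } else {
    unclass(layer_centrality(layer, metric))
  }
}

per_layer_metric_scores <- function(x, metric, drop_layers = NULL,
                                    words = NULL) {
  layers <- x$layers
  if (!is.null(drop_layers)) layers <- layers[setdiff(names(layers), drop_layers)]
  if (!is.null(words))
    layers <- lapply(layers, function(g) igraph::induced_subgraph(g, words))
  lapply(layers, metric_scores, metric = metric)
}

#' Optimize layer influences by differential evolution
#'
#' For each of `n_holdout_configs` random word removals, runs differential
#' evolution over raw nonnegative layer coordinates (normalized to the
#' simplex inside the objective) to maximize the mean vocabulary-normalized
#' word gain over the configured window against the reference ensemble.
#' Reports per-run optimal weights, their mean and sd, and the gain curve
#' achieved by the mean weights on the full vocabulary.
#'
#' @param x an [mln] object.
#' @param ref_ensemble reference `trajectory_ensemble` over the vocabulary.
#' @param config an [optimization_config()].
#' @param init_weights optional matrix of weight vectors seeded into every
#'   DE initial population.
#' @return an object of class `optimization_result`: list with
#'   `per_run_weights` (runs x layers matrix), `mean_weights`, `sd_weights`,
#'   `per_run_value`, `converged` (logical vector), `achieved`
#'   (a [gain_curve()] at the mean weights, full vocabulary, full t range),
#'   `mean_window_gain` (objective of the mean weights on the full problem)
#'   and `config`.
#' @export
optimize_weights <- function(x, ref_ensemble, config, init_weights = NULL) {
  stopifnot(inherits(x, "mln"), inherits(config, "optimization_config"))
  words <- x$vocab$word
  lnames <- setdiff(names(x$layers), config$drop_layers)
  L <- length(lnames)
  full_scores <- per_layer_metric_scores(x, config$metric, config$drop_layers)
  seeds <- split_seed(config$seed, 2L * config$n_holdout_configs)
  n_hold <- round(config$holdout_fraction * length(words))
  runs <- matrix(NA_real_, config$n_holdout_configs, L,
                 dimnames = list(NULL, lnames))
  vals <- numeric(config$n_holdout_configs)
  conv <- logical(config$n_holdout_configs)
  for (h in seq_len(config$n_holdout_configs)) {
    holdout <- if (n_hold > 0L)
      with_seed(seeds[h], sample(words, n_hold)) else character()
    retained <- setdiff(words, holdout)
    scores_h <- if (config$holdout_mode == "induced" && n_hold > 0L)
      per_layer_metric_scores(x, config$metric, config$drop_layers,
                              words = retained)
    else lapply(full_scores, function(v) v[retained])
    refs_h <- restrict_problem(full_scores, ref_ensemble, config$window,
                               holdout)$refs
    win_h <- pmax(1L, pmin(length(retained),
                           round(config$window * length(retained) / length(words))))
    ctx <- make_objective_context(scores_h, refs_h, win_h,
                                  config$normalization,
                                  config$n_window_points)
    fit <- de_optimize(function(v) objective_value(ctx, v), n_dim = L,
                       pop_size = 15L * L,
                       recombination = config$de$recombination,
                       max_generations = config$de$max_generations,
                       tol = config$de$tol, init = init_weights,
                       seed = seeds[config$n_holdout_configs + h])
    if (!fit$converged)
      warning("DE did not converge in hold-out run ", h,
              "; best-found weights returned")
    runs[h, ] <- simplex_normalize(fit$par)
    vals[h] <- fit$value
    conv[h] <- fit$converged
  }
  mean_w <- simplex_normalize(colMeans(runs))
  sd_w <- apply(runs, 2L, stats::sd)
  n <- length(words)
  base <- random_baseline(n)
  pred <- rank_by_score(combined_score(full_scores, mean_w,
                                       config$normalization),
                        tie_policy = "expected",
                        label = paste0("optimal_", config$metric))
  achieved <- gain_curve(pred, ref_ensemble, base)
  mean_gain <- objective(mean_w, full_scores, ref_ensemble, config$window,
                         normalization = config$normalization)
  structure(list(per_run_weights = runs, mean_weights = mean_w,
                 sd_weights = sd_w, per_run_value = vals, converged = conv,
                 achieved = achieved, mean_window_gain = mean_gain,
                 config = config),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Layer-influence optimization (%s metric, window %d-%d)\n",
              x$config$metric, x$config$window[1L], x$config$window[2L]))
  w <- rbind(mean = x$mean_weights, sd = x$sd_weights)
  print(round(w, 4))
  cat(sprintf("mean window gain at mean weights: %.4f\n", x$mean_window_gain))
  invisible(x)
}

#' Randomized-multiplex control for the optimization
#'
#' Replaces every layer with a degree-preserving randomization (double-edge
#' swaps) and reruns [optimize_weights()] on the randomized multiplex. If
#' predictive power comes from the actual layer structure rather than from
#' degree sequences alone, the control achieves a clearly smaller optimized
#' gain.
#'
#' @inheritParams optimize_weights
#' @param n_swaps_per_edge swaps per edge in the layer randomization.
#' @param seed seed for the randomization (default derived from config).
#' @return list with `control` (the control's `optimization_result`) and
#'   `randomized_mln`.
#' @export
randomized_multiplex_control <- function(x, ref_ensemble, config,
                                         n_swaps_per_edge = 10L,
                                         seed = NULL) {
  if (is.null(seed)) seed <- split_seed(config$seed + 1L, 1L)
  rnd <- with_seed(seed, {
    layers <- lapply(x$layers, function(g) {
      if (igraph::ecount(g) < 2L) return(g)
      igraph::rewire(g, igraph::keeping_degseq(
        niter = n_swaps_per_edge * igraph::ecount(g)))
    })
    mln(layers, vocabulary = x$vocab)
  })
  list(control = optimize_weights(rnd, ref_ensemble, config),
       randomized_mln = rnd)
}
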