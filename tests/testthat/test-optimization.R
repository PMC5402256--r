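test_that("layer weights must form a simplex point", {
  expect_silent(layer_weights(c(a = 0.6, b = 0.4)))
  expect_error(layer_weights(c(a = 0.7, b = 0.4)))
  expect_error(layer_weights(c(a = -0.1, b = 1.1)))
  expect_error(layer_weights(c(0.5, 0.5)))
})

test_that("combined scores reduce to single layers at simplex vertices", {
  set.seed(4)
  words <- sprintf("w%02d", 1:15)
  sc <- list(l1 = stats::setNames(rnorm(15), words),
             l2 = stats::setNames(rnorm(15), words),
             l3 = stats::setNames(rnorm(15), words))
  vert <- combined_score(sc, c(l1 = 1, l2 = 0, l3 = 0))
  expect_equal(order(-unclass(vert)), order(-sc$l1))

  same <- list(a = sc$l1, b = sc$l1)
  unif <- combined_score(same, c(a = 0.5, b = 0.5))
  expect_equal(order(-unclass(unif)), order(-sc$l1))

  # direct arithmetic oracle for minmax normalization
  w <- c(l1 = 0.2, l2 = 0.5, l3 = 0.3)
  got <- combined_score(sc, w)
  mm <- function(v) (v - min(v)) / (max(v) - min(v))
  want <- 0.2 * mm(sc$l1) + 0.5 * mm(sc$l2) + 0.3 * mm(sc$l3)
  expect_equal(unclass(got), want[words], ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(combined_score(sc, c(l1 = 1, lx = 0, l3 = 0)), "exactly")
})

test_that("the objective is invariant to per-layer affine rescaling", {
  ds <- small_dataset(N = 40, seed = 9)
  aoa <- sample_aoa_ensemble(ds$norms, n = 5, seed = 2)
  sc <- lexiplex:::per_layer_metric_scores(ds$mln, "degree")
  w <- c(association = 0.4, feature = 0.3, cooccurrence = 0.2,
         phonological = 0.1)
  o1 <- objective(w, sc, aoa, c(3, 35))
  sc2 <- sc
  sc2$feature <- 7 * sc2$feature + 3          # affine rescale of one layer
  expect_equal(objective(w, sc2, aoa, c(3, 35)), o1, tolerance = 1e-12)
  # rank normalization is invariant under any monotone rescaling
  o3 <- objective(w, sc, aoa, c(3, 35), normalization = "rank")
  sc3 <- sc
  sc3$feature <- sc3$feature^3
  expect_equal(objective(w, sc3, aoa, c(3, 35), normalization = "rank"), o3,
               tolerance = 1e-12)
})

test_that("the objective attains its closed-form bounds in edge cases", {
  words <- sprintf("w%02d", 1:30)
  ref <- lexiplex:::new_trajectory(words, "ref")
  ens <- lexiplex:::trajectory_ensemble(list(ref))
  # perfect information: scores are the reversed reference positions
  perfect <- stats::setNames(rev(seq_along(words)), words)
  sc <- list(a = perfect, b = perfect)
  win <- c(5, 25)
  got <- objective(c(a = 0.7, b = 0.3), sc, ens, win)
  expect_equal(got, mean(1 - (5:25) / 30), tolerance = 1e-12)

  # fully tied scores carry no information: expected gain exactly zero
  tied <- list(a = stats::setNames(rep(1, 30), words),
               b = stats::setNames(rep(2, 30), words))
  expect_equal(objective(c(a = 0.5, b = 0.5), tied, ens, win), 0,
               tolerance = 1e-12)
})

test_that("planted weights beat random simplex points on noiseless data", {
  ds <- small_dataset(N = 100, seed = 14)
  aoa <- sample_aoa_ensemble(ds$norms, n = 10, seed = 3)
  sc <- lexiplex:::per_layer_metric_scores(ds$mln, "degree")
  pw <- ds$ground_truth$planted_weights
  win <- c(5, 80)
  o_pl <- objective(pw, sc, aoa, win)
  set.seed(6)
  beats <- vapply(1:100, function(i) {
    w <- stats::rexp(4)
    o_pl >= objective(stats::setNames(w / sum(w), names(pw)), sc, aoa, win)
  }, TRUE)
  expect_gte(mean(beats), 0.95)
})

test_that("differential evolution solves a smooth concave problem", {
  target <- c(0.2, 0.7, 0.4)
  fit <- de_optimize(function(x) -sum((x - target)^2), n_dim = 3, seed = 5)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$par - target)), 0.01)
})

test_that("seeding the planted point guarantees no worse an optimum", {
  ds <- small_dataset(N = 60, seed = 21)
  aoa <- sample_aoa_ensemble(ds$norms, n = 8, seed = 4)
  sc <- lexiplex:::per_layer_metric_scores(ds$mln, "degree")
  pw <- ds$ground_truth$planted_weights
  ctx <- lexiplex:::make_objective_context(sc, aoa, c(3, 50))
  fit <- de_optimize(function(v) lexiplex:::objective_value(ctx, v),
                     n_dim = 4, init = rbind(unname(pw)), seed = 7,
                     max_generations = 60)
  expect_gte(fit$value, lexiplex:::objective_value(ctx, unname(pw)) - 1e-6)
})

test_that("optimization recovers an informative layer among noise", {
  # layer 1 carries the acquisition signal; layers 2-3 are pure noise
  set.seed(31)
  words <- sprintf("w%03d", 1:80)
  ref_order <- sample(words)
  signal <- stats::setNames(rev(seq_along(words))[match(words, ref_order)],
                            words)
  noise <- function(s) stats::setNames(stats::rnorm(80, sd = 1), words)
  sc <- list(sig = signal, n1 = noise(), n2 = noise())
  ens <- lexiplex:::trajectory_ensemble(
    list(lexiplex:::new_trajectory(ref_order, "ref")))
  ctx <- lexiplex:::make_objective_context(sc, ens, c(5, 60))
  fit <- de_optimize(function(v) lexiplex:::objective_value(ctx, v),
                     n_dim = 3, seed = 11)
  w <- fit$par / sum(fit$par)
  expect_gt(w[1L], 0.8)
})

test_that("duplicate informative layers share the informative mass", {
  set.seed(33)
  words <- sprintf("w%03d", 1:80)
  ref_order <- sample(words)
  signal <- stats::setNames(rev(seq_along(words))[match(words, ref_order)],
                            words)
  sc <- list(s1 = signal, s2 = signal,
             n1 = stats::setNames(stats::rnorm(80), words))
  ens <- lexiplex:::trajectory_ensemble(
    list(lexiplex:::new_trajectory(ref_order, "ref")))
  ctx <- lexiplex:::make_objective_context(sc, ens, c(5, 60))
  fit <- de_optimize(function(v) lexiplex:::objective_value(ctx, v),
                     n_dim = 3, seed = 12)
  w <- fit$par / sum(fit$par)
  expect_gt(w[1L] + w[2L], 0.9)   # split between the twins unconstrained
})

test_that("optimize_weights returns valid simplex weights and gain curves", {
  ds <- small_dataset(N = 50, seed = 17)
  aoa <- sample_aoa_ensemble(ds$norms, n = 5, seed = 5)
  oc <- optimization_config(metric = "degree", window = c(3, 40),
                            n_holdout_configs = 3, seed = 19,
                            de = list(recombination = 0.7,
                                      max_generations = 60, tol = 1e-6))
  res <- suppressWarnings(optimize_weights(ds$mln, aoa, oc))
  expect_s3_class(res, "optimization_result")
  expect_equal(sum(res$mean_weights), 1, tolerance = 1e-9)
  expect_true(all(res$mean_weights >= 0))
  expect_true(all(abs(rowSums(res$per_run_weights) - 1) < 1e-9))
  expect_s3_class(res$achieved, "gain_curve")
  expect_equal(nrow(res$achieved), 50)

  ctrl <- suppressWarnings(
    randomized_multiplex_control(ds$mln, aoa, oc))
  expect_equal(sum(ctrl$control$mean_weights), 1, tolerance = 1e-9)
  expect_true(all(ctrl$control$mean_weights >= 0))
  # degree sequences preserved by the control randomization
  for (nm in names(ds$mln$layers))
    expect_equal(igraph::degree(ctrl$randomized_mln$layers[[nm]]),
                 igraph::degree(ds$mln$layers[[nm]]))
})
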