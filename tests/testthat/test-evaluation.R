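perm_traj <- function(words, seed = NULL, label = "t") {
  if (!is.null(seed)) words <- withr::with_seed(seed, sample(words))
  lexiplex:::new_trajectory(words, label)
}

test_that("overlap counts the shared early vocabulary", {
  tau <- perm_traj(c("a", "b", "c", "d"))
  ref <- perm_traj(c("c", "d", "a", "b"))
  expect_equal(overlap(tau, ref, 2), 0)
  expect_equal(overlap(tau, ref, 4), 4)
  for (t in 1:4) expect_equal(overlap(tau, tau, t), t)
  expect_equal(overlap(tau, ref, 2), overlap(ref, tau, 2))
  expect_error(overlap(tau, ref, 5), "must be in")

  words <- sprintf("w%02d", 1:20)
  for (seed in 1:5) {
    t1 <- perm_traj(words, seed)
    t2 <- perm_traj(words, seed + 100)
    cu <- lexiplex:::overlap_curve(t1, t2)
    for (t in 1:20)
      expect_equal(cu[t], length(intersect(t1[1:t], t2[1:t])))
  }
})

test_that("mean overlap averages the ensemble and handles ties exactly", {
  words <- sprintf("w%02d", 1:12)
  tau <- perm_traj(words, 1)
  ens <- lexiplex:::trajectory_ensemble(list(tau, tau, tau))
  for (t in c(1, 5, 12))
    expect_equal(mean_overlap(perm_traj(words, 2), ens, t),
                 overlap(perm_traj(words, 2), tau, t))

  # fully tied prediction: expected overlap equals the analytic random mean
  tied <- rank_by_score(stats::setNames(rep(1, 12), words))
  refs <- lexiplex:::trajectory_ensemble(lapply(1:4, function(s)
    perm_traj(words, s)))
  base <- random_baseline(12)
  for (t in 1:12)
    expect_equal(mean_overlap(tied, refs, t), base$mean_overlap[t],
                 tolerance = 1e-12)

  # expected-policy equals Monte Carlo tie resolutions within 3 SEs
  set.seed(7)
  s <- stats::setNames(sample(1:4, 12, TRUE), words)   # heavy ties
  expected <- gain_curve(rank_by_score(s, "expected"), refs, base)
  mc <- rank_by_score(s, "resolutions", n_resolutions = 5000, seed = 3)
  for (t in c(3, 6, 9)) {
    draws <- vapply(mc$trajectories, function(tr)
      mean(vapply(refs$trajectories, function(r) overlap(tr, r, t), 0)), 0)
    se <- stats::sd(draws) / sqrt(length(draws))
    expect_lt(abs(expected$overlap[t] - mean(draws)), 3 * se + 1e-9)
  }
})

test_that("the analytic baseline matches exhaustive permutation enumeration", {
  # N = 4: all 24 permutations
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  for (N in c(4L, 5L)) {
    words <- letters[1:N]
    all_p <- perms(words)
    base <- random_baseline(N)
    for (t in 1:N) {
      ov <- vapply(all_p, function(p)
        length(intersect(p[1:t], words[1:t])), 0L)
      expect_equal(base$mean_overlap[t], mean(ov), tolerance = 1e-12)
      expect_equal(base$sd_overlap[t],
                   sqrt(mean((ov - mean(ov))^2)), tolerance = 1e-12)
    }
  }
  base4 <- random_baseline(4)
  expect_equal(base4$mean_overlap[2], 1.0)
  expect_equal(base4$sd_overlap[2], sqrt(2 * 0.5 * 0.5 * 2 / 3),
               tolerance = 1e-9)
  expect_equal(base4$mean_overlap[4], 4)
  expect_equal(base4$sd_overlap[4], 0)
})

test_that("gain curves reproduce closed forms for perfect predictions", {
  words <- sprintf("w%02d", 1:30)
  ref <- perm_traj(words, 4)
  ens <- lexiplex:::trajectory_ensemble(list(ref))
  base <- random_baseline(30)
  cu <- gain_curve(ref, ens, base)
  for (t in 1:29)
    expect_equal(cu$norm_gain[t], 1 - t / 30, tolerance = 1e-12)

  # the worked three-word example: O = (1, 2, 3), g = t - t^2/3
  s <- c(food = 62, water = 45, eat = 20)
  pred <- rank_by_score(s)
  ref3 <- lexiplex:::trajectory_ensemble(
    list(perm_traj(c("food", "water", "eat"))))
  cu3 <- gain_curve(pred, ref3, random_baseline(3))
  expect_equal(cu3$overlap, c(1, 2, 3))
  expect_equal(cu3$gain, c(1, 2, 3) - (1:3)^2 / 3)
})

test_that("random predictions fluctuate around zero gain", {
  words <- sprintf("w%03d", 1:100)
  ref <- perm_traj(words, 5)
  ens <- lexiplex:::trajectory_ensemble(list(ref))
  base <- random_baseline(100)
  z60 <- vapply(1:60, function(s)
    gain_curve(perm_traj(words, s + 10), ens, base)$zscore[60], 0)
  expect_lt(abs(mean(z60)), 0.5)
  expect_gt(stats::sd(z60), 0.5)
})

test_that("significance combines Gaussian and direct-sampling branches", {
  expect_equal(round(critical_z(0.025), 2), 1.96)

  words <- sprintf("w%03d", 1:100)
  ref <- perm_traj(words, 2)
  ens <- lexiplex:::trajectory_ensemble(list(ref))
  base <- random_baseline(100)
  cu <- significance(gain_curve(ref, ens, base), base, gaussian_min_t = 60,
                     n_direct = 1000, seed = 1)
  # perfect prediction: tiny Gaussian p deep in the curve
  expect_lt(cu$pvalue[70], 1e-6)
  expect_equal(cu$significance_method[70], "gaussian")
  expect_equal(cu$significance_method[10], "direct_sampling")
  expect_lt(cu$pvalue[10], 0.01)

  # Z = 0 maps to Gaussian p = 0.5
  cu2 <- gain_curve(ref, ens, base)
  cu2$zscore[] <- 0
  cu2 <- significance(cu2, base, gaussian_min_t = 1)
  expect_equal(cu2$pvalue[50], 0.5)

  # direct sampling at t = N: every permutation reaches full overlap
  words8 <- letters[1:8]
  ref8 <- perm_traj(words8)
  ens8 <- lexiplex:::trajectory_ensemble(list(ref8))
  base8 <- random_baseline(8)
  cu8 <- significance(gain_curve(ref8, ens8, base8), base8,
                      gaussian_min_t = 100, n_direct = 1000, seed = 2)
  expect_equal(cu8$pvalue[8], 1)

  # ensemble-based direct sampling agrees with the hypergeometric branch
  refs <- lexiplex:::trajectory_ensemble(list(ref8))
  cu8e <- significance(gain_curve(ref8, ens8, base8), base8,
                       ref_ensemble = refs, gaussian_min_t = 100,
                       n_direct = 2000, seed = 3)
  expect_equal(cu8e$pvalue[8], 1)
  expect_lt(abs(cu8e$pvalue[4] - cu8$pvalue[4]), 0.05)
})

test_that("stage ranking rewards uniformly higher normalized gain", {
  words <- sprintf("w%02d", 1:50)
  ref <- perm_traj(words, 3)
  ens <- lexiplex:::trajectory_ensemble(list(ref))
  base <- random_baseline(50)
  good <- gain_curve(ref, ens, base, label = "good")
  bad <- gain_curve(perm_traj(words, 99), ens, base, label = "bad")
  m2t <- stats::setNames(as.integer(round(seq(2, 50, length.out = 15))), 16:30)
  win <- stage_windows(vels_t = c(1L, 10L))
  rep1 <- stage_report(list(good), win, m2t)
  expect_true(all(rep1$rank == 1))
  rep2 <- stage_report(list(good, bad), win, m2t)
  expect_true(all(rep2$rank[rep2$label == "good"] == 1))
  expect_true(all(rep2$rank[rep2$label == "bad"] == 2))
})

test_that("normalized gain respects its analytic bounds", {
  words <- sprintf("w%02d", 1:25)
  base <- random_baseline(25)
  ref <- perm_traj(words, 8)
  ens <- lexiplex:::trajectory_ensemble(list(ref))
  for (seed in 1:6) {
    cu <- gain_curve(perm_traj(words, seed), ens, base)
    expect_true(all(cu$norm_gain <= 1 - base$mean_overlap / cu$t + 1e-12))
    expect_true(all(cu$norm_gain >= -base$mean_overlap / cu$t - 1e-12))
    expect_true(all(diff(cu$overlap) >= -1e-12))
    expect_equal(cu$overlap[25], 25)
  }
})
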