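toy_norms <- function() {
  # mommy and ball producible by >= half the children at month 16,
  # chair not until month 18
  prod <- rbind(mommy = c(0.93, 0.95, 0.97),
                ball = c(0.64, 0.70, 0.80),
                chair = c(0.14, 0.30, 0.55))
  cdi_norms(prod, months = 16:18)
}

test_that("cdi_norms validates and round-trips through CSV", {
  n <- toy_norms()
  expect_s3_class(n, "cdi_norms")
  expect_error(cdi_norms(rbind(a = c(0.5, 1.2)), months = 16:17), ">=")
  f <- withr::local_tempfile(fileext = ".csv")
  write_cdi_norms(n, f)
  n2 <- read_cdi_norms(f)
  expect_equal(n2$production[rownames(n$production), ], n$production)
  expect_equal(n2$months, n$months)
})

test_that("aoa sampling drains eligible words month by month", {
  n <- toy_norms()
  for (seed in 1:20) {
    tr <- sample_aoa_ordering(n, seed = seed)
    expect_setequal(as.character(tr), rownames(n$production))
    # chair only becomes eligible at month 18, after mommy and ball are drawn
    expect_equal(as.character(tr)[3L], "chair")
    expect_true(!is.unsorted(attr(tr, "sampling_month")))
  }
})

test_that("a word alone above threshold at the first month is always first", {
  prod <- rbind(early = c(0.8, 0.9, 1.0), late1 = c(0.1, 0.8, 0.9),
                late2 = c(0.2, 0.9, 0.95))
  n <- cdi_norms(prod, months = 16:18)
  for (seed in 1:10)
    expect_equal(as.character(sample_aoa_ordering(n, seed = seed))[1L],
                 "early")
})

test_that("words never reaching threshold are appended by final-month production", {
  prod <- rbind(a = c(0.9, 0.9), b = c(0.1, 0.2), c = c(0.0, 0.4))
  n <- cdi_norms(prod, months = 16:17)
  tr <- sample_aoa_ordering(n, seed = 3)
  expect_equal(as.character(tr)[1L], "a")
  expect_setequal(as.character(tr)[2:3], c("b", "c"))
  expect_true(all(is.na(attr(tr, "sampling_month")[2:3])))
})

test_that("step norms with distinct crossing months give a deterministic order", {
  words <- sprintf("w%d", 1:6)
  n <- step_norms(words)
  trs <- lapply(1:5, function(s) as.character(sample_aoa_ordering(n, seed = s)))
  for (tr in trs) expect_equal(tr, words)
})

test_that("higher same-month production leads to stochastically earlier draws", {
  prod <- rbind(hi = c(0.9), lo = c(0.6))
  n <- cdi_norms(prod, months = 16L)
  firsts <- vapply(1:2000, function(s)
    as.character(sample_aoa_ordering(n, seed = s))[1L], "")
  p_hi <- mean(firsts == "hi")
  expect_gt(p_hi, 0.5)   # direction; the exact law is checked at acceptance
})

test_that("aoa ensembles are reproducible from the master seed", {
  n <- toy_norms()
  e1 <- sample_aoa_ensemble(n, n = 6, seed = 11)
  e2 <- sample_aoa_ensemble(n, n = 6, seed = 11)
  expect_identical(lapply(e1$trajectories, as.character),
                   lapply(e2$trajectories, as.character))
  e3 <- sample_aoa_ensemble(n, n = 1, seed = 11)
  single <- sample_aoa_ordering(n, seed = split_seed(11, 1), label = "x")
  expect_equal(as.character(e3$trajectories[[1L]]), as.character(single))
})

test_that("rank_by_score orders by descending score", {
  s <- c(food = 62, water = 45, eat = 20)
  tr <- rank_by_score(s)$trajectories[[1L]]
  expect_equal(as.character(tr), c("food", "water", "eat"))
  # permutation-invariance of the input table when there are no ties
  tr2 <- rank_by_score(s[c(2, 3, 1)])$trajectories[[1L]]
  expect_equal(as.character(tr2), as.character(tr))
  expect_error(rank_by_score(c(a = 1, b = NaN)), "finite")
})

test_that("tie blocks are recorded and shuffled fairly across resolutions", {
  s <- c(a = 5, b = 5, c = 1)
  exp_tr <- rank_by_score(s, "expected")$trajectories[[1L]]
  expect_equal(attr(exp_tr, "block_start"), c(1L, 1L, 3L))
  expect_equal(attr(exp_tr, "block_end"), c(2L, 2L, 3L))

  ens <- rank_by_score(s, "resolutions", n_resolutions = 2000, seed = 9)
  firsts <- vapply(ens$trajectories, function(tr) as.character(tr)[1L], "")
  p_a <- mean(firsts == "a")
  sd3 <- 3 * sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(p_a - 0.5), sd3)
  for (tr in ens$trajectories) expect_equal(as.character(tr)[3L], "c")
})

test_that("every emitted trajectory is a permutation of the vocabulary", {
  ds <- small_dataset(N = 40, seed = 5)
  ens <- sample_aoa_ensemble(ds$norms, n = 8, seed = 2)
  for (tr in ens$trajectories)
    expect_setequal(as.character(tr), ds$mln$vocab$word)
  sc <- multiplex_centrality(ds$mln, "multidegree")
  for (tr in rank_by_score(sc, "resolutions", n_resolutions = 5)$trajectories)
    expect_setequal(as.character(tr), ds$mln$vocab$word)
})

test_that("inventory size by month is nondecreasing and threshold-driven", {
  n <- toy_norms()
  inv <- inventory_size_by_month(n)
  expect_equal(unname(inv), c(2L, 2L, 3L))
  expect_true(!is.unsorted(inv))
})

test_that("trajectory ensembles round-trip through CSV", {
  n <- toy_norms()
  ens <- sample_aoa_ensemble(n, n = 3, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(ens, f)
  ens2 <- read_trajectories(f)
  expect_setequal(vapply(ens2$trajectories, function(t) attr(t, "label"), ""),
                  vapply(ens$trajectories, function(t) attr(t, "label"), ""))
  lab <- function(e) vapply(e$trajectories, function(t) attr(t, "label"), "")
  ord2 <- lapply(ens2$trajectories, as.character)[order(lab(ens2))]
  ord1 <- lapply(ens$trajectories, as.character)[order(lab(ens))]
  expect_identical(ord2, ord1)
})
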