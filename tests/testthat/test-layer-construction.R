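words5 <- c("cat", "bat", "dog", "apple", "go")

test_that("association layer symmetrizes and deduplicates records", {
  rec <- data.frame(cue = c("cat", "dog", "cat"), target = c("dog", "cat", "dog"))
  g <- build_association_layer(rec, words5)
  expect_equal(igraph::ecount(g), 1)
  expect_true(igraph::are_adjacent(g, "cat", "dog"))

  # set oracle on random directed records
  set.seed(11)
  rc <- data.frame(cue = sample(words5, 100, TRUE),
                   target = sample(words5, 100, TRUE))
  rc <- rc[rc$cue != rc$target, ]
  g2 <- build_association_layer(rc, words5)
  expect_equal(igraph::ecount(g2),
               length(unique(paste(pmin(rc$cue, rc$target),
                                   pmax(rc$cue, rc$target)))))
  expect_warning(build_association_layer(data.frame(cue = character(),
                                                    target = character()),
                                         words5), "empty")
})

test_that("feature layer links words sharing at least one feature", {
  rec <- data.frame(word = c("dog", "cat", "apple"),
                    feature = c("has_legs", "has_legs", "is_red"))
  g <- build_feature_layer(rec, words5)
  expect_true(igraph::are_adjacent(g, "dog", "cat"))
  expect_false(igraph::are_adjacent(g, "dog", "apple"))
  expect_equal(igraph::degree(g)[["apple"]], 0)

  # bipartite projection oracle on a random word-feature table
  set.seed(3)
  rec2 <- unique(data.frame(word = sample(words5, 40, TRUE),
                            feature = sample(paste0("f", 1:6), 40, TRUE)))
  g2 <- build_feature_layer(rec2, words5)
  feats <- split(rec2$feature, rec2$word)
  for (i in 1:(length(words5) - 1)) for (j in (i + 1):length(words5)) {
    shared <- length(intersect(feats[[words5[i]]], feats[[words5[j]]])) > 0
    expect_equal(igraph::are_adjacent(g2, words5[i], words5[j]), shared)
  }
})

test_that("co-occurrence threshold is strict", {
  rec <- data.frame(word1 = c("cat", "cat"), word2 = c("dog", "go"),
                    count = c(46L, 45L))
  g <- build_cooccurrence_layer(rec, words5, threshold = 45L)
  expect_true(igraph::are_adjacent(g, "cat", "dog"))
  expect_false(igraph::are_adjacent(g, "cat", "go"))
  expect_error(build_cooccurrence_layer(
    data.frame(word1 = "cat", word2 = "dog", count = -1L), words5),
    "negative")

  set.seed(7)
  rc <- data.frame(word1 = "cat", word2 = c("bat", "dog", "apple", "go"),
                   count = sample(0:100, 4))
  g2 <- build_cooccurrence_layer(rc, words5, threshold = 40L)
  expect_equal(igraph::ecount(g2), sum(rc$count > 40L))
})

test_that("adjacent-bigram co-occurrence counter matches a direct tally", {
  utt <- list(c("the", "dog", "runs"), c("dog", "runs"), c("go"))
  tab <- count_cooccurrences(utt)
  expect_equal(tab$count[tab$word1 == "dog" & tab$word2 == "runs"], 2L)
  expect_equal(nrow(tab), 2L)           # pairs: dog-the, dog-runs
  expect_equal(nrow(count_cooccurrences(list(character()))), 0L)
})

test_that("phoneme edit distance equals the dynamic-programming oracle", {
  expect_equal(ipa_edit_distance(c("k", "ae", "t"), c("b", "ae", "t")), 1L)
  expect_equal(ipa_edit_distance(c("k", "ae", "t"), c("k", "ae", "t")), 0L)
  phonemes <- c("p", "b", "t", "d", "k", "g", "ae", "ei", "s", "z")
  set.seed(5)
  for (i in 1:40) {
    s1 <- sample(phonemes, sample(1:6, 1), TRUE)
    s2 <- sample(phonemes, sample(1:6, 1), TRUE)
    expect_equal(ipa_edit_distance(s1, s2), oracle_edit_distance(s1, s2))
  }
})

test_that("phonological layer links neighbourhoods at distance one", {
  lex <- list(cat = c("k", "ae", "t"), bat = c("b", "ae", "t"),
              at = c("ae", "t"), dog = c("d", "o", "g"))
  g <- build_phonological_layer(lex, words5)
  expect_true(igraph::are_adjacent(g, "cat", "bat"))
  expect_equal(igraph::degree(g)[["dog"]], 0)
  expect_equal(igraph::degree(g)[["apple"]], 0)  # no transcription

  # all-pairs oracle on a random lexicon of short forms
  set.seed(13)
  wd <- sprintf("w%02d", 1:50)
  lex2 <- lapply(wd, function(w) sample(c("a", "b", "c"), sample(1:4, 1), TRUE))
  names(lex2) <- wd
  g2 <- build_phonological_layer(lex2, wd)
  for (i in seq(1, 49, by = 7)) for (j in seq(i + 1, 50, by = 11)) {
    expect_equal(igraph::are_adjacent(g2, wd[i], wd[j]),
                 oracle_edit_distance(lex2[[i]], lex2[[j]]) == 1L)
  }
})

test_that("vocabulary intersection keeps connected inventory words and is idempotent", {
  words <- c("a", "b", "c", "d", "e", "f")
  layers <- list(
    l1 = make_layer(rbind(c("a", "b"), c("c", "d")), words, "l1"),
    l2 = make_layer(rbind(c("d", "e")), words, "l2"))
  # f isolated everywhere -> removed even though on the inventory;
  # e connected on one layer only -> kept
  x <- intersect_vocabulary(c("a", "b", "c", "d", "e", "f"), layers)
  expect_setequal(x$vocab$word, c("a", "b", "c", "d", "e"))

  # c's only neighbour d stays, but if the inventory drops d, c must go too
  # (iterated removal)
  y <- intersect_vocabulary(c("a", "b", "c", "e"), layers)
  expect_setequal(y$vocab$word, c("a", "b"))

  # idempotence on random instances
  for (seed in 1:4) {
    lay <- list(l1 = rand_layer(12, 0.1, seed, "l1"),
                l2 = rand_layer(12, 0.1, seed + 50, "l2"))
    cdi <- sprintf("w%02d", 1:9)
    z1 <- intersect_vocabulary(cdi, lay)
    z2 <- intersect_vocabulary(z1$vocab$word, z1$layers)
    expect_equal(z2$vocab$word, z1$vocab$word)
    expect_equal(lapply(z2$layers, igraph::ecount),
                 lapply(z1$layers, igraph::ecount))
  }
  expect_error(intersect_vocabulary("zz", layers), "empty vocabulary")
})

test_that("layer building is order-independent under record shuffling", {
  set.seed(21)
  rec <- data.frame(cue = sample(words5, 60, TRUE),
                    target = sample(words5, 60, TRUE))
  rec <- rec[rec$cue != rec$target, ]
  g1 <- build_association_layer(rec, words5)
  g2 <- build_association_layer(rec[sample(nrow(rec)), ], words5)
  expect_identical(oracle_adj(g1, words5), oracle_adj(g2, words5))
})

test_that("raw-input readers parse the TSV formats", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# cue\ttarget\tstrength", "cat\tdog\t0.5", "dog\tbat\t0.1"), f)
  d <- read_association_tsv(f)
  expect_equal(d$cue, c("cat", "dog"))
  expect_equal(d$strength, c(0.5, 0.1))

  writeLines(c("cat\tk ae t", "bat\tb ae t"), f)
  lex <- read_phon_lexicon_tsv(f)
  expect_equal(lex$cat, c("k", "ae", "t"))

  writeLines(c("# inventory", "cat", "dog", "play dough"), f)
  expect_equal(read_cdi_list(f), c("cat", "dog", "play dough"))
  expect_equal(normalize_word("Play  Dough"), "play_dough")
})
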