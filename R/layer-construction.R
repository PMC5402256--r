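#' Normalize raw word labels into node ids
#'
#' Node identity across layers is by word id string. At ingest, labels are
#' optionally case-folded, whitespace-trimmed, and multiword labels (e.g.
#' "play dough") are joined with an underscore so each inventory item maps to
#' a single node id.
#'
#' @param x character vector of raw labels.
#' @param case_fold lower-case the labels? Default TRUE.
#' @return character vector of normalized ids.
#' @export
normalize_word <- function(x, case_fold = TRUE) {
  x <- trimws(as.character(x))
  if (case_fold) x <- tolower(x)
  gsub("[[:space:]]+", "_", x)
}

drop_unknown <- function(keep, what) {
  n_bad <- sum(!keep)
  if (n_bad > 0L)
    message("dropped ", n_bad, " ", what, " referencing out-of-vocabulary words")
  keep
}

#' Build the free-association layer
#'
#' An undirected edge joins words A and B if at least one directed
#' cue-to-target association record (A to B, or B to A) exists. Association
#' strengths, if present, are ignored; records mentioning out-of-vocabulary
#' words are dropped with a message.
#'
#' @param records data frame with columns `cue` and `target` (word ids);
#'   an optional `strength` column is ignored.
#' @param words character vector of vocabulary word ids.
#' @return undirected simple igraph layer named `"association"`.
#' @export
build_association_layer <- function(records, words) {
  if (NROW(records) == 0L) {
    warning("empty association record set; returning an edgeless layer")
    return(make_layer(NULL, words, "association"))
  }
  cue <- as.character(records$cue); tgt <- as.character(records$target)
  keep <- drop_unknown(cue %in% words & tgt %in% words, "association records")
  cue <- cue[keep]; tgt <- tgt[keep]
  keep2 <- cue != tgt
  make_layer(cbind(cue[keep2], tgt[keep2]), words, "association")
}

#' Build the semantic-feature layer
#'
#' Words A and B are connected if they share at least one semantic feature,
#' i.e. the layer is the one-mode projection of the word-feature bipartite
#' graph with a unit threshold. Words with no features stay isolated.
#'
#' @param records data frame with columns `word` and `feature`.
#' @param words character vector of vocabulary word ids.
#' @return undirected simple igraph layer named `"feature"`.
#' @export
build_feature_layer <- function(records, words) {
  if (NROW(records) == 0L) {
    warning("empty feature record set; returning an edgeless layer")
    return(make_layer(NULL, words, "feature"))
  }
  w <- as.character(records$word); f <- as.character(records$feature)
  stopifnot(all(nzchar(f)))
  keep <- drop_unknown(w %in% words, "feature records")
  w <- w[keep]; f <- f[keep]
  wf <- unique(data.frame(w = w, f = f, stringsAsFactors = FALSE))
  by_feat <- split(wf$w, wf$f)
  pairs <- lapply(by_feat, function(ws) {
    if (length(ws) < 2L) return(NULL)
    t(utils::combn(sort(ws), 2L))
  })
  make_layer(do.call(rbind, pairs), words, "feature")
}

#' Build the co-occurrence layer
#'
#' Words A and B are connected if their co-occurrence count strictly exceeds
#' the threshold (default 45, chosen to approximately match the link density
#' of the semantic layers).
#'
#' @param records data frame with columns `word1`, `word2`, `count`.
#' @param words character vector of vocabulary word ids.
#' @param threshold nonnegative integer; an edge requires `count > threshold`.
#' @return undirected simple igraph layer named `"cooccurrence"`.
#' @export
build_cooccurrence_layer <- function(records, words, threshold = 45L) {
  stopifnot(threshold >= 0)
  if (NROW(records) == 0L) {
    warning("empty co-occurrence record set; returning an edgeless layer")
    return(make_layer(NULL, words, "cooccurrence"))
  }
  if (any(records$count < 0)) stop("negative co-occurrence count")
  a <- as.character(records$word1); b <- as.character(records$word2)
  keep <- drop_unknown(a %in% words & b %in% words, "co-occurrence records")
  sel <- keep & records$count > threshold & a != b
  make_layer(cbind(a[sel], b[sel]), words, "cooccurrence")
}

#' Count word co-occurrences in tokenized utterances
#'
#' A convention helper for deriving pair counts from child-directed speech
#' transcripts: every adjacent bigram within an utterance contributes one
#' co-occurrence of the unordered pair. Counts are an input format, not a
#' claim about how any particular corpus was originally processed.
#'
#' @param utterances list of character vectors (tokens of one utterance each).
#' @return data frame with columns `word1`, `word2`, `count`.
#' @export
count_cooccurrences <- function(utterances) {
  stopifnot(is.list(utterances))
  pairs <- lapply(utterances, function(u) {
    if (length(u) < 2L) return(NULL)
    a <- u[-length(u)]; b <- u[-1L]
    keep <- a != b
    cbind(pmin(a, b), pmax(a, b))[keep, , drop = FALSE]
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(data.frame(word1 = character(), word2 = character(),
                      count = integer()))
  key <- paste(pairs[, 1L], pairs[, 2L], sep = "\r")
  tab <- table(key)
  sp <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(word1 = vapply(sp, `[`, "", 1L),
             word2 = vapply(sp, `[`, "", 2L),
             count = as.integer(tab), row.names = NULL)
}

#' Phoneme-level edit distance
#'
#' Unit-cost Levenshtein distance between two phoneme token sequences
#' (insertions, deletions and substitutions of whole phoneme tokens).
#' Internally each distinct token is mapped to a single Unicode character and
#' the distance computed with [utils::adist()].
#'
#' @param s1,s2 character vectors of phoneme tokens.
#' @return nonnegative integer distance.
#' @export
ipa_edit_distance <- function(s1, s2) {
  stopifnot(length(s1) >= 1L, length(s2) >= 1L)
  alphabet <- unique(c(s1, s2))
  enc <- function(s) intToUtf8(match(s, alphabet) + 256L)
  as.integer(utils::adist(enc(s1), enc(s2)))
}

# encode a list of token sequences as strings over a private character map
encode_ipa <- function(seqs) {
  alphabet <- unique(unlist(seqs, use.names = FALSE))
  vapply(seqs, function(s) intToUtf8(match(s, alphabet) + 256L), character(1))
}

#' Build the phonological-similarity layer
#'
#' Words are connected if their IPA transcriptions are at phoneme edit
#' distance exactly one (each word's phonological neighbourhood). Words
#' without a transcription stay isolated. When a word has several
#' transcriptions, the first is used unless `use_all_pronunciations = TRUE`,
#' in which case a pair is linked if any transcription pair is at distance
#' one.
#'
#' @param lexicon named list mapping word id to a character vector of phoneme
#'   tokens, or to a list of such vectors (alternative pronunciations).
#' @param words character vector of vocabulary word ids.
#' @param use_all_pronunciations link on any pronunciation pair? Default FALSE.
#' @return undirected simple igraph layer named `"phonological"`.
#' @export
build_phonological_layer <- function(lexicon, words,
                                     use_all_pronunciations = FALSE) {
  lexicon <- lexicon[names(lexicon) %in% words]
  uncovered <- setdiff(words, names(lexicon))
  if (length(uncovered))
    message(length(uncovered), " word(s) without transcription left isolated")
  forms <- list(); owner <- character()
  for (w in names(lexicon)) {
    entry <- lexicon[[w]]
    alts <- if (is.list(entry)) entry else list(entry)
    if (!use_all_pronunciations) alts <- alts[1L]
    for (a in alts) {
      stopifnot(length(a) >= 1L)
      forms[[length(forms) + 1L]] <- as.character(a)
      owner <- c(owner, w)
    }
  }
  if (length(forms) < 2L) return(make_layer(NULL, words, "phonological"))
  strs <- encode_ipa(forms)
  len <- nchar(strs)
  edges <- NULL
  # only pairs with length difference <= 1 can be at edit distance 1
  for (i in seq_len(length(strs) - 1L)) {
    cand <- which(abs(len[-seq_len(i)] - len[i]) <= 1L) + i
    cand <- cand[owner[cand] != owner[i]]
    if (!length(cand)) next
    d <- utils::adist(strs[i], strs[cand])[1L, ]
    hit <- cand[d == 1L]
    if (length(hit))
      edges <- rbind(edges, cbind(owner[i], owner[hit]))
  }
  make_layer(edges, words, "phonological")
}

#' Intersect layers with an inventory word list
#'
#' Retains the words that appear on the inventory list AND have at least one
#' connection on at least one layer, then re-induces every layer on the
#' retained set. Because removing words can isolate others, the removal is
#' iterated to a fixed point, so the operation is idempotent.
#'
#' @param cdi_words character vector of inventory (CDI) word ids.
#' @param layers named list of igraph layers built on a superset vocabulary.
#' @param vocabulary optional attribute data frame (see [mln]) for the
#'   superset; it is subset to the retained words.
#' @return an [mln] on the retained vocabulary.
#' @export
intersect_vocabulary <- function(cdi_words, layers, vocabulary = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  keep <- intersect(igraph::V(layers[[1L]])$name, cdi_words)
  repeat {
    sub <- lapply(layers, function(g)
      igraph::induced_subgraph(g, intersect(igraph::V(g)$name, keep)))
    deg <- Reduce(`+`, lapply(sub, igraph::degree))
    keep2 <- names(deg)[deg >= 1]
    if (length(keep2) == 0L)
      stop("empty vocabulary after intersection (started from ",
           length(cdi_words), " inventory words, ",
           igraph::vcount(layers[[1L]]), " network words)")
    if (setequal(keep2, keep)) break
    keep <- keep2
  }
  keep <- sort(keep)
  layers <- lapply(layers, function(g) {
    h <- igraph::induced_subgraph(g, keep)
    igraph::permute(h, match(igraph::V(h)$name, keep))
  })
  vocab <- if (is.null(vocabulary)) NULL else
    vocabulary[vocabulary$word %in% keep, , drop = FALSE]
  mln(layers, vocabulary = vocab)
}

# ---- TSV readers -----------------------------------------------------------

read_tsv_skip <- function(path, col_names) {
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(d)[seq_along(col_names)] <- col_names
  d
}

#' Readers for the raw relational input formats
#'
#' All readers expect UTF-8 tab-separated files without a header; lines
#' starting with `#` are skipped. Columns: association pairs
#' (`cue`, `target`\[, `strength`\]); feature norms (`word`, `feature`);
#' co-occurrence counts (`word1`, `word2`, `count`); phonological lexicon
#' (`word`, space-separated IPA tokens); inventory word list (`word`).
#'
#' @param path file path.
#' @return a data frame (or for `read_phon_lexicon_tsv` a named list of
#'   phoneme token vectors; for `read_cdi_list` a character vector).
#' @name layer_readers
NULL

#' @rdname layer_readers
#' @export
read_association_tsv <- function(path) {
  d <- read_tsv_skip(path, c("cue", "target"))
  if (ncol(d) >= 3L) names(d)[3L] <- "strength"
  d
}

#' @rdname layer_readers
#' @export
read_feature_tsv <- function(path) read_tsv_skip(path, c("word", "feature"))

#' @rdname layer_readers
#' @export
read_cooccurrence_tsv <- function(path) {
  d <- read_tsv_skip(path, c("word1", "word2", "count"))
  d$count <- as.integer(d$count)
  d
}

#' @rdname layer_readers
#' @export
read_phon_lexicon_tsv <- function(path) {
  d <- read_tsv_skip(path, c("word", "ipa"))
  out <- strsplit(as.character(d$ipa), "[[:space:]]+")
  names(out) <- as.character(d$word)
  out[!duplicated(names(out))]
}

#' @rdname layer_readers
#' @export
read_cdi_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines[nzchar(lines) & !startsWith(lines, "#")])
  unique(lines)
}
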