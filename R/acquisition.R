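#' Communicative-development-inventory production norms
#'
#' A `cdi_norms` object stores, for every vocabulary word and every month of
#' a reporting range (by default 16-30 months), the fraction of children
#' reported to produce the word at that month.
#'
#' @param production numeric matrix, words x months, entries in `[0, 1]`;
#'   rownames are word ids.
#' @param months integer vector of months, one per column.
#' @return an object of class `cdi_norms`.
#' @export
cdi_norms <- function(production, months = 16:30) {
  production <- as.matrix(production)
  stopifnot(ncol(production) == length(months),
            !is.null(rownames(production)),
            all(is.finite(production)),
            all(production >= 0 & production <= 1),
            !is.unsorted(months))
  colnames(production) <- as.character(months)
  structure(list(production = production, months = as.integer(months)),
            class = "cdi_norms")
}

#' @export
print.cdi_norms <- function(x, ...) {
  cat(sprintf("CDI norms: %d words, months %d-%d\n",
              nrow(x$production), min(x$months), max(x$months)))
  invisible(x)
}

#' Read and write CDI norms as CSV
#'
#' Long format with columns `word`, `month`, `fraction`.
#'
#' @param norms a [cdi_norms] object.
#' @param path file path.
#' @return `read_cdi_norms` returns a [cdi_norms]; `write_cdi_norms` returns
#'   `path` invisibly.
#' @export
write_cdi_norms <- function(norms, path) {
  long <- data.frame(
    word = rep(rownames(norms$production), times = length(norms$months)),
    month = rep(norms$months, each = nrow(norms$production)),
    fraction = as.vector(norms$production))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cdi_norms
#' @export
read_cdi_norms <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  months <- sort(unique(long$month))
  words <- unique(long$word)
  prod <- matrix(NA_real_, length(words), length(months),
                 dimnames = list(words, months))
  prod[cbind(match(long$word, words), match(long$month, months))] <- long$fraction
  if (anyNA(prod)) stop("norms do not cover every word x month cell")
  cdi_norms(prod, months)
}

new_trajectory <- function(order, label) {
  structure(as.character(order), label = label, class = "trajectory")
}

trajectory_ensemble <- function(trajectories, seeds = NULL) {
  words <- sort(unclass(trajectories[[1L]]))
  for (tr in trajectories)
    stopifnot(identical(sort(unclass(tr)), words))
  structure(list(trajectories = trajectories, seeds = seeds),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d trajectories over %d words\n",
              length(x$trajectories), length(x$trajectories[[1L]])))
  invisible(x)
}

#' Sample one normative acquisition ordering from CDI norms
#'
#' A word counts as known once at least `threshold` (default 50%) of
#' children produce it in a month; it stays eligible afterwards even if its
#' curve later dips. Months are visited in order; within a month, the
#' not-yet-sampled eligible words are drawn sequentially without replacement
#' with probability proportional to that month's production fraction, each
#' draw filling the next trajectory position. After the final month any
#' remaining (never-eligible) words are drawn the same way using final-month
#' production, with zero fractions floored at 1e-6, so the result is always
#' a full permutation of the vocabulary.
#'
#' @param norms a [cdi_norms] object covering the vocabulary.
#' @param threshold production fraction at which a word counts as known.
#' @param seed integer seed.
#' @param label label stored on the trajectory.
#' @return a `trajectory` (character vector of word ids in learning order)
#'   with attribute `sampling_month` giving the month index at which each
#'   position was drawn (NA for the post-range residual phase).
#' @export
sample_aoa_ordering <- function(norms, threshold = 0.5, seed = 1L,
                                label = "aoa_sample") {
  stopifnot(inherits(norms, "cdi_norms"), threshold > 0, threshold < 1)
  prod <- norms$production
  words <- rownames(prod)
  # first month at which each word's production reaches the threshold
  crossed <- prod >= threshold
  first_month <- apply(crossed, 1L, function(z) if (any(z)) which(z)[1L] else NA_integer_)
  out <- character(0); out_month <- integer(0)
  remaining <- words
  with_seed(seed, {
    for (mi in seq_along(norms$months)) {
      pool <- remaining[!is.na(first_month[remaining]) &
                          first_month[remaining] <= mi]
      if (length(pool) == 0L) next
      w <- pmax(prod[pool, mi], 1e-6)
      drawn <- if (length(pool) == 1L) pool else sample(pool, length(pool), prob = w)
      out <- c(out, drawn)
      out_month <- c(out_month, rep(mi, length(drawn)))
      remaining <- setdiff(remaining, drawn)
    }
    if (length(remaining) > 0L) {
      w <- pmax(prod[remaining, ncol(prod)], 1e-6)
      drawn <- if (length(remaining) == 1L) remaining else
        sample(remaining, length(remaining), prob = w)
      out <- c(out, drawn)
      out_month <- c(out_month, rep(NA_integer_, length(drawn)))
    }
  })
  stopifnot(setequal(out, words), length(out) == length(words))
  tr <- new_trajectory(out, label)
  attr(tr, "sampling_month") <- out_month
  tr
}

#' Sample an ensemble of normative acquisition orderings
#'
#' Draws `n` independent orderings via [sample_aoa_ordering()], with
#' per-sample seeds derived from the master seed by [split_seed()], so the
#' whole ensemble is reproducible from one integer.
#'
#' @inheritParams sample_aoa_ordering
#' @param n ensemble size (default 30).
#' @return a `trajectory_ensemble`.
#' @export
sample_aoa_ensemble <- function(norms, n = 30L, threshold = 0.5, seed = 1L) {
  stopifnot(n >= 1L)
  seeds <- split_seed(seed, n)
  trs <- lapply(seq_len(n), function(i)
    sample_aoa_ordering(norms, threshold = threshold, seed = seeds[i],
                        label = paste0("aoa_sample_", i)))
  trajectory_ensemble(trs, seeds = seeds)
}

#' Predicted acquisition trajectories from word scores
#'
#' Orders words by descending score (largest score learned first). Ties are
#' handled by one of two policies. `"expected"` (default) emits one canonical
#' trajectory carrying tie-block metadata (`block_start`, `block_end`
#' positions per word) that lets the evaluator compute the exact expected
#' overlap contribution of tied blocks — equivalent in expectation to
#' averaging over all tie resolutions. `"resolutions"` emits `n_resolutions`
#' trajectories with each tied block independently shuffled, for Monte Carlo
#' averaging.
#'
#' @param scores named numeric vector (or `word_scores`) covering the
#'   vocabulary; all values must be finite.
#' @param tie_policy `"expected"` or `"resolutions"`.
#' @param n_resolutions number of tie resolutions when
#'   `tie_policy = "resolutions"`.
#' @param seed integer seed for tie shuffling.
#' @param label label prefix for the trajectories.
#' @return a `trajectory_ensemble`; under the expected policy it holds one
#'   trajectory with attributes `block_start` and `block_end` (integer
#'   vectors aligned with trajectory positions).
#' @export
rank_by_score <- function(scores, tie_policy = c("expected", "resolutions"),
                          n_resolutions = 100L, seed = 1L, label = NULL) {
  tie_policy <- match.arg(tie_policy)
  if (is.null(label))
    label <- if (!is.null(attr(scores, "metric")))
      paste(attr(scores, "scope"), attr(scores, "metric"), sep = "_") else "score"
  s <- unclass(scores)
  if (is.null(names(s)) || !all(is.finite(s))) stop("scores must be finite and named")
  words <- names(s)
  ord <- order(-s, words)                 # deterministic canonical order
  canon <- words[ord]
  sv <- s[ord]
  # tie blocks as runs of equal score in the canonical order
  block_id <- cumsum(c(1L, diff(sv) != 0))
  block_start <- stats::ave(seq_along(canon), block_id, FUN = min)
  block_end <- stats::ave(seq_along(canon), block_id, FUN = max)
  if (tie_policy == "expected") {
    tr <- new_trajectory(canon, label)
    attr(tr, "block_start") <- as.integer(block_start)
    attr(tr, "block_end") <- as.integer(block_end)
    return(trajectory_ensemble(list(tr)))
  }
  seeds <- split_seed(seed, n_resolutions)
  trs <- lapply(seq_len(n_resolutions), function(i) {
    with_seed(seeds[i], {
      perm <- canon
      for (b in unique(block_id)) {
        idx <- which(block_id == b)
        if (length(idx) > 1L) perm[idx] <- sample(perm[idx])
      }
      new_trajectory(perm, paste0(label, "_res", i))
    })
  })
  trajectory_ensemble(trs, seeds = seeds)
}

#' Inventory size per month implied by CDI norms
#'
#' The inventory size at month m is the number of words whose production
#' fraction has reached the threshold at some month <= m. This provides the
#' month-to-inventory-size mapping used to convert learning-stage month
#' windows into trajectory-position windows.
#'
#' @inheritParams sample_aoa_ordering
#' @return named integer vector, one entry per month.
#' @export
inventory_size_by_month <- function(norms, threshold = 0.5) {
  crossed <- norms$production >= threshold
  cum <- apply(crossed, 1L, cummax)       # months x words
  stats::setNames(as.integer(rowSums(cum)), norms$months)
}

#' Read and write trajectory ensembles as CSV
#'
#' Long format with columns `label`, `position`, `word`.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param path file path.
#' @return `read_trajectories` returns a `trajectory_ensemble`;
#'   `write_trajectories` returns `path` invisibly.
#' @export
write_trajectories <- function(ensemble, path) {
  rows <- lapply(ensemble$trajectories, function(tr)
    data.frame(label = attr(tr, "label"), position = seq_along(tr),
               word = as.character(tr)))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  trs <- lapply(split(d, d$label), function(g)
    new_trajectory(g$word[order(g$position)], g$label[1L]))
  trajectory_ensemble(unname(trs))
}
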