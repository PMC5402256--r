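# independent brute-force oracles, deliberately naive implementations

# adjacency matrix from an igraph layer, in vertex-name order
oracle_adj <- function(g, words = igraph::V(g)$name) {
  n <- length(words)
  a <- matrix(0L, n, n, dimnames = list(words, words))
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    a[el] <- 1L
    a[el[, 2:1, drop = FALSE]] <- 1L
  }
  a
}

# all-pairs shortest-path matrix by repeated breadth-first search
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s; lev <- 0L
    while (length(frontier)) {
      lev <- lev + 1L
      nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 &
                     !is.finite(d[s, ]))
      d[s, nxt] <- lev
      frontier <- nxt
    }
  }
  d
}

# mean local clustering: triangles over wedges per node, degree < 2 -> 0
oracle_clustering <- function(a) {
  n <- nrow(a)
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1L)
    k <- length(nb)
    if (k < 2L) return(0)
    sum(a[nb, nb]) / (k * (k - 1))
  }, 0)
  mean(vals)
}

# degree assortativity: Pearson correlation over directed edge stubs
oracle_assortativity <- function(a) {
  deg <- rowSums(a)
  el <- which(a == 1L, arr.ind = TRUE)   # both directions
  suppressWarnings(stats::cor(deg[el[, 1L]], deg[el[, 2L]]))
}

# Kendall tau-b by exhaustive pair enumeration
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Levenshtein distance over token sequences by full DP table
oracle_edit_distance <- function(s1, s2) {
  n1 <- length(s1); n2 <- length(s2)
  d <- matrix(0L, n1 + 1L, n2 + 1L)
  d[, 1L] <- 0:n1; d[1L, ] <- 0:n2
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    cost <- if (s1[i] == s2[j]) 0L else 1L
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + cost)
  }
  d[n1 + 1L, n2 + 1L]
}

# shortest-path betweenness by explicit path counting (Floyd-Warshall style)
oracle_betweenness <- function(a, normalized = TRUE) {
  n <- nrow(a)
  d <- oracle_distances(a)
  sigma <- matrix(0, n, n)               # number of shortest paths s -> t
  sigma[a == 1L] <- 1
  diag(sigma) <- 1
  for (len in 2:max(1, max(d[is.finite(d)]))) {
    idx <- which(d == len, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      s <- idx[r, 1L]; t <- idx[r, 2L]
      pred <- which(a[, t] == 1L & d[s, ] == len - 1L)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v) next
      if (!is.finite(d[s, t])) next
      if (d[s, v] + d[v, t] == d[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    bc[v] <- tot / 2                     # undirected: each pair counted twice
  }
  if (normalized && n > 2L) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}

# PageRank by dense power iteration with uniform teleport
oracle_pagerank <- function(a, damping = 0.85, tol = 1e-12, weights = NULL) {
  n <- nrow(a)
  w <- if (is.null(weights)) a else weights
  out <- rowSums(w)
  p <- rep(1 / n, n)
  repeat {
    contrib <- vapply(seq_len(n), function(j) {
      if (out[j] == 0) 0 else p[j] / out[j]
    }, 0)
    pn <- (1 - damping) / n + damping * (as.vector(t(w) %*% contrib) +
                                           sum(p[out == 0]) / n)
    if (max(abs(pn - p)) < tol) break
    p <- pn
  }
  pn / sum(pn)
}

# expected overlap curve by Monte Carlo over random permutations
oracle_random_overlap <- function(N, n_samples, seed, ref = seq_len(N)) {
  withr::with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      tau <- sample.int(N)
      vapply(seq_len(N), function(t)
        length(intersect(tau[seq_len(t)], ref[seq_len(t)])), 0L)
    }, integer(N))
  })
}
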