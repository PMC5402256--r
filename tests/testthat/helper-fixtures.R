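# small builders used across the suite

rand_layer <- function(n, p = 0.15, seed = 1, name = "layer",
                       words = sprintf("w%02d", seq_len(n))) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- words
  g$name <- name
  g
}

rand_mln <- function(n = 20, L = 3, p = 0.15, seed = 1) {
  words <- sprintf("w%02d", seq_len(n))
  layers <- lapply(seq_len(L), function(l)
    rand_layer(n, p, seed = seed + l, name = paste0("layer", l), words = words))
  names(layers) <- paste0("layer", l <- seq_len(L))
  mln(layers)
}

path_layer <- function(words, name = "path") {
  edges <- cbind(words[-length(words)], words[-1L])
  make_layer(edges, words, name)
}

# norms where word i crosses the threshold exactly at month months[i],
# production 1 from the crossing month onwards and 0 before
step_norms <- function(words, months = seq(16, length.out = length(words))) {
  all_months <- seq(min(months), max(months))
  prod <- t(vapply(months, function(m) as.numeric(all_months >= m),
                   numeric(length(all_months))))
  rownames(prod) <- words
  cdi_norms(prod, all_months)
}

# tiny 4-layer synthetic dataset for end-to-end tests
small_dataset <- function(N = 60, seed = 42, aoa_noise_sd = 0, ...) {
  generate_dataset(synthetic_spec(N = N, aoa_noise_sd = aoa_noise_sd,
                                  seed = seed, ...))
}
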