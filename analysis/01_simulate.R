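#!/usr/bin/env Rscript

# Stage 1 — simulate the study dataset.
#
# Generates a four-layer multiplex lexical network at the empirical scale
# (N = 529 words; heavy-tailed association/co-occurrence degrees,
# exponential-like feature/phonological degrees; coupled degrees and
# overlapping edges across the semantic layers), word attributes, and
# CDI-like production norms over months 16-30 driven by a planted convex
# combination of layer degree scores (association-dominant, negligible
# phonology). Writes the dataset under results/01_simulate/.

suppressPackageStartupMessages(library(lexiplex))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1L]) else 20L

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(N = 529L, seed = seed)
ds <- generate_dataset(spec)

write_mln_edges(ds$mln, file.path(out, "mln.edges"))
write_vocabulary(ds$attributes, file.path(out, "attributes.csv"))
write_cdi_norms(ds$norms, file.path(out, "cdi.csv"))
jsonlite::write_json(
  list(seed = seed, N = spec$N,
       planted_weights = as.list(ds$ground_truth$planted_weights),
       planted_metric = spec$planted_metric,
       aoa_noise_sd = spec$aoa_noise_sd),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

print(ds$mln)
cat(sprintf("multiplex connected: %s\n", is_connected_multiplex(ds$mln)))
cat(sprintf("wrote %s\n", out))
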