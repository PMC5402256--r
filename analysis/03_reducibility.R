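#!/usr/bin/env Rscript

# Stage 3 — structural reducibility.
#
# Maps every layer to its Laplacian density matrix, computes pairwise
# Jensen-Shannon divergences, builds the Ward dendrogram on the sqrt-JSD
# distance and scans every cut with the relative-entropy quality function.
# Reads results/01_simulate/, writes results/03_reducibility/.

suppressPackageStartupMessages(library(lexiplex))

x <- read_mln_edges("results/01_simulate/mln.edges")
out <- "results/03_reducibility"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

res <- reducibility_analysis(x)
utils::write.csv(res$jsd, file.path(out, "jsd.csv"))
write_reducibility_newick(res, file.path(out, "dendrogram.nwk"))
jsonlite::write_json(list(quality = res$quality, best_cut = res$best_cut,
                          irreducible = res$irreducible,
                          merge_sequence = res$merge_sequence),
                     file.path(out, "reducibility.json"),
                     auto_unbox = TRUE, digits = NA)

print(res)
cat(sprintf("wrote %s\n", out))
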