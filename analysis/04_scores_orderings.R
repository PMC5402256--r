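#!/usr/bin/env Rscript

# Stage 4 — word scores and normative acquisition orderings.
#
# Computes the candidate word scores compared throughout the study
# (per-layer degree, multiplex closeness/PageRank/multidegree, word
# frequency, negative word length) and samples the ensemble of 30 normative
# acquisition orderings from the production norms. Reads
# results/01_simulate/, writes results/04_scores/.

suppressPackageStartupMessages(library(lexiplex))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1L]) else 22L

x <- read_mln_edges("results/01_simulate/mln.edges",
                    vocabulary = read_vocabulary(
                      "results/01_simulate/attributes.csv"))
norms <- read_cdi_norms("results/01_simulate/cdi.csv")
out <- "results/04_scores"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scores <- list()
for (nm in names(x$layers))
  scores[[paste0("deg_", nm)]] <- layer_centrality(x$layers[[nm]], "degree")
scores$clos_multiplex <- multiplex_centrality(x, "closeness")
scores$pager_multiplex <- multiplex_centrality(x, "pagerank")
scores$multidegree <- multiplex_centrality(x, "multidegree")
scores$freq_child <- attribute_score(x$vocab, "frequency")
scores$short_len <- attribute_score(x$vocab, "neg_length")

tab <- do.call(rbind, lapply(names(scores), function(nm)
  data.frame(word = names(scores[[nm]]), metric = nm,
             score = as.numeric(scores[[nm]]))))
utils::write.csv(tab, file.path(out, "scores.csv"), row.names = FALSE)

aoa <- sample_aoa_ensemble(norms, n = 30L, seed = seed)
write_trajectories(aoa, file.path(out, "aoa_orderings.csv"))

inv <- inventory_size_by_month(norms)
utils::write.csv(data.frame(month = names(inv), inventory = as.integer(inv)),
                 file.path(out, "inventory_by_month.csv"), row.names = FALSE)

cat(sprintf("scored %d orderings over %d words; 30 normative samples\n",
            length(scores), nrow(x$vocab)))
cat("inventory size by month:\n"); print(inv)
cat(sprintf("wrote %s\n", out))
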