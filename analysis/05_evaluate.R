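#!/usr/bin/env Rscript

# Stage 5 — gain curves and learning-stage comparison.
#
# Evaluates every candidate ordering against the normative ensemble:
# mean overlap, word gain, vocabulary-normalized gain and Z-score per
# inventory size, with Gaussian p-values after 60 acquired words and
# direct-sampling p-values before, then ranks the orderings within the
# VELS/ELS/LLS learning-stage windows. Reads results/01_simulate/ and
# results/04_scores/, writes results/05_evaluate/.

suppressPackageStartupMessages(library(lexiplex))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1L]) else 23L

x <- read_mln_edges("results/01_simulate/mln.edges",
                    vocabulary = read_vocabulary(
                      "results/01_simulate/attributes.csv"))
norms <- read_cdi_norms("results/01_simulate/cdi.csv")
sc <- utils::read.csv("results/04_scores/scores.csv")
aoa <- read_trajectories("results/04_scores/aoa_orderings.csv")
out <- "results/05_evaluate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

n <- nrow(x$vocab)
base <- random_baseline(n)
curves <- lapply(split(sc, sc$metric), function(g) {
  pred <- rank_by_score(stats::setNames(g$score, g$word), label = g$metric[1L])
  significance(gain_curve(pred, aoa, base, label = g$metric[1L]), base,
               ref_ensemble = aoa, gaussian_min_t = 60L, alpha = 0.025,
               n_direct = 10000L, seed = seed)
})
write_gain_curves(curves, file.path(out, "gain_curves.csv"))

m2t <- inventory_size_by_month(norms)
rep <- stage_report(curves, stage_windows(), m2t)
utils::write.csv(rep, file.path(out, "stage_report.csv"), row.names = FALSE)

cat("stage winners (mean normalized gain):\n")
print(rep[rep$rank <= 2, ], digits = 3, row.names = FALSE)
sig <- vapply(curves, function(cu) mean(cu$zscore > critical_z(),
                                        na.rm = TRUE), 0)
cat("\nshare of inventory sizes with Z above 1.96, by ordering:\n")
print(round(sort(sig, decreasing = TRUE), 2))
cat(sprintf("wrote %s\n", out))
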