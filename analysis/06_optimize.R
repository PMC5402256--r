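#!/usr/bin/env Rscript

# Stage 6 — layer-influence optimization with hold-out robustness.
#
# For degree and closeness scores, optimizes the convex layer weights that
# maximize the mean vocabulary-normalized word gain over each learning
# stage's window by differential evolution, averaging over 50 random 20%
# word removals, and contrasts the achieved gains with a degree-preserving
# randomized-multiplex control. Reads earlier stages, writes
# results/06_optimize/.

suppressPackageStartupMessages(library(lexiplex))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1L]) else 24L
n_configs <- if (length(i <- which(args == "--configs")))
  as.integer(args[i + 1L]) else 50L

x <- read_mln_edges("results/01_simulate/mln.edges")
norms <- read_cdi_norms("results/01_simulate/cdi.csv")
aoa <- read_trajectories("results/04_scores/aoa_orderings.csv")
out <- "results/06_optimize"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

m2t <- inventory_size_by_month(norms)
windows <- stage_windows()
n <- nrow(x$vocab)
stage_ts <- lapply(windows, lexiplex:::stage_t_range, month_to_t = m2t, N = n)

seeds <- split_seed(seed, 4L)
res_all <- list()
for (metric in c("degree", "closeness")) {
  for (st in names(stage_ts)) {
    oc <- optimization_config(metric = metric, window = stage_ts[[st]],
                              n_holdout_configs = n_configs,
                              seed = seeds[if (metric == "degree") 1L else 2L])
    fit <- suppressWarnings(optimize_weights(x, aoa, oc))
    res_all[[paste(metric, st, sep = "_")]] <- list(
      metric = metric, stage = st, window = stage_ts[[st]],
      mean_weights = as.list(fit$mean_weights),
      sd_weights = as.list(fit$sd_weights),
      mean_window_gain = fit$mean_window_gain)
    cat(sprintf("%-9s %-4s window %3d-%3d  gain %.3f  weights: %s\n",
                metric, st, stage_ts[[st]][1L], stage_ts[[st]][2L],
                fit$mean_window_gain,
                paste(sprintf("%s=%.3f", names(fit$mean_weights),
                              fit$mean_weights), collapse = " ")))
  }
}

# randomized-multiplex control over the ELS window; closeness is used
# because degree scores are invariant under degree-preserving rewiring
oc_ctrl <- optimization_config(metric = "closeness", window = stage_ts$ELS,
                               n_holdout_configs = min(n_configs, 10L),
                               seed = seeds[3L])
emp <- suppressWarnings(optimize_weights(x, aoa, oc_ctrl))
ctrl <- suppressWarnings(randomized_multiplex_control(x, aoa, oc_ctrl,
                                                      seed = seeds[4L]))
res_all$control <- list(
  empirical_gain = emp$mean_window_gain,
  control_gain = ctrl$control$mean_window_gain)
cat(sprintf("\nELS closeness optimization: empirical gain %.3f vs randomized control %.3f\n",
            emp$mean_window_gain, ctrl$control$mean_window_gain))
cat("note: the default synthetic mechanism is degree-planted, and the control\n",
    "preserves degree sequences, so near-equality is expected here; the\n",
    "control shows a drop when acquisition depends on topology beyond\n",
    "degrees (e.g. a closeness-planted mechanism).\n", sep = "")

jsonlite::write_json(res_all, file.path(out, "optimization.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("wrote %s\n", out))
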