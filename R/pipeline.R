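#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: either a synthetic-data
#' spec or paths to the raw relational input files, the fixed analysis
#' constants (co-occurrence count threshold 45, production threshold 0.5,
#' Gaussian Z threshold at the one-sided 2.5% level), ensemble sizes (100
#' null samples, 30 normative orderings, 50 hold-out configurations), the
#' learning-stage windows, and one master seed from which every stage
#' derives its own.
#'
#' @param out_dir output directory.
#' @param seed integer master seed.
#' @param synthetic a [synthetic_spec()] (synthetic mode), or NULL.
#' @param inputs real-data mode: named list of paths (`assoc`, `feat`,
#'   `cooc`, `phon`, `cdi_norms`), or NULL.
#' @param cooc_threshold co-occurrence count threshold (default 45).
#' @param cdi_threshold production fraction for "known" (default 0.5).
#' @param n_null_samples configuration-model ensemble size (default 100).
#' @param n_aoa normative orderings sampled (default 30).
#' @param n_holdout_configs hold-out configurations (default 50).
#' @param holdout_fraction words removed per configuration (default 0.2).
#' @param gaussian_min_t first t using the Gaussian p-value (default 60).
#' @param alpha one-sided significance level (default 0.025).
#' @param n_direct direct-sampling draws for small t (default 10000).
#' @param windows learning-stage windows ([stage_windows()]).
#' @param opt_metrics per-layer metrics to optimize (default degree and
#'   closeness, the two best-performing orderings).
#' @param opt_window inventory-size window for the optimization objective;
#'   NULL uses the ELS window derived from the norms.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, synthetic = synthetic_spec(),
                            inputs = NULL, cooc_threshold = 45L,
                            cdi_threshold = 0.5, n_null_samples = 100L,
                            n_aoa = 30L, n_holdout_configs = 50L,
                            holdout_fraction = 0.2, gaussian_min_t = 60L,
                            alpha = 0.025, n_direct = 10000L,
                            windows = stage_windows(),
                            opt_metrics = c("degree", "closeness"),
                            opt_window = NULL) {
  if (is.null(synthetic) && is.null(inputs))
    stop("either a synthetic spec or real input paths are required")
  if (!is.null(inputs)) {
    absent <- inputs[!vapply(inputs, file.exists, TRUE)]
    if (length(absent))
      stop("missing input file(s): ", paste(unlist(absent), collapse = ", "))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, inputs = inputs,
                 cooc_threshold = cooc_threshold,
                 cdi_threshold = cdi_threshold,
                 n_null_samples = as.integer(n_null_samples),
                 n_aoa = as.integer(n_aoa),
                 n_holdout_configs = as.integer(n_holdout_configs),
                 holdout_fraction = holdout_fraction,
                 gaussian_min_t = as.integer(gaussian_min_t),
                 alpha = alpha, n_direct = as.integer(n_direct),
                 windows = windows, opt_metrics = opt_metrics,
                 opt_window = opt_window),
            class = "pipeline_config")
}

stage_msg <- function(manifest, name, t0, outputs) {
  manifest$stages[[name]] <- list(
    seconds = round(as.numeric(Sys.time()) - t0, 2),
    outputs = unname(outputs))
  message(sprintf("[%s] done in %.1fs", name,
                  manifest$stages[[name]]$seconds))
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes the six analysis stages in order — build/simulate the multiplex
#' and norms, layer topology statistics against configuration-model nulls,
#' structural reducibility, word scoring, normative-ordering sampling,
#' gain-curve evaluation and layer-influence optimization — writing each
#' stage's tables under `out_dir` and a `manifest.json` (package version,
#' seeds, per-stage outputs and timings) that allows exact re-runs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly; all artefacts are files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  seeds <- split_seed(config$seed, 6L)
  manifest <- list(package_version = as.character(utils::packageVersion("lexiplex")),
                   master_seed = config$seed, stage_seeds = seeds,
                   mode = if (is.null(config$inputs)) "synthetic" else "real",
                   stages = list())

  # stage 1: build or simulate
  t0 <- as.numeric(Sys.time())
  if (is.null(config$inputs)) {
    ds <- generate_dataset(config$synthetic, seed = seeds[1L])
    x <- ds$mln; norms <- ds$norms
    write_vocabulary(ds$attributes, out("attributes.csv"))
    jsonlite::write_json(
      list(planted_weights = as.list(ds$ground_truth$planted_weights)),
      out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    norms0 <- read_cdi_norms(config$inputs$cdi_norms)
    cdi_words <- normalize_word(rownames(norms0$production))
    assoc <- read_association_tsv(config$inputs$assoc)
    feat <- read_feature_tsv(config$inputs$feat)
    cooc <- read_cooccurrence_tsv(config$inputs$cooc)
    phon <- read_phon_lexicon_tsv(config$inputs$phon)
    words0 <- unique(c(cdi_words, normalize_word(c(assoc$cue, assoc$target)),
                       normalize_word(feat$word),
                       normalize_word(c(cooc$word1, cooc$word2))))
    layers <- list(
      association = build_association_layer(
        data.frame(cue = normalize_word(assoc$cue),
                   target = normalize_word(assoc$target)), words0),
      feature = build_feature_layer(
        data.frame(word = normalize_word(feat$word), feature = feat$feature),
        words0),
      cooccurrence = build_cooccurrence_layer(
        data.frame(word1 = normalize_word(cooc$word1),
                   word2 = normalize_word(cooc$word2), count = cooc$count),
        words0, threshold = config$cooc_threshold),
      phonological = build_phonological_layer(
        stats::setNames(phon, normalize_word(names(phon))), words0))
    x <- intersect_vocabulary(cdi_words, layers)
    keep <- match(x$vocab$word, cdi_words)
    norms <- cdi_norms(norms0$production[keep, , drop = FALSE], norms0$months)
  }
  write_mln_edges(x, out("mln.edges"))
  write_cdi_norms(norms, out("cdi.csv"))
  manifest <- stage_msg(manifest, "build", t0,
                        c("mln.edges", "cdi.csv"))

  # stage 2: topology vs configuration models
  t0 <- as.numeric(Sys.time())
  null_seeds <- split_seed(seeds[2L], length(x$layers))
  nulls <- lapply(seq_along(x$layers), function(i)
    configuration_model_ensemble(x$layers[[i]],
                                 n_samples = config$n_null_samples,
                                 seed = null_seeds[i]))
  names(nulls) <- names(x$layers)
  stats_tab <- do.call(rbind, c(lapply(x$layers, layer_summary),
                                list(aggregate = layer_summary(
                                  aggregate_graph(x)))))
  stats_tab <- cbind(network = rownames(stats_tab), stats_tab)
  cm_tab <- do.call(rbind, lapply(nulls, function(ne)
    as.data.frame(as.list(ne$stat_means))))
  cm_tab <- cbind(network = rownames(cm_tab), cm_tab)
  utils::write.csv(stats_tab, out("layer_stats.csv"), row.names = FALSE)
  utils::write.csv(cm_tab, out("layer_stats_cm.csv"), row.names = FALSE)
  kt <- cross_layer_degree_correlation(x)
  utils::write.csv(kt$tau, out("degree_correlation_tau.csv"))
  ov <- edge_overlap(x, nulls)
  utils::write.csv(ov$observed, out("edge_overlap.csv"))
  utils::write.csv(ov$zscore, out("edge_overlap_zscore.csv"))
  manifest <- stage_msg(manifest, "stats", t0,
                        c("layer_stats.csv", "layer_stats_cm.csv",
                          "degree_correlation_tau.csv", "edge_overlap.csv",
                          "edge_overlap_zscore.csv"))

  # stage 3: structural reducibility
  t0 <- as.numeric(Sys.time())
  red <- reducibility_analysis(x)
  write_reducibility_newick(red, out("reducibility.nwk"))
  jsonlite::write_json(list(quality = red$quality, best_cut = red$best_cut,
                            irreducible = red$irreducible),
                       out("reducibility.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- stage_msg(manifest, "reduce", t0,
                        c("reducibility.nwk", "reducibility.json"))

  # stage 4: word scores
  t0 <- as.numeric(Sys.time())
  score_list <- list()
  for (nm in names(x$layers))
    score_list[[paste0("deg_", nm)]] <- layer_centrality(x$layers[[nm]], "degree")
  score_list$clos_multiplex <- multiplex_centrality(x, "closeness")
  score_list$pager_multiplex <- multiplex_centrality(x, "pagerank")
  score_list$multidegree <- multiplex_centrality(x, "multidegree")
  if (!is.null(x$vocab$frequency)) {
    score_list$freq_child <- attribute_score(x$vocab, "frequency")
    score_list$short_len <- attribute_score(x$vocab, "neg_length")
  }
  sc_tab <- do.call(rbind, lapply(names(score_list), function(nm)
    data.frame(word = names(score_list[[nm]]), metric = nm,
               score = as.numeric(score_list[[nm]]))))
  utils::write.csv(sc_tab, out("scores.csv"), row.names = FALSE)
  manifest <- stage_msg(manifest, "score", t0, "scores.csv")

  # stage 5: normative acquisition orderings
  t0 <- as.numeric(Sys.time())
  aoa <- sample_aoa_ensemble(norms, n = config$n_aoa,
                             threshold = config$cdi_threshold,
                             seed = seeds[3L])
  write_trajectories(aoa, out("aoa_orderings.csv"))
  manifest <- stage_msg(manifest, "sample-aoa", t0, "aoa_orderings.csv")

  # stage 6: gain-curve evaluation
  t0 <- as.numeric(Sys.time())
  n <- nrow(x$vocab)
  base <- random_baseline(n)
  curves <- lapply(names(score_list), function(nm) {
    pred <- rank_by_score(score_list[[nm]], tie_policy = "expected",
                          label = nm)
    significance(gain_curve(pred, aoa, base, label = nm), base,
                 ref_ensemble = aoa,
                 gaussian_min_t = config$gaussian_min_t,
                 alpha = config$alpha, n_direct = config$n_direct,
                 seed = seeds[4L])
  })
  write_gain_curves(curves, out("gain_curves.csv"))
  m2t <- inventory_size_by_month(norms, config$cdi_threshold)
  stages_tab <- stage_report(curves, config$windows, m2t)
  utils::write.csv(stages_tab, out("stage_report.csv"), row.names = FALSE)
  manifest <- stage_msg(manifest, "evaluate", t0,
                        c("gain_curves.csv", "stage_report.csv"))

  # stage 7: layer-influence optimization + randomized control
  t0 <- as.numeric(Sys.time())
  opt_window <- config$opt_window
  if (is.null(opt_window))
    opt_window <- stage_t_range(config$windows$ELS, m2t, n)
  opt_seeds <- split_seed(seeds[5L], 2L * length(config$opt_metrics))
  opt_out <- list()
  for (i in seq_along(config$opt_metrics)) {
    met <- config$opt_metrics[i]
    oc <- optimization_config(metric = met, window = opt_window,
                              holdout_fraction = config$holdout_fraction,
                              n_holdout_configs = config$n_holdout_configs,
                              seed = opt_seeds[2L * i - 1L])
    res <- optimize_weights(x, aoa, oc)
    ctrl <- randomized_multiplex_control(x, aoa, oc, seed = opt_seeds[2L * i])
    opt_out[[met]] <- list(
      mean_weights = as.list(res$mean_weights),
      sd_weights = as.list(res$sd_weights),
      mean_window_gain = res$mean_window_gain,
      control_mean_weights = as.list(ctrl$control$mean_weights),
      control_mean_window_gain = ctrl$control$mean_window_gain,
      window = opt_window, converged = all(res$converged))
  }
  jsonlite::write_json(opt_out, out("optimization.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- stage_msg(manifest, "optimize", t0, "optimization.json")

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
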