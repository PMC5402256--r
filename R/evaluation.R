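traj_positions <- function(tr) {
  stats::setNames(seq_along(tr), as.character(tr))
}

#' Overlap between two acquisition trajectories
#'
#' The number of words appearing in the first `t` positions of both
#' trajectories.
#'
#' @param tau,ref trajectories (character vectors of word ids) over the same
#'   vocabulary.
#' @param t inventory size, `1 <= t <= N`.
#' @return integer overlap.
#' @export
overlap <- function(tau, ref, t) {
  n <- length(tau)
  if (!(t >= 1 && t <= n)) stop("t must be in 1..", n)
  length(intersect(tau[seq_len(t)], ref[seq_len(t)]))
}

# overlap curve O(t) for t = 1..N between one predicted trajectory and one
# reference; exact expected value when the prediction carries tie blocks
overlap_curve <- function(tau, ref) {
  n <- length(tau)
  q <- traj_positions(ref)[as.character(tau)]       # ref position, tau order
  a <- attr(tau, "block_start"); b <- attr(tau, "block_end")
  if (is.null(a)) { a <- seq_len(n); b <- seq_len(n) }
  full <- cumsum(tabulate(pmax(q, b), nbins = n))
  partial <- numeric(n)
  for (s in unique(a[b > a])) {
    idx <- which(a == s)                            # members of this block
    e <- b[idx[1L]]
    qs <- sort(q[idx])
    ts <- s:(e - 1L)
    cnt <- findInterval(ts, qs)
    partial[ts] <- partial[ts] + cnt * (ts - s + 1L) / length(idx)
  }
  full + partial
}

# mean overlap curve of a prediction (trajectory or ensemble) against a
# reference ensemble
mean_overlap_curve <- function(pred, ref_ensemble) {
  preds <- if (inherits(pred, "trajectory_ensemble")) pred$trajectories else
    list(pred)
  refs <- if (inherits(ref_ensemble, "trajectory_ensemble"))
    ref_ensemble$trajectories else list(ref_ensemble)
  curves <- lapply(preds, function(p)
    rowMeans(vapply(refs, function(r) overlap_curve(p, r),
                    numeric(length(p)))))
  Reduce(`+`, curves) / length(curves)
}

#' Mean overlap of a prediction against a reference ensemble
#'
#' Arithmetic mean of [overlap()] over all ensemble members. Predictions
#' produced by [rank_by_score()] under the `"expected"` tie policy
#' contribute the exact expected intersection of each tied block (the
#' block-wise hypergeometric expectation), equivalent in expectation to
#' averaging over all tie resolutions.
#'
#' @param pred a trajectory or `trajectory_ensemble` (prediction).
#' @param ref_ensemble a trajectory or `trajectory_ensemble` (references).
#' @param t inventory size.
#' @return mean overlap (numeric).
#' @export
mean_overlap <- function(pred, ref_ensemble, t) {
  mean_overlap_curve(pred, ref_ensemble)[t]
}

#' Random-guessing overlap baseline
#'
#' Statistics of the overlap between a uniformly random trajectory and the
#' reference at every inventory size t. Analytically the overlap of a random
#' permutation's first t words with a fixed t-set is hypergeometric with
#' mean `t^2/N` and variance `t (t/N) (1 - t/N) (N - t)/(N - 1)`. Monte
#' Carlo mode estimates mean and sd empirically from random permutations;
#' when a reference ensemble is supplied, the sampled statistic is the
#' ensemble-averaged overlap — the same statistic [gain_curve()] computes —
#' so Z-scores are calibrated against correlated reference ensembles too.
#'
#' @param N vocabulary size.
#' @param method `"analytic"` (default) or `"montecarlo"`.
#' @param n_samples number of random permutations for Monte Carlo.
#' @param seed integer seed for Monte Carlo.
#' @param ref_ensemble optional `trajectory_ensemble` for Monte Carlo mode.
#' @return an object of class `random_baseline`: list with vectors
#'   `mean_overlap` and `sd_overlap` (indexed by t = 1..N), `N`, `method`.
#' @export
random_baseline <- function(N, method = c("analytic", "montecarlo"),
                            n_samples = 1000L, seed = 1L,
                            ref_ensemble = NULL) {
  method <- match.arg(method)
  t <- seq_len(N)
  if (method == "analytic") {
    m <- t^2 / N
    v <- t * (t / N) * (1 - t / N) * (N - t) / max(N - 1, 1)
    out <- list(mean_overlap = m, sd_overlap = sqrt(pmax(v, 0)))
  } else {
    words <- if (is.null(ref_ensemble)) as.character(seq_len(N)) else
      sort(as.character(ref_ensemble$trajectories[[1L]]))
    refs <- if (is.null(ref_ensemble))
      trajectory_ensemble(list(new_trajectory(words, "ref"))) else ref_ensemble
    seeds <- split_seed(seed, n_samples)
    curves <- vapply(seq_len(n_samples), function(i) {
      tau <- new_trajectory(with_seed(seeds[i], sample(words)), "ran")
      mean_overlap_curve(tau, refs)
    }, numeric(N))
    out <- list(mean_overlap = rowMeans(curves),
                sd_overlap = apply(curves, 1L, stats::sd))
  }
  structure(c(out, list(N = N, method = method,
                        n_samples = if (method == "montecarlo") n_samples else NULL)),
            class = "random_baseline")
}

#' Gain curve of a predicted ordering
#'
#' For every inventory size t: the mean overlap `O(t)` of the prediction
#' with the normative ensemble, the word gain `g(t) = O(t) - E[O(ran, t)]`,
#' the vocabulary-normalized gain `G(t) = g(t)/t`, and the Z-score
#' `Z(t) = g(t) / sd(O(ran, t))` (`NA` where the sd is 0, e.g. at t = N).
#'
#' @param pred a trajectory or `trajectory_ensemble` (prediction).
#' @param ref_ensemble reference `trajectory_ensemble`.
#' @param baseline a [random_baseline()] for the same N.
#' @param label curve label; defaults to the prediction's label.
#' @return a `gain_curve` data frame with columns `label`, `t`, `overlap`,
#'   `gain`, `norm_gain`, `zscore`.
#' @export
gain_curve <- function(pred, ref_ensemble, baseline, label = NULL) {
  o <- mean_overlap_curve(pred, ref_ensemble)
  n <- length(o)
  stopifnot(baseline$N == n)
  if (is.null(label)) {
    tr1 <- if (inherits(pred, "trajectory_ensemble")) pred$trajectories[[1L]] else pred
    label <- if (!is.null(attr(tr1, "label"))) attr(tr1, "label") else "prediction"
  }
  g <- o - baseline$mean_overlap
  z <- ifelse(baseline$sd_overlap > 0, g / baseline$sd_overlap, NA_real_)
  structure(data.frame(label = label, t = seq_len(n), overlap = o, gain = g,
                       norm_gain = g / seq_len(n), zscore = z),
            class = c("gain_curve", "data.frame"))
}

#' One-sided critical Z value
#'
#' The Gaussian critical value used to flag gains as significantly better
#' than random: `qnorm(1 - alpha)`; at the 2.5% level this is 1.96.
#'
#' @param alpha one-sided significance level (default 0.025).
#' @return critical Z (numeric).
#' @export
critical_z <- function(alpha = 0.025) stats::qnorm(1 - alpha)

#' Significance of a gain curve
#'
#' For inventory sizes `t >= gaussian_min_t` (the range where the random
#' overlap distribution is well approximated by a Gaussian) the one-sided
#' p-value is `1 - pnorm(Z)`. For smaller t the Gaussian approximation is
#' unreliable and a direct-sampling p-value is used instead: the fraction of
#' random orderings whose (ensemble-averaged) overlap at t is at least the
#' observed mean overlap. When no reference ensemble is supplied the random
#' overlap is drawn from its exact single-reference law (hypergeometric),
#' which is the distribution a permutation sample would give.
#'
#' @param curve a [gain_curve()].
#' @param baseline the [random_baseline()] used for the curve.
#' @param ref_ensemble optional reference `trajectory_ensemble`; when given,
#'   direct sampling draws random orderings and evaluates them against it.
#' @param gaussian_min_t first t at which the Gaussian approximation is used
#'   (default 60).
#' @param alpha one-sided significance level (default 0.025).
#' @param n_direct number of direct samples (default 100000; at least 1000).
#' @param seed integer seed for direct sampling.
#' @return the curve with columns `pvalue`, `significant` and
#'   `significance_method` (`"gaussian"` or `"direct_sampling"`) added.
#' @export
significance <- function(curve, baseline, ref_ensemble = NULL,
                         gaussian_min_t = 60L, alpha = 0.025,
                         n_direct = 100000L, seed = 1L) {
  n <- nrow(curve)
  pv <- rep(NA_real_, n)
  meth <- ifelse(curve$t >= gaussian_min_t, "gaussian", "direct_sampling")
  gaus <- which(meth == "gaussian")
  pv[gaus] <- stats::pnorm(curve$zscore[gaus], lower.tail = FALSE)
  small <- which(meth == "direct_sampling")
  if (length(small) > 0L) {
    stopifnot(n_direct >= 1000L)
    tmax <- max(curve$t[small])
    obs <- curve$overlap[small]
    if (is.null(ref_ensemble)) {
      pv[small] <- with_seed(seed, vapply(seq_along(small), function(k) {
        t <- curve$t[small[k]]
        draws <- stats::rhyper(n_direct, t, baseline$N - t, t)
        mean(draws >= obs[k])
      }, 0))
    } else {
      refs <- ref_ensemble$trajectories
      words <- sort(as.character(refs[[1L]]))
      stopifnot(length(words) == baseline$N)
      # C[w, t] = number of references having word w within their first t
      qmat <- vapply(refs, function(r) traj_positions(r)[words],
                     numeric(length(words)))
      C <- vapply(seq_len(tmax), function(t) rowSums(qmat <= t),
                  numeric(length(words)))
      # mask[i, t] selects positions i <= t (the first t draws)
      mask <- upper.tri(matrix(0, tmax, tmax), diag = TRUE)
      stats_mat <- with_seed(seed, {
        vapply(seq_len(n_direct), function(i) {
          idx <- sample.int(length(words), tmax)
          colSums(C[idx, , drop = FALSE] * mask) / length(refs)
        }, numeric(tmax))
      })
      for (k in seq_along(small)) {
        t <- curve$t[small[k]]
        pv[small[k]] <- mean(stats_mat[t, ] >= obs[k])
      }
    }
  }
  curve$pvalue <- pv
  curve$significant <- pv < alpha
  curve$significance_method <- meth
  curve
}

#' Learning-stage windows
#'
#' The analysis distinguishes a very early learning stage (VELS, months
#' 19-20, operationalised as the first 40 learned words), an early learning
#' stage (ELS, months 20-23) and a late learning stage (LLS, months 23-28).
#'
#' @param vels,els,lls length-2 integer month ranges.
#' @param vels_t optional explicit inventory-size range for VELS
#'   (default `c(1, 40)`).
#' @return a named list of stage definitions.
#' @export
stage_windows <- function(vels = c(19L, 20L), els = c(20L, 23L),
                          lls = c(23L, 28L), vels_t = c(1L, 40L)) {
  list(VELS = list(months = vels, t_range = vels_t),
       ELS = list(months = els, t_range = NULL),
       LLS = list(months = lls, t_range = NULL))
}

stage_t_range <- function(stage, month_to_t, N) {
  if (!is.null(stage$t_range)) return(stage$t_range)
  avail <- as.integer(names(month_to_t))
  mo <- pmin(pmax(stage$months, min(avail)), max(avail))
  if (!identical(mo, stage$months))
    message("stage months ", paste(stage$months, collapse = "-"),
            " clamped to covered range ", paste(mo, collapse = "-"))
  mt <- month_to_t[as.character(mo)]
  c(max(1L, mt[1L] + 1L), min(N, max(mt[2L], mt[1L] + 1L)))
}

#' Rank candidate orderings within learning stages
#'
#' For each stage, candidate gain curves are ranked by their mean normalized
#' word gain over the stage's inventory-size range (month ranges are
#' converted to t ranges with the supplied month-to-inventory-size map, e.g.
#' from [inventory_size_by_month()]).
#'
#' @param curves list of [gain_curve()] objects.
#' @param windows stage definitions from [stage_windows()].
#' @param month_to_t named integer vector mapping month to inventory size;
#'   must be nondecreasing.
#' @return data frame with columns `stage`, `label`, `t_lo`, `t_hi`,
#'   `mean_norm_gain`, `rank` (1 = best per stage).
#' @export
stage_report <- function(curves, windows, month_to_t) {
  stopifnot(!is.unsorted(month_to_t))
  N <- max(curves[[1L]]$t)
  rows <- lapply(names(windows), function(st) {
    tr <- stage_t_range(windows[[st]], month_to_t, N)
    ts <- seq.int(tr[1L], tr[2L])
    g <- vapply(curves, function(cu) mean(cu$norm_gain[cu$t %in% ts]), 0)
    data.frame(stage = st,
               label = vapply(curves, function(cu) cu$label[1L], ""),
               t_lo = tr[1L], t_hi = tr[2L], mean_norm_gain = g,
               rank = rank(-g, ties.method = "min"), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Write gain curves as CSV
#'
#' @param curves a `gain_curve` or list of them.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gain_curves <- function(curves, path) {
  if (inherits(curves, "gain_curve")) curves <- list(curves)
  utils::write.csv(do.call(rbind, lapply(curves, as.data.frame)), path,
                   row.names = FALSE)
  invisible(path)
}
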