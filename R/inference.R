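# Statistical tests and sensitivity analyses for the ti:tv ratio among
# parallel adaptive replacements: exact binomial machinery at the path
# level, resampling (path bootstrap, class randomization) at the event
# level, cutoff scans, and contamination arithmetic.
#
# All tests are one-sided "greater", per the a priori hypothesis that
# mutational bias elevates the ti:tv ratio among parallel replacements.

#' Null specification for the ti:tv ratio
#'
#' The conservative null expectation is a ti:tv ratio of 0.5 (each site has
#' one possible transition and two possible transversions), i.e. a
#' transition probability of 1/3 per path. Genetic-code-aware models give
#' ratios between 0.4 and 0.5 (see \code{\link{null_ratio}}); 0.5 is the
#' most conservative of them against the alternative of transition
#' enrichment.
#'
#' @param ratio Null ti:tv ratio R0 (positive, finite). Default 0.5.
#' @return An object of class \code{null_spec}: list with \code{ratio} and
#'   the implied per-path transition probability \code{p = ratio/(1+ratio)}.
#' @export
null_spec <- function(ratio = 0.5) {
  stopifnot(length(ratio) == 1, is.numeric(ratio), is.finite(ratio), ratio > 0)
  structure(list(ratio = ratio, p = ratio / (1 + ratio)), class = "null_spec")
}

#' Exact one-sided binomial test for transition paths
#'
#' Tests whether the number of transition paths exceeds the null expectation,
#' treating each path as an independent Bernoulli draw with transition
#' probability \code{null$p}. The p-value is the exact upper tail
#' \eqn{P(X \ge ti\_paths)} for \eqn{X \sim Binomial(ti+tv, p_0)}.
#'
#' @param ti_paths,tv_paths Non-negative integer path counts, summing to at
#'   least 1.
#' @param null A \code{\link{null_spec}}.
#' @return An object of class \code{titv_test} with \code{p_value},
#'   \code{method = "binomial_exact"}, \code{sidedness}, \code{null_ratio}
#'   and \code{observed_statistic} (the observed transition path count).
#' @examples
#' binomial_path_test(28, 27)$p_value  # ~5.3e-3
#' @export
binomial_path_test <- function(ti_paths, tv_paths, null = null_spec()) {
  stopifnot(ti_paths >= 0, tv_paths >= 0, ti_paths + tv_paths >= 1,
            inherits(null, "null_spec"))
  n <- ti_paths + tv_paths
  p <- stats::pbinom(ti_paths - 1, n, null$p, lower.tail = FALSE)
  structure(
    list(p_value = p, method = "binomial_exact",
         sidedness = "one_sided_greater", null_ratio = null$ratio,
         observed_statistic = ti_paths, n = n),
    class = "titv_test"
  )
}

#' @export
print.titv_test <- function(x, ...) {
  cat(sprintf("One-sided %s test: observed %s, P = %s\n",
              x$method, format(x$observed_statistic, digits = 4),
              format_pvalue(x)))
  invisible(x)
}

# Display convention: Monte-Carlo p-values below 1e-5 are not distinguished.
format_pvalue <- function(x) {
  if (identical(x$method, "randomization") && x$p_value < 1e-5) {
    return("<1e-05")
  }
  format(signif(x$p_value, 3))
}

#' Expected number of transition paths under the null
#'
#' @param n_paths Total number of paths.
#' @param null A \code{\link{null_spec}}.
#' @return \code{n_paths * null$p}; e.g. 18.3 of 55 paths at the 0.5 null.
#' @export
expected_ti_paths <- function(n_paths, null = null_spec()) {
  stopifnot(n_paths >= 0)
  n_paths * null$p
}

#' Clopper-Pearson confidence interval for the path-level ti:tv ratio
#'
#' Computes the exact (Clopper-Pearson) binomial confidence interval for the
#' transition proportion among paths and transforms the endpoints to the
#' ratio scale via \eqn{r = p/(1-p)}. With no transversion paths the upper
#' endpoint is \code{Inf}.
#'
#' @param ti_paths,tv_paths Path counts (sum >= 1).
#' @param level Confidence level, default 0.95.
#' @return An object of class \code{ratio_estimate} with \code{level_of}
#'   (\code{"paths"}), \code{ratio}, \code{ci_low}, \code{ci_high},
#'   \code{ci_level} and \code{method}.
#' @examples
#' binomial_ratio_ci(43, 20)  # approximately (1.2, 3.9)
#' @export
binomial_ratio_ci <- function(ti_paths, tv_paths, level = 0.95) {
  stopifnot(ti_paths >= 0, tv_paths >= 0, ti_paths + tv_paths >= 1,
            level > 0, level < 1)
  x <- ti_paths; n <- ti_paths + tv_paths
  alpha <- 1 - level
  p_lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  p_hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  structure(
    list(level_of = "paths", ratio = ti_paths / tv_paths,
         ci_low = p_lo / (1 - p_lo),
         ci_high = if (p_hi >= 1) Inf else p_hi / (1 - p_hi),
         ci_level = level, method = "clopper_pearson_transformed"),
    class = "ratio_estimate"
  )
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("ti:tv ratio (%s): %s, %d%% CI (%s, %s) [%s]\n",
              x$level_of, format_ratio(x$ratio), round(100 * x$ci_level),
              format_ratio(x$ci_low), format_ratio(x$ci_high), x$method))
  invisible(x)
}

# Canonical internal representation for resampling: event counts and class,
# sorted (class, then count, then label) so results do not depend on input
# row order.
resampling_frame <- function(dataset) {
  stopifnot(inherits(dataset, "parallelism_dataset"))
  d <- dataset[dataset$n_events >= 2L, , drop = FALSE]
  if (!nrow(d)) stop("dataset has no parallel paths (n_events >= 2)")
  ord <- order(d$mutation_class, d$n_events, d$path_label)
  list(events = as.numeric(d$n_events[ord]),
       is_ti = d$mutation_class[ord] == "ti")
}

#' Path-bootstrap confidence interval for the event-level ti:tv ratio
#'
#' Because paths carry variable numbers of events, the event-level ratio has
#' no exact binomial analysis; the sampling unit is therefore the path. Each
#' bootstrap sample resamples paths with replacement (each keeping its event
#' count), and the percentile interval of the resulting event-level ti:tv
#' ratios is reported. All-transition resamples give an infinite ratio,
#' which sorts above every finite value.
#'
#' @param dataset A \code{parallelism_dataset} with at least one parallel
#'   path.
#' @param n_boot Number of bootstrap samples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @return A \code{ratio_estimate} with \code{method =
#'   "percentile_bootstrap"}, plus \code{n_boot} and \code{seed}. Endpoints
#'   are invariant to the row order of \code{dataset}.
#' @examples
#' bootstrap_event_ratio(load_fixture("natural"), n_boot = 1000, seed = 1)
#' @export
bootstrap_event_ratio <- function(dataset, n_boot = 10000, level = 0.95,
                                  seed = NULL) {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  fr <- resampling_frame(dataset)
  n <- length(fr$events)
  if (!is.null(seed)) set.seed(seed)
  ev_ti <- fr$events * fr$is_ti
  ev_tv <- fr$events * !fr$is_ti
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  ti_sum <- colSums(matrix(ev_ti[idx], nrow = n))
  tv_sum <- colSums(matrix(ev_tv[idx], nrow = n))
  ratios <- ti_sum / tv_sum  # Inf when tv_sum == 0
  alpha <- 1 - level
  qs <- stats::quantile(ratios, c(alpha / 2, 1 - alpha / 2), type = 1,
                        names = FALSE)
  structure(
    list(level_of = "events",
         ratio = sum(ev_ti) / sum(ev_tv),
         ci_low = qs[1], ci_high = qs[2], ci_level = level,
         method = "percentile_bootstrap", n_boot = n_boot, seed = seed),
    class = "ratio_estimate"
  )
}

#' Randomization test for the event-level ti:tv ratio
#'
#' Tests whether the event-level ti:tv ratio exceeds the null expectation by
#' randomly reassigning each path's mutational class (transition with
#' probability \code{null$p}), keeping its event count, and recomputing the
#' event-level ratio. The one-sided p-value uses the add-one convention,
#' \eqn{p = (1 + \#\{ratio^* \ge ratio_{obs}\}) / (n_{reps} + 1)}, with ties
#' (including infinite = infinite) counted as exceedances; it can never be
#' smaller than \code{1/(n_reps+1)}.
#'
#' @param dataset A \code{parallelism_dataset}.
#' @param null A \code{\link{null_spec}}.
#' @param n_reps Number of randomizations (default 1e6, as in the study
#'   analyses).
#' @param seed Optional integer seed.
#' @return A \code{titv_test} with \code{method = "randomization"},
#'   \code{n_replicates}, \code{seed} and \code{observed_statistic} (the
#'   observed event-level ratio).
#' @examples
#' randomization_event_test(load_fixture("natural"), n_reps = 1e4, seed = 1)
#' @export
randomization_event_test <- function(dataset, null = null_spec(),
                                     n_reps = 1e6, seed = NULL) {
  stopifnot(inherits(null, "null_spec"), n_reps >= 1)
  fr <- resampling_frame(dataset)
  n <- length(fr$events)
  total <- sum(fr$events)
  obs <- sum(fr$events[fr$is_ti]) / sum(fr$events[!fr$is_ti])
  if (!is.null(seed)) set.seed(seed)
  n_reps <- as.integer(n_reps)
  chunk <- max(1L, min(n_reps, as.integer(ceiling(2e6 / n))))
  exceed <- 0
  done <- 0L
  while (done < n_reps) {
    m <- min(chunk, n_reps - done)
    draws <- matrix(stats::runif(n * m) < null$p, nrow = n)
    ti_sum <- colSums(fr$events * draws)
    stat <- ti_sum / (total - ti_sum)
    exceed <- exceed + sum(stat >= obs)
    done <- done + m
  }
  structure(
    list(p_value = (1 + exceed) / (n_reps + 1), method = "randomization",
         sidedness = "one_sided_greater", null_ratio = null$ratio,
         observed_statistic = obs, n_replicates = n_reps, seed = seed),
    class = "titv_test"
  )
}

#' Sensitivity scan over event-count cutoffs
#'
#' Reruns the path and event analyses after restricting the dataset to paths
#' observed at least \code{k} times, for \code{k = 2..k_max}. Stricter
#' cutoffs should purge hitch-hikers and other neutral contaminants; a
#' mutational-bias signal should survive them.
#'
#' @param dataset A \code{parallelism_dataset}.
#' @param k_max Largest cutoff (default 8).
#' @param null A \code{\link{null_spec}}.
#' @param n_reps Randomizations per cutoff for the event-level p-value.
#' @param seed Optional integer seed (each cutoff derives its own stream).
#' @return A data.frame of class \code{cutoff_scan} with one row per cutoff:
#'   \code{cutoff}, \code{ti_paths}, \code{tv_paths}, \code{path_ratio},
#'   \code{path_p}, \code{ti_events}, \code{tv_events}, \code{event_ratio},
#'   \code{event_p}. Cutoffs that exclude every path yield zero counts and
#'   \code{NA} ratios and p-values.
#' @examples
#' cutoff_scan(load_fixture("experimental"), k_max = 4, n_reps = 1e3, seed = 1)
#' @export
cutoff_scan <- function(dataset, k_max = 8, null = null_spec(),
                        n_reps = 1e5, seed = NULL) {
  stopifnot(k_max >= 2)
  rows <- lapply(2:k_max, function(k) {
    d <- apply_cutoff(dataset, k)
    agg <- aggregate_paths(d)
    if (agg$ti_paths + agg$tv_paths == 0) {
      return(data.frame(cutoff = k, ti_paths = 0L, tv_paths = 0L,
                        path_ratio = NA_real_, path_p = NA_real_,
                        ti_events = 0L, tv_events = 0L,
                        event_ratio = NA_real_, event_p = NA_real_))
    }
    pt <- binomial_path_test(agg$ti_paths, agg$tv_paths, null)
    et <- randomization_event_test(d, null, n_reps = n_reps,
                                   seed = if (is.null(seed)) NULL else seed + k)
    data.frame(cutoff = k,
               ti_paths = agg$ti_paths, tv_paths = agg$tv_paths,
               path_ratio = agg$path_ratio, path_p = pt$p_value,
               ti_events = agg$ti_events, tv_events = agg$tv_events,
               event_ratio = agg$event_ratio, event_p = et$p_value)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_scan", "data.frame")
  out
}

#' Contamination level needed to explain an observed path excess
#'
#' Asks how much contamination by non-adaptive changes (hitch-hikers,
#' misidentifications) would be required to explain the observed transition
#' excess, under the worst-case assumption that every contaminant is a
#' transition. The genuine paths are assumed to sit exactly at the null
#' ratio: \code{genuine_tv = tv_paths}, \code{genuine_ti = R0 * tv_paths},
#' and the remaining transitions are contaminants.
#'
#' @param ti_paths,tv_paths Observed path counts.
#' @param null A \code{\link{null_spec}}.
#' @return An object of class \code{contamination_result}: list with
#'   \code{observed_ti}, \code{observed_tv}, \code{genuine_ti},
#'   \code{genuine_tv}, \code{n_contaminants} (floored at 0) and
#'   \code{contaminant_fraction}.
#' @examples
#' contamination_threshold(43, 20)  # 33 all-transition contaminants
#' @export
contamination_threshold <- function(ti_paths, tv_paths, null = null_spec()) {
  stopifnot(ti_paths >= 0, tv_paths >= 0, inherits(null, "null_spec"))
  genuine_ti <- null$ratio * tv_paths
  n_cont <- max(0, ti_paths - genuine_ti)
  structure(
    list(observed_ti = ti_paths, observed_tv = tv_paths,
         genuine_ti = min(genuine_ti, ti_paths), genuine_tv = tv_paths,
         n_contaminants = n_cont,
         contaminant_fraction = if (ti_paths + tv_paths > 0)
           n_cont / (ti_paths + tv_paths) else 0),
    class = "contamination_result"
  )
}

#' @export
print.contamination_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Observed %d ti / %d tv paths: explaining the excess with all-transition\n",
    "contaminants requires %.3g contaminants (%.1f%% of paths) alongside\n",
    "%.3g:%.3g genuine paths at the null ratio.\n"),
    x$observed_ti, x$observed_tv, x$n_contaminants,
    100 * x$contaminant_fraction, x$genuine_ti, x$genuine_tv))
  invisible(x)
}

#' Rule-of-three upper bound for a zero count
#'
#' Upper endpoint of the 95% confidence interval for a proportion when 0
#' successes are observed in \code{n_trials} trials: \code{3/n}, capped at 1.
#' Used to bound the hitch-hiker frequency from the absence of synonymous
#' changes among sequenced substitutions (e.g. 0 of 241 gives 1.2%).
#'
#' @param n_trials Number of trials (>= 1) with zero observed successes.
#' @return The upper-bound proportion.
#' @examples
#' zero_count_upper_bound(241)  # 0.01245 (1.2%)
#' @export
zero_count_upper_bound <- function(n_trials) {
  stopifnot(length(n_trials) == 1, n_trials >= 1, n_trials == round(n_trials))
  min(1, 3 / n_trials)
}
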