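# Bundled analysis of one parallelism dataset, and JSON/TSV report writers.

#' Full ti:tv analysis of a parallelism dataset
#'
#' Runs the complete analysis on one dataset: path/event aggregation, the
#' one-sided binomial path test and Clopper-Pearson ratio interval, the
#' path-bootstrap event interval and randomization event test, the
#' event-count cutoff scan, the contamination threshold, and the implied
#' mutation-bias estimate.
#'
#' @param dataset A \code{parallelism_dataset}.
#' @param null A \code{\link{null_spec}}.
#' @param n_boot Bootstrap samples for the event CI.
#' @param n_reps Randomizations for the event test (also used, per cutoff,
#'   by the scan).
#' @param k_max Largest event-count cutoff for the scan.
#' @param level Confidence level for both intervals.
#' @param seed Integer seed; sub-analyses derive fixed offsets from it so a
#'   report is reproducible end to end.
#' @return An object of class \code{parallelism_analysis}: a list with
#'   \code{counts}, \code{expected_ti_paths}, \code{path_test},
#'   \code{path_ci}, \code{event_test}, \code{event_ci}, \code{cutoffs},
#'   \code{contamination}, \code{kappa_hat} and \code{provenance}.
#' @examples
#' analyze_dataset(load_fixture("natural"), n_boot = 200, n_reps = 200,
#'                 seed = 1)
#' @export
analyze_dataset <- function(dataset, null = null_spec(), n_boot = 10000,
                            n_reps = 1e6, k_max = 8, level = 0.95,
                            seed = 1) {
  stopifnot(inherits(dataset, "parallelism_dataset"))
  agg <- aggregate_paths(dataset)
  out <- list(
    counts = agg,
    expected_ti_paths = expected_ti_paths(agg$ti_paths + agg$tv_paths, null),
    path_test = binomial_path_test(agg$ti_paths, agg$tv_paths, null),
    path_ci = binomial_ratio_ci(agg$ti_paths, agg$tv_paths, level),
    event_ci = bootstrap_event_ratio(dataset, n_boot = n_boot, level = level,
                                     seed = seed),
    event_test = randomization_event_test(dataset, null, n_reps = n_reps,
                                          seed = seed + 1L),
    cutoffs = cutoff_scan(dataset, k_max = k_max, null = null,
                          n_reps = n_reps, seed = seed + 100L),
    contamination = contamination_threshold(agg$ti_paths, agg$tv_paths, null),
    kappa_hat = if (agg$tv_events > 0) estimate_kappa(agg, null) else NA_real_,
    provenance = list(
      package_version = as.character(utils::packageVersion("titvbias")),
      dataset_name = dataset_name(dataset),
      n_records = nrow(dataset),
      dataset_checksum = dataset_checksum(dataset),
      null_ratio = null$ratio, n_boot = n_boot, n_reps = n_reps,
      k_max = k_max, ci_level = level, seed = seed)
  )
  class(out) <- "parallelism_analysis"
  out
}

# md5 of the canonical TSV serialization (rows sorted), so reports carry a
# fingerprint of the exact data analyzed.
dataset_checksum <- function(dataset) {
  d <- as.data.frame(dataset)
  d <- d[do.call(order, d), , drop = FALSE]
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(d, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' @export
print.parallelism_analysis <- function(x, ...) {
  cat(sprintf("== ti:tv analysis of dataset '%s' (null ratio %.3g) ==\n",
              x$provenance$dataset_name, x$provenance$null_ratio))
  print(x$counts)
  cat(sprintf("Expected ti paths under the null: %.1f of %d\n",
              x$expected_ti_paths, x$counts$ti_paths + x$counts$tv_paths))
  cat("Paths : "); print(x$path_ci)
  cat(sprintf("        binomial P = %s\n", format_pvalue(x$path_test)))
  cat("Events: "); print(x$event_ci)
  cat(sprintf("        randomization P = %s (%g reps)\n",
              format_pvalue(x$event_test), x$event_test$n_replicates))
  cat(sprintf("Implied mutation bias: %.2g-fold over the null\n", x$kappa_hat))
  invisible(x)
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write an analysis report as JSON
#'
#' Serializes a \code{\link{analyze_dataset}} result (including provenance:
#' package version, dataset checksum, seeds, and null spec) to a JSON file.
#' Infinities are encoded as the string \code{"Inf"}.
#'
#' @param analysis A \code{parallelism_analysis}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_analysis_json <- function(analysis, path) {
  stopifnot(inherits(analysis, "parallelism_analysis"))
  x <- strip_class(analysis)
  x$cutoffs <- as.data.frame(analysis$cutoffs)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", force = TRUE)
  invisible(path)
}

#' Write the null-model table as JSON
#'
#' @param usage Optional \code{codon_usage} table.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_null_model_json <- function(path, usage = NULL) {
  tab <- null_model_table(usage)
  jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Render a cutoff scan as a TSV table
#'
#' @param scan A \code{\link{cutoff_scan}} result.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_cutoff_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "cutoff_scan"))
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
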