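# Path/event data model for parallel adaptive amino acid replacements.
#
# A *path* is one specific parallel replacement (e.g. V132M at one site); an
# *event* is one independent occurrence of that path in a replicate
# population, lineage, or species. Datasets are tables of paths with their
# mutational class (ti/tv) and event counts; a record must have >= 2 events
# to count as a parallelism.

path_required_columns <- c("case_id", "phenotype", "taxon", "target_gene",
                           "path_label", "mutation_class", "n_events",
                           "evidence_type")

#' Construct a parallelism dataset
#'
#' @param records A data.frame with (at least) columns \code{case_id},
#'   \code{phenotype}, \code{taxon}, \code{target_gene}, \code{path_label},
#'   \code{mutation_class} (\code{"ti"} or \code{"tv"}), \code{n_events}
#'   (integer >= 1) and \code{evidence_type}. Extra columns are preserved.
#' @param name Provenance label: \code{"experimental"}, \code{"natural"},
#'   \code{"user"}, \code{"simulated"}, or any short string.
#' @return An object of class \code{parallelism_dataset} (a data.frame with a
#'   \code{dataset_name} attribute). Records with \code{n_events == 1} are
#'   storable but are excluded from parallelism analyses by
#'   \code{\link{aggregate_paths}} and \code{\link{apply_cutoff}}.
#' @export
parallelism_dataset <- function(records, name = "user") {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(path_required_columns, names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  bad <- !records$mutation_class %in% c("ti", "tv")
  if (any(bad)) {
    stop("mutation_class must be 'ti' or 'tv'; bad value(s): ",
         paste(unique(records$mutation_class[bad]), collapse = ", "))
  }
  ne <- records$n_events
  if (!is.numeric(ne) || any(is.na(ne)) || any(ne < 1) || any(ne != round(ne))) {
    stop("n_events must be integers >= 1")
  }
  records$n_events <- as.integer(ne)
  rownames(records) <- NULL
  structure(records, dataset_name = name,
            class = c("parallelism_dataset", "data.frame"))
}

#' @export
print.parallelism_dataset <- function(x, ...) {
  cat(sprintf("Parallelism dataset '%s': %d paths (%d ti, %d tv), %d events\n",
              dataset_name(x), nrow(x),
              sum(x$mutation_class == "ti"), sum(x$mutation_class == "tv"),
              sum(x$n_events)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @rdname parallelism_dataset
#' @param x A \code{parallelism_dataset}.
#' @export
dataset_name <- function(x) {
  nm <- attr(x, "dataset_name")
  if (is.null(nm)) "user" else nm
}

#' Load a bundled parallelism fixture
#'
#' The package bundles the curated path/event tables of the two study
#' datasets: \code{"experimental"} (5 laboratory-evolution cases, 63 paths /
#' 389 events) and \code{"natural"} (10 cases of adaptation in nature, 55
#' paths / 231 events). A third fixture, \code{"excluded"}, holds the two
#' aphid-clade sodium-pump parallels (T797A, N122Y) that the original
#' curators did not count as adaptive parallels, with the reason recorded.
#'
#' @param name One of \code{"experimental"}, \code{"natural"},
#'   \code{"excluded"}.
#' @return A \code{parallelism_dataset}.
#' @examples
#' aggregate_paths(load_fixture("experimental"))
#' @export
load_fixture <- function(name = c("experimental", "natural", "excluded")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_paths.tsv"),
                      package = "titvbias", mustWork = TRUE)
  read_paths_tsv(path, name = name)
}

#' Read / write a parallelism dataset as TSV
#'
#' The paths TSV dialect is tab-separated UTF-8 with a header row containing
#' at least the columns of \code{\link{parallelism_dataset}};
#' \code{mutation_class} uses the tokens \code{ti} / \code{tv}; lines
#' starting with \code{#} are comments. Unknown columns are preserved, and
#' write-then-read is the identity on canonical form.
#'
#' @param path File path.
#' @param name Provenance label for the returned dataset.
#' @return \code{read_paths_tsv} returns a \code{parallelism_dataset};
#'   \code{write_paths_tsv} returns \code{path} invisibly.
#' @export
read_paths_tsv <- function(path, name = "user") {
  if (!file.exists(path)) stop("paths TSV not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(idx)) stop("no header row in ", path)
  header <- strsplit(lines[idx[1]], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(path_required_columns, header)
  if (length(missing_cols)) {
    stop("line ", idx[1], ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rows <- lapply(idx[-1], function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      stop("line ", i, ": expected ", length(header), " fields, got ",
           length(fields))
    }
    fields
  })
  if (length(rows)) {
    mat <- do.call(rbind, rows)
    records <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(records) <- header
  } else {
    records <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(header)), header),
      stringsAsFactors = FALSE)
  }
  ne <- suppressWarnings(as.numeric(records$n_events))
  bad <- which(is.na(ne) | ne < 1 | ne != round(ne))
  if (length(bad)) {
    stop("line ", idx[-1][bad[1]], ": n_events must be an integer >= 1, got '",
         records$n_events[bad[1]], "'")
  }
  records$n_events <- as.integer(ne)
  badcl <- which(!records$mutation_class %in% c("ti", "tv"))
  if (length(badcl)) {
    stop("line ", idx[-1][badcl[1]], ": mutation_class must be 'ti' or 'tv', got '",
         records$mutation_class[badcl[1]], "'")
  }
  parallelism_dataset(records, name = name)
}

#' @rdname read_paths_tsv
#' @param dataset A \code{parallelism_dataset}.
#' @export
write_paths_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "parallelism_dataset"))
  df <- as.data.frame(dataset)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Aggregate a dataset to path and event counts
#'
#' Sums transition and transversion paths and events over all records with
#' \code{n_events >= 2} (the parallelism inclusion rule) and forms the two
#' ti:tv ratios. A zero denominator gives \code{Inf} (bootstrap resamples can
#' produce all-transition samples), and an empty dataset gives \code{NaN}
#' ratios.
#'
#' @param dataset A \code{parallelism_dataset}.
#' @return An object of class \code{aggregate_counts}: a list with
#'   \code{ti_paths}, \code{tv_paths}, \code{ti_events}, \code{tv_events},
#'   \code{path_ratio}, \code{event_ratio}.
#' @examples
#' aggregate_paths(load_fixture("natural"))  # 28/27 paths, 132/99 events
#' @export
aggregate_paths <- function(dataset) {
  stopifnot(inherits(dataset, "parallelism_dataset"))
  d <- dataset[dataset$n_events >= 2L, , drop = FALSE]
  ti <- d$mutation_class == "ti"
  out <- list(
    ti_paths = sum(ti),
    tv_paths = sum(!ti),
    ti_events = sum(d$n_events[ti]),
    tv_events = sum(d$n_events[!ti])
  )
  out$path_ratio <- out$ti_paths / out$tv_paths
  out$event_ratio <- out$ti_events / out$tv_events
  structure(out, class = "aggregate_counts")
}

#' @export
print.aggregate_counts <- function(x, ...) {
  cat(sprintf("Paths : %d ti / %d tv (ti:tv = %s)\n",
              x$ti_paths, x$tv_paths, format_ratio(x$path_ratio)))
  cat(sprintf("Events: %d ti / %d tv (ti:tv = %s)\n",
              x$ti_events, x$tv_events, format_ratio(x$event_ratio)))
  invisible(x)
}

# Display convention: 1 decimal for ratios >= 1, 2 decimals below 1.
format_ratio <- function(r) {
  if (length(r) != 1 || is.nan(r)) return("NA")
  if (!is.finite(r)) return("Inf")
  formatC(r, digits = if (r >= 1) 1 else 2, format = "f")
}

#' Restrict a dataset to paths with at least k events
#'
#' Increasingly stringent event-count cutoffs reduce the expected frequency
#' of hitch-hikers and other neutral contaminants among the retained paths.
#'
#' @param dataset A \code{parallelism_dataset}.
#' @param k Minimum number of parallel events per path (integer >= 2).
#' @return The filtered \code{parallelism_dataset}.
#' @examples
#' aggregate_paths(apply_cutoff(load_fixture("experimental"), 4))
#' @export
apply_cutoff <- function(dataset, k) {
  stopifnot(inherits(dataset, "parallelism_dataset"),
            length(k) == 1, is.numeric(k), k == round(k))
  if (k < 2) stop("cutoff k must be >= 2 (the parallelism inclusion rule)")
  out <- dataset[dataset$n_events >= k, , drop = FALSE]
  parallelism_dataset(as.data.frame(out), name = dataset_name(dataset))
}
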