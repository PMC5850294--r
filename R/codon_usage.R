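# Codon usage tables for the usage-weighted null models. Input format is a
# CUTG-style frequency table: one row per codon, `codon<sep>count`, with
# whitespace or comma separators and '#' comment lines.

#' Read a codon usage table
#'
#' Parses a CUTG-style table with one row per codon (all 64 required) and a
#' non-negative count or frequency. Frequencies are normalized over the 61
#' sense codons; stop codons are retained in the table but carry no weight in
#' the null models.
#'
#' @param path Path to the table. Rows are `codon<sep>value` with whitespace
#'   or comma separators; lines starting with `#` are ignored.
#' @param species Optional species label stored on the result.
#' @return An object of class \code{codon_usage}: a data.frame with columns
#'   \code{codon}, \code{count} and \code{frequency} (normalized over sense
#'   codons; \code{NA} for stops), with a \code{species} attribute.
#' @export
read_codon_usage <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("codon usage file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  codons <- character(0); counts <- numeric(0)
  for (i in idx) {
    fields <- strsplit(trimws(lines[i]), "[\\s,]+", perl = TRUE)[[1]]
    if (length(fields) != 2L) {
      stop("line ", i, ": expected `codon<sep>count`, got: ", lines[i])
    }
    cod <- toupper(fields[1])
    if (!grepl("^[ACGT]{3}$", cod)) {
      stop("line ", i, ": not a DNA codon: ", fields[1])
    }
    val <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(val)) stop("line ", i, ": non-numeric value: ", fields[2])
    if (val < 0) stop("line ", i, ": negative value: ", fields[2])
    if (cod %in% codons) stop("line ", i, ": duplicate codon: ", cod)
    codons <- c(codons, cod); counts <- c(counts, val)
  }
  missing <- setdiff(names(genetic_code_table()), codons)
  if (length(missing)) {
    stop("codon usage table is missing ", length(missing), " codons: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "")
  }
  codon_usage(stats::setNames(counts, codons), species = species)
}

#' Construct a codon usage object from counts
#'
#' @param counts Named numeric vector over all 64 codons (non-negative).
#' @param species Optional species label.
#' @return A \code{codon_usage} object; see \code{\link{read_codon_usage}}.
#' @export
codon_usage <- function(counts, species = NA_character_) {
  all_cod <- names(genetic_code_table())
  stopifnot(setequal(names(counts), all_cod), all(counts >= 0))
  counts <- counts[all_cod]
  sense <- sense_codons()
  tot <- sum(counts[sense])
  if (tot <= 0) stop("all sense-codon frequencies are zero")
  freq <- rep(NA_real_, 64)
  names(freq) <- all_cod
  freq[sense] <- counts[sense] / tot
  out <- data.frame(codon = all_cod, count = unname(counts),
                    frequency = unname(freq), stringsAsFactors = FALSE)
  structure(out, species = species, class = c("codon_usage", "data.frame"))
}

#' Uniform codon usage over the 61 sense codons
#'
#' @return A \code{codon_usage} with every sense codon at frequency 1/61.
#' @export
uniform_codon_usage <- function() {
  counts <- stats::setNames(rep(0, 64), names(genetic_code_table()))
  counts[sense_codons()] <- 1
  codon_usage(counts, species = "uniform")
}

# Named vector of normalized sense-codon weights.
codon_weights <- function(usage) {
  w <- stats::setNames(usage$frequency, usage$codon)
  w[sense_codons()]
}
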