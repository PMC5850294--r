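# Genetic-code enumeration and null models for the expected ti:tv ratio
# among amino-acid-changing mutations. Canonical code only (NCBI table 1),
# DNA alphabet (T, not U), uppercase codons throughout.

.titv_cache <- new.env(parent = emptyenv())

#' The canonical genetic code
#'
#' Returns the standard genetic code (NCBI translation table 1) as a named
#' character vector mapping the 64 DNA codons to one-letter amino acid codes,
#' with \code{"*"} for the three stop codons.
#'
#' @return Named character vector of length 64.
#' @export
genetic_code_table <- function() {
  if (is.null(.titv_cache$code)) {
    code <- Biostrings::GENETIC_CODE
    .titv_cache$code <- stats::setNames(as.character(code), names(code))
  }
  .titv_cache$code
}

#' Sense codons of the canonical code
#'
#' @return Character vector of the 61 non-stop codons, lexicographically
#'   sorted.
#' @export
sense_codons <- function() {
  code <- genetic_code_table()
  sort(names(code)[code != "*"])
}

#' Classify a nucleotide change as transition or transversion
#'
#' Transitions are the within-class changes A<->G (purines) and C<->T
#' (pyrimidines); the remaining eight ordered base pairs are transversions.
#' Each nucleotide site is therefore subject to one possible transition and
#' two possible transversions.
#'
#' @param from_base,to_base Character vectors of single bases in
#'   \code{A,C,G,T}. Recycled to a common length; \code{from_base} and
#'   \code{to_base} must differ elementwise.
#' @return Character vector of \code{"transition"} / \code{"transversion"}.
#' @examples
#' classify_change("A", "G")  # transition
#' classify_change("A", "C")  # transversion
#' @export
classify_change <- function(from_base, to_base) {
  n <- max(length(from_base), length(to_base))
  from_base <- rep_len(as.character(from_base), n)
  to_base <- rep_len(as.character(to_base), n)
  ok <- from_base %in% c("A", "C", "G", "T") & to_base %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    stop("bases must be one of A, C, G, T (got ",
         paste(unique(c(from_base[!ok], to_base[!ok])), collapse = ", "), ")")
  }
  if (any(from_base == to_base)) {
    stop("from_base and to_base must differ (a change, not a state)")
  }
  purine <- c("A", "G")
  same_class <- (from_base %in% purine) == (to_base %in% purine)
  ifelse(same_class, "transition", "transversion")
}

#' Enumerate all single-nucleotide changes from sense codons
#'
#' Generates the 61 x 9 = 549 ordered single-nucleotide changes away from the
#' sense codons of the canonical genetic code, classifies each as transition
#' or transversion, and labels its coding effect. Of the 549, exactly 392
#' change one amino acid to another (116 transitions, 276 transversions); the
#' rest are synonymous or create a stop codon.
#'
#' Rows are deterministically ordered by ancestral codon (lexicographic),
#' then position (1..3), then target base (lexicographic), so downstream
#' results are bit-stable.
#'
#' @return A data.frame with one row per change and columns
#'   \code{ancestral_codon}, \code{position}, \code{from_base},
#'   \code{to_base}, \code{derived_codon}, \code{ancestral_aa},
#'   \code{derived_aa}, \code{change_class} (\code{"transition"} /
#'   \code{"transversion"}), \code{coding_effect} (\code{"synonymous"},
#'   \code{"missense"}, \code{"nonsense"}).
#' @export
enumerate_single_nucleotide_mutations <- function() {
  if (!is.null(.titv_cache$enumeration)) {
    return(.titv_cache$enumeration)
  }
  code <- genetic_code_table()
  bases <- c("A", "C", "G", "T")
  cods <- sense_codons()

  # 9 changes per codon: 3 positions x 3 alternative bases
  anc_site <- rep(cods, each = 3L)
  pos_site <- rep(1:3, times = length(cods))
  from_site <- substr(anc_site, pos_site, pos_site)
  # targets: the 3 bases != from, in lexicographic order
  targets <- vapply(from_site, function(b) setdiff(bases, b), character(3))
  anc <- rep(anc_site, each = 3L)
  pos <- rep(pos_site, each = 3L)
  from <- rep(from_site, each = 3L)
  to <- as.vector(targets)

  der <- anc
  substr(der, pos, pos) <- to
  aa1 <- unname(code[anc])
  aa2 <- unname(code[der])
  effect <- ifelse(aa2 == "*", "nonsense",
                   ifelse(aa1 == aa2, "synonymous", "missense"))
  out <- data.frame(
    ancestral_codon = anc,
    position = pos,
    from_base = from,
    to_base = to,
    derived_codon = der,
    ancestral_aa = aa1,
    derived_aa = aa2,
    change_class = classify_change(from, to),
    coding_effect = effect,
    stringsAsFactors = FALSE
  )
  .titv_cache$enumeration <- out
  out
}

#' @rdname null_ratio
#' @export
null_model_ids <- function() {
  c("uniform_all", "nonsyn_unweighted", "nonsyn_usage",
    "accessible_aa", "accessible_aa_usage")
}

#' Null-model expected transition:transversion ratios
#'
#' Computes the expected ti:tv ratio among adaptive changes under five null
#' models in which the mutational class of a change is irrelevant to its
#' chance of being adaptive:
#' \describe{
#'   \item{\code{uniform_all}}{every single-nucleotide mutation equally
#'     likely: one transition vs two transversions per site, ratio exactly
#'     0.5.}
#'   \item{\code{nonsyn_unweighted}}{every amino-acid-changing mutation
#'     equally likely: 116 transitions / 276 transversions = 0.42.}
#'   \item{\code{nonsyn_usage}}{as above, each change weighted by the usage
#'     frequency of its ancestral codon.}
#'   \item{\code{accessible_aa}}{per ancestral codon (uniform weight), one of
#'     the distinct amino acids reachable by a single nucleotide change
#'     becomes advantageous, each equally likely; a destination reachable
#'     from the codon by any transition is counted as a transition
#'     (conservative), else as a transversion. Ratio \eqn{\approx} 0.49.}
#'   \item{\code{accessible_aa_usage}}{as above with codons weighted by
#'     usage.}
#' }
#'
#' @param model_id One of \code{null_model_ids()}.
#' @param usage A \code{codon_usage} object (see \code{\link{read_codon_usage}});
#'   defaults to uniform usage over the 61 sense codons. Ignored by the
#'   unweighted models.
#' @return An object of class \code{null_model_result}: a list with
#'   \code{model_id}, \code{ti_mass}, \code{tv_mass} and
#'   \code{ratio = ti_mass / tv_mass}. For \code{nonsyn_unweighted} the
#'   masses are the integer mutation counts.
#' @examples
#' null_ratio("uniform_all")$ratio        # 0.5
#' null_ratio("nonsyn_unweighted")$ratio  # 116/276 = 0.42
#' @export
null_ratio <- function(model_id, usage = NULL) {
  model_id <- match.arg(model_id, null_model_ids())
  if (is.null(usage)) usage <- uniform_codon_usage()
  stopifnot(inherits(usage, "codon_usage"))
  wts <- codon_weights(usage)

  if (model_id == "uniform_all") {
    ti <- 1; tv <- 2
  } else if (model_id %in% c("nonsyn_unweighted", "nonsyn_usage")) {
    mis <- enumerate_single_nucleotide_mutations()
    mis <- mis[mis$coding_effect == "missense", ]
    w <- if (model_id == "nonsyn_unweighted") rep(1, nrow(mis)) else wts[mis$ancestral_codon]
    ti <- sum(w[mis$change_class == "transition"])
    tv <- sum(w[mis$change_class == "transversion"])
  } else {
    mis <- enumerate_single_nucleotide_mutations()
    mis <- mis[mis$coding_effect == "missense", ]
    uniform <- model_id == "accessible_aa"
    ti <- 0; tv <- 0
    for (cod in sense_codons()) {
      sub <- mis[mis$ancestral_codon == cod, ]
      dests <- unique(sub$derived_aa)
      if (!length(dests)) next
      wc <- if (uniform) 1 / length(sense_codons()) else wts[[cod]]
      wd <- wc / length(dests)
      for (aa in dests) {
        reachable_by_ti <- any(sub$change_class[sub$derived_aa == aa] == "transition")
        if (reachable_by_ti) ti <- ti + wd else tv <- tv + wd
      }
    }
  }
  structure(
    list(model_id = model_id, ti_mass = ti, tv_mass = tv, ratio = ti / tv),
    class = "null_model_result"
  )
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("Null model '%s': ti mass %.4g, tv mass %.4g, ti:tv ratio %.4f\n",
              x$model_id, x$ti_mass, x$tv_mass, x$ratio))
  invisible(x)
}

#' All five null models at once
#'
#' @param usage Optional \code{codon_usage}; defaults to uniform.
#' @return A data.frame with one row per model: \code{model_id},
#'   \code{ti_mass}, \code{tv_mass}, \code{ratio}.
#' @export
null_model_table <- function(usage = NULL) {
  rows <- lapply(null_model_ids(), function(id) {
    r <- null_ratio(id, usage = usage)
    data.frame(model_id = r$model_id, ti_mass = r$ti_mass,
               tv_mass = r$tv_mass, ratio = r$ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Expand an IUPAC codon pattern (e.g. "CCN", "GGR") to the set of concrete
# codons it matches.
expand_codon_pattern <- function(pattern) {
  pattern <- toupper(pattern)
  if (nchar(pattern) != 3L) stop("codon pattern must have 3 letters: ", pattern)
  map <- Biostrings::IUPAC_CODE_MAP
  letters3 <- strsplit(pattern, "")[[1]]
  if (!all(letters3 %in% names(map))) {
    stop("codon pattern contains a non-IUPAC symbol: ", pattern)
  }
  sets <- lapply(letters3, function(ch) strsplit(map[[ch]], "")[[1]])
  grid <- expand.grid(sets[[1]], sets[[2]], sets[[3]], stringsAsFactors = FALSE)
  paste0(grid[[1]], grid[[2]], grid[[3]])
}

#' Infer the mutational class of an amino acid replacement
#'
#' Given an amino acid replacement, enumerates every pair of codons at
#' nucleotide Hamming distance 1 connecting the two amino acids under the
#' canonical code and reports whether the underlying nucleotide change is
#' always a transition, always a transversion, ambiguous (both kinds of
#' witness exist), or unreachable by any single nucleotide change. For
#' example, Pro to Ser is always a C to T transition in the first position of
#' a CCN codon, whereas Gly to Arg is ambiguous unless the codons are known.
#'
#' Optional IUPAC codon patterns restrict the ancestral and/or derived codons
#' considered, for the case where sequences have been consulted (e.g. Gly to
#' Arg with ancestral \code{"GGA"} and derived \code{"AGA"} is a transition).
#' Replacements needing two or more nucleotide changes are reported as
#' \code{"unreachable"}, never silently dropped, so that double-nucleotide
#' paths can be excluded explicitly from parallelism counts.
#'
#' @param from_aa,to_aa One-letter amino acid codes (distinct, not stop).
#' @param ancestral_codon,derived_codon Optional IUPAC codon patterns
#'   restricting the witnesses.
#' @return An object of class \code{replacement_classification}: a list with
#'   \code{from_aa}, \code{to_aa}, \code{verdict} (one of
#'   \code{"always_transition"}, \code{"always_transversion"},
#'   \code{"ambiguous"}, \code{"unreachable"}) and \code{witnesses}, the
#'   data.frame of codon changes realizing the replacement.
#' @examples
#' infer_replacement_class("P", "S")$verdict  # always_transition
#' infer_replacement_class("G", "R")$verdict  # ambiguous
#' infer_replacement_class("G", "R", ancestral_codon = "GGA",
#'                         derived_codon = "AGA")$verdict
#' infer_replacement_class("Q", "T")$verdict  # unreachable (2-nt change)
#' @export
infer_replacement_class <- function(from_aa, to_aa,
                                    ancestral_codon = NULL,
                                    derived_codon = NULL) {
  aas <- sort(unique(unname(genetic_code_table())))
  aas <- setdiff(aas, "*")
  from_aa <- toupper(from_aa); to_aa <- toupper(to_aa)
  if (!(from_aa %in% aas) || !(to_aa %in% aas)) {
    stop("from_aa and to_aa must be one-letter codes of the 20 amino acids")
  }
  if (from_aa == to_aa) stop("from_aa and to_aa must differ (a replacement)")

  wit <- enumerate_single_nucleotide_mutations()
  wit <- wit[wit$ancestral_aa == from_aa & wit$derived_aa == to_aa, ]
  if (!is.null(ancestral_codon)) {
    wit <- wit[wit$ancestral_codon %in% expand_codon_pattern(ancestral_codon), ]
  }
  if (!is.null(derived_codon)) {
    wit <- wit[wit$derived_codon %in% expand_codon_pattern(derived_codon), ]
  }
  has_ti <- any(wit$change_class == "transition")
  has_tv <- any(wit$change_class == "transversion")
  verdict <- if (!nrow(wit)) "unreachable"
             else if (has_ti && has_tv) "ambiguous"
             else if (has_ti) "always_transition"
             else "always_transversion"
  structure(
    list(from_aa = from_aa, to_aa = to_aa, verdict = verdict,
         witnesses = wit),
    class = "replacement_classification"
  )
}

#' @export
print.replacement_classification <- function(x, ...) {
  cat(sprintf("%s -> %s: %s (%d witness codon change%s)\n",
              x$from_aa, x$to_aa, x$verdict, nrow(x$witnesses),
              if (nrow(x$witnesses) == 1) "" else "s"))
  invisible(x)
}
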