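# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: translation goes through seqinr, tail
# probabilities through direct enumeration.

# Translate a DNA codon with seqinr (numcode 1); returns "*" for stops.
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

# Transition iff both bases are purines or both pyrimidines (bases differ).
oracle_is_transition <- function(a, b) {
  (a %in% c("A", "G")) == (b %in% c("A", "G"))
}

# All 64 codons, lexicographic.
oracle_all_codons <- function() {
  b <- c("A", "C", "G", "T")
  sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
}

# Classify an amino acid replacement by scanning every codon pair at
# nucleotide Hamming distance 1 (both codons sense), independent of the
# package's enumeration.
oracle_replacement_verdict <- function(from_aa, to_aa) {
  has_ti <- FALSE; has_tv <- FALSE
  for (c1 in oracle_all_codons()) {
    if (oracle_translate(c1) != from_aa) next
    for (pos in 1:3) {
      b1 <- substr(c1, pos, pos)
      for (b2 in setdiff(c("A", "C", "G", "T"), b1)) {
        c2 <- c1
        substr(c2, pos, pos) <- b2
        if (oracle_translate(c2) != to_aa) next
        if (oracle_is_transition(b1, b2)) has_ti <- TRUE else has_tv <- TRUE
      }
    }
  }
  if (!has_ti && !has_tv) "unreachable"
  else if (has_ti && has_tv) "ambiguous"
  else if (has_ti) "always_transition"
  else "always_transversion"
}

# Exact one-sided tail probability of the class-randomization statistic
# (event-level ti:tv ratio) by exhaustive enumeration of all 2^n class
# assignments. Ties (including Inf >= Inf) count as exceedances.
oracle_randomization_tail <- function(events, obs_ratio, p_ti) {
  n <- length(events)
  total <- sum(events)
  tail_p <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- bitwAnd(bitwShiftL(1L, 0:(n - 1)), mask) != 0L
    ti_sum <- sum(events[bits])
    stat <- ti_sum / (total - ti_sum)
    if (stat >= obs_ratio) {
      k <- sum(bits)
      tail_p <- tail_p + p_ti^k * (1 - p_ti)^(n - k)
    }
  }
  tail_p
}

# Published cutoff tables (count and ratio cells at printed rounding).
published_experimental_cutoffs <- function() {
  data.frame(
    cutoff = 2:8,
    ti_paths = c(43, 30, 26, 17, 13, 12, 10),
    tv_paths = c(20, 12, 5, 3, 3, 3, 2),
    path_ratio = c(2.2, 2.5, 5.2, 5.7, 4.3, 4.0, 5.0),
    ti_events = c(304, 278, 266, 230, 210, 204, 190),
    tv_events = c(85, 69, 48, 40, 40, 40, 33),
    event_ratio = c(3.6, 4.0, 5.5, 5.8, 5.3, 5.1, 5.8)
  )
}

published_natural_cutoffs <- function() {
  data.frame(
    cutoff = 2:8,
    ti_paths = c(28, 16, 14, 9, 6, 5, 3),
    tv_paths = c(27, 16, 12, 7, 5, 3, 1),
    path_ratio = c(1.0, 1.0, 1.2, 1.3, 1.2, 1.7, 3.0),
    ti_events = c(132, 108, 102, 82, 67, 61, 47),
    tv_events = c(99, 77, 65, 45, 35, 23, 9),
    event_ratio = c(1.3, 1.4, 1.6, 1.8, 1.9, 2.7, 5.2)
  )
}

# Build a small in-memory dataset from event-count vectors.
make_dataset <- function(ti_events, tv_events, name = "user") {
  records <- data.frame(
    case_id = "test", phenotype = "test", taxon = "test",
    target_gene = "test",
    path_label = c(sprintf("ti%d", seq_along(ti_events)),
                   sprintf("tv%d", seq_along(tv_events))),
    mutation_class = rep(c("ti", "tv"), c(length(ti_events), length(tv_events))),
    n_events = c(ti_events, tv_events),
    evidence_type = "experimental_linkage",
    stringsAsFactors = FALSE
  )
  parallelism_dataset(records, name = name)
}
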