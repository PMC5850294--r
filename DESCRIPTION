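Package: titvbias
Title: Transition:Transversion Bias in Parallel Adaptive Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether mutational bias shapes the outcome of
    adaptive evolution, using the overrepresentation of transitions among
    parallel adaptive amino acid replacements as the test statistic. Provides
    genetic-code-based null models for the expected transition:transversion
    ratio among amino-acid-changing mutations (with optional codon-usage
    weighting), curated path/event tables of experimental and natural
    parallelisms as fixtures, exact binomial tests and Clopper-Pearson ratio
    intervals for paths, path-bootstrap confidence intervals and
    randomization tests for events, cutoff and contamination sensitivity
    analyses, and an origin-fixation simulator of parallel adaptation under
    tunable transition bias for power analysis and calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
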