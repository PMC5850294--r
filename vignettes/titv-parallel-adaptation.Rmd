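---
title: "Transition bias in parallel adaptation: models, tests, and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition bias in parallel adaptation: models, tests, and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titvbias)
```

## The question and the data model

Transitions (A↔G, C↔T) arise by mutation more often than transversions in
nearly every genome studied. In origin–fixation (strong-selection,
weak-mutation) population genetics the substitution rate of a beneficial
allele is proportional to its mutation rate times its fixation probability,
so a mutational bias should propagate into *adaptive* outcomes whenever
adaptation is mutation-limited. The cleanest place to look is parallel
adaptive amino acid replacements, where recurrence plus independent
functional or genetic evidence argues that each change is a driver.

The data model distinguishes the **path** — one specific replacement, e.g.
V132M at one site — from the **events** along it: independent occurrences
in replicate populations, lineages, or species. A record must carry at
least two events to count as a parallelism; `aggregate_paths()` and
`apply_cutoff()` enforce this rule, and records with one event are storable
but never analysed. Path and event ratios answer different questions (see
the simulator section), so both are always reported.

Two fixtures transcribe the study datasets path by path: `experimental`
(five laboratory cases; 43 ti / 20 tv paths, 304 / 85 events) and `natural`
(ten cases from nature; 28 / 27 paths, 132 / 99 events). Path-level
metadata beyond class and event count is populated only where the curation
narrative names the path (the sodium-pump replacements such as Q111L or
G120R); other paths carry stable synthetic labels like `lambda_J.ti.4`,
because the source tables identify paths only by class and count. The two
aphid-clade parallels that the original curators declined to count (T797A,
N122Y — present in both a cardenolide consumer and a non-consumer) are kept
out of the `natural` fixture and shipped separately as `excluded`, with the
reason recorded, so the exclusion is transparent rather than silent.

## Null models from the genetic code

`null_ratio()` computes the expected ti:tv ratio under five readings of
"mutational class is irrelevant":

1. `uniform_all` — every single-nucleotide mutation equally likely; each
   site offers 1 transition and 2 transversions, ratio exactly 0.5.
2. `nonsyn_unweighted` — only amino-acid-changing mutations can be
   adaptive. The canonical code yields 549 single-nucleotide changes from
   sense codons, of which 392 are missense; these split 116 transitions to
   276 transversions, ratio ≈ 0.42. Stop-involving changes are excluded
   throughout — the models describe amino acid replacements, and including
   nonsense changes would not reproduce the 392-change missense space.
3. `nonsyn_usage` — as (2) with each change weighted by the usage
   frequency of its ancestral codon (CUTG-style tables via
   `read_codon_usage()`; frequencies are normalized over the 61 sense
   codons and stop codons carry no weight).
4. `accessible_aa` — an adaptation-flavoured model: for each ancestral
   codon, one of the amino acids reachable by a single nucleotide change
   becomes advantageous. Codons are weighted uniformly, destinations
   uniformly within a codon, and the ratio is the ratio of summed masses
   (not a mean of per-codon ratios), so each (codon, destination) pair is
   one adaptive opportunity. A destination reachable from the codon by
   *any* transition counts as a transition — the conservative tie-break,
   since it can only raise the expected ratio, and indeed
   `accessible_aa` ≥ `nonsyn_unweighted` always holds. Ratio ≈ 0.49.
5. `accessible_aa_usage` — (4) with usage-weighted codons.

Whether model (4) should weight codons by genomic frequency, or give extra
weight to destinations reachable from several positions, is genuinely
underdetermined; the uniform-codon, distinct-destination reading was chosen
because it treats each mutational opportunity once and reproduces the
expected ≈ 0.49 to two decimals. All models land in [0.40, 0.50] under
uniform usage, so downstream tests use the *conservative* null R₀ = 0.5:
any transition excess beyond it cannot be an artefact of the code's
structure. Real codon-usage tables move model (3) within roughly
0.39–0.43 and model (5) within 0.47–0.51; the bundled GC-rich table is
synthetic (built as codon weight 3^GC) and exists to pin the direction and
magnitude of usage effects in a regression test, not to represent any
species.

`infer_replacement_class()` supports curation: it enumerates every codon
pair at Hamming distance 1 connecting two amino acids and reports
`always_transition` / `always_transversion` / `ambiguous` / `unreachable`,
optionally restricted by IUPAC codon patterns when sequences have been
consulted. `unreachable` is an explicit verdict rather than an error or a
silent drop because double-nucleotide replacements (e.g. Gln→Thr) must be
excluded from parallel counts deliberately, with a record of why. The
verdicts are tested against a brute-force oracle that uses an independent
translation routine over all 380 ordered amino acid pairs.

## Inference conventions

All tests are one-sided "greater": the hypothesis that mutation bias
elevates transitions is directional and stated a priori. No multiplicity
correction is applied — the cutoff scan is a sensitivity display, not a
family of discoveries.

**Paths.** With per-path transition probability p₀ = R₀/(1+R₀) (= 1/3 at
the default null), `binomial_path_test()` computes the exact binomial upper
tail. The interval in `binomial_ratio_ci()` is Clopper–Pearson on the
transition proportion, mapped to the ratio scale by r = p/(1−p); with no
transversion paths the upper endpoint is +Inf, not an error. Exact
inversion was chosen over asymptotic intervals because several cutoff rows
have single-digit counts.

**Events.** Paths carry wildly unequal event counts (up to 35), so no
exact event-level analysis exists and the path is the resampling unit.
`bootstrap_event_ratio()` resamples paths with replacement 10,000 times and
takes percentile (type-1, i.e. order-statistic) quantiles — interpolation
is avoided because all-transition resamples give ratio = Inf, which must
simply sort above every finite value. `randomization_event_test()`
reassigns each path's class with probability p₀, keeps its event count,
and compares event-level ratios with the add-one convention
p = (1 + #{ratio* ≥ obs})/(n_reps + 1); ties, including Inf ≥ Inf, count as
exceedances. Both conventions are conservative, and the add-one form keeps
p ≥ 1/(n_reps+1) — a 10⁶-replicate run with no exceedance reports
p ≈ 10⁻⁶ numerically and prints `<1e-05`, since Monte-Carlo values below
10⁻⁵ are not meaningfully distinguishable at that replication. Before
resampling, records are sorted canonically (class, count, label), so
results are invariant to input row order under a fixed seed. The
randomization p-value is validated against exhaustive enumeration of all
2ⁿ class assignments on small datasets.

**Sensitivity.** `cutoff_scan()` replays the analysis for minimum
events-per-path k = 2..8; counts are monotone non-increasing and a cutoff
that empties the data yields NA ratios and p-values rather than errors.
`contamination_threshold()` answers "how much contamination would explain
the excess?" under the worst case for the mutation-bias hypothesis: every
contaminant is a transition and the genuine remainder sits exactly at the
null ratio, so genuine_tv = observed tv, genuine_ti = R₀·tv, and the rest
of the transitions are contaminants (floored at zero when the data already
sit at or below the null). `zero_count_upper_bound()` is the rule-of-three
95% bound 3/n for a zero count, capped at 1.

Every stochastic entry point takes an explicit integer seed and records it
(along with the null spec, replication counts, package version, and an md5
checksum of the canonically sorted data) in the report produced by
`analyze_dataset()`, so a JSON report fully determines its own
reproduction.

## The origin–fixation simulator

`simulate_dataset()` generates parallelism datasets under the mechanism the
analysis is designed to detect. The abstraction is deliberately minimal:
a fixed set of B_ti beneficial transitions and B_tv beneficial
transversions; each replicate population independently fixes m
substitutions drawn with probability ∝ mutation rate × selective advantage
(weight κ·s for transitions, s for transversions); mutations seen in ≥ 2
replicates become paths with n_events = number of replicates containing
them, singletons being generated but excluded exactly as in the empirical
scoring. There is no explicit population size, drift, clonal interference,
or sequence context — fixation probability is folded into the weight, which
is the defining assumption of the origin–fixation regime and the reason the
simulator can serve as a *null and alternative generator* rather than a
population-genetic study in itself.

Defaults were fixed once to describe a laboratory-style design:
96 replicates (the largest experimental case ran 96 populations), 5
substitutions per replicate, a 20/40 beneficial split (the ≈ 0.5
availability ratio implied by the code), κ = 3 (the middle of the
empirically typical 2–4-fold transition bias), equal selection
coefficients (systematic fitness assays find hardly any transition–
transversion difference; unequal s is supported to explore the
alternative), and without-replacement sampling within a replicate (a site
substitutes once, matching how parallel paths are scored; with-replacement
is available for sensitivity).

Two limiting behaviours make the path/event distinction informative, and
both are asserted in the test suite at R = 2000: as replicates accumulate,
every beneficial path is eventually seen, so the **path** ratio converges
to the availability ratio B_ti/B_tv (≈ the 0.5 null), while the **event**
ratio converges to κ·B_ti/B_tv — events, not paths, carry the mutation
bias. Consequently `estimate_kappa()` reads the fold-excess of the event
ratio over R₀ as an estimate of κ. Two caveats: weighted sampling without
replacement slightly under-samples high-weight mutations (so κ̂ is mildly
conservative for large m relative to the beneficial set), and the estimator
assumes availability at the null ratio.

What the generator does *not* emulate: the heavy-tailed empirical event
spectra (single paths with 35 events), heterogeneous per-case designs,
CpG or other context-dependent rate variation, and non-independence among
lineages in the natural data. Passing calibration and recovery tests
therefore shows the inference machinery is correct under the stated
mechanism — not that real datasets satisfy it.

## Calibration and test scale

Type-I calibration of the path test uses κ = 1 with a sparse design (200
ti / 400 tv beneficial mutations, 20 replicates × 10 substitutions), so
that included paths are approximately independent Bernoulli(1/3) draws
rather than an exhaustive census of the beneficial set; an exhaustive
design would make the binomial test degenerate-conservative (the
hypergeometric effect). Because the exact binomial test is discrete, its
realized size sits at or below the nominal α; the suite therefore compares
the empirical rejection rate against the *exact* expected size computed
per simulated dataset, within Monte-Carlo error, rather than against α
itself.

Problem sizes in the shipped tests were chosen to keep the whole suite
fast while leaving Monte-Carlo error well inside the asserted tolerances:
10,000-sample bootstraps and 10⁶-replicate randomizations where the
published precision demands them, 10⁵–2×10⁵ replicates for the cutoff-scan
p-value checks (with 3–4 standard-error bands), 400 simulations for
calibration, and 2×10⁵ replicates against the exhaustive oracle. The
`analysis/` drivers run the full-scale versions.

## Known limitations

- Only the canonical nuclear code (NCBI table 1) is supported; organelle
  codes would change every enumeration constant.
- The exact 12-species codon-usage ranges depend on external CUTG tables
  and are supported as a property of user-supplied tables, not reproduced
  from bundled data.
- The curation that produced the fixtures (parsimony reconstruction,
  inclusion judgments) is upstream of this package; the fixtures are its
  output, and the package's checks guarantee internal consistency with the
  published per-case sums, not the curation itself.
- The contamination threshold is an accounting identity under a worst-case
  assumption, not a contamination estimator.
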