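# Fixtures, TSV dialect, aggregation, and cutoff filtering.

test_that("the experimental fixture reproduces the published case and total counts", {
  d <- load_fixture("experimental")
  agg <- aggregate_paths(d)
  expect_equal(agg$ti_paths, 43)
  expect_equal(agg$tv_paths, 20)
  expect_equal(agg$ti_events, 304)
  expect_equal(agg$tv_events, 85)
  expect_equal(agg$path_ratio, 43 / 20)
  expect_equal(agg$event_ratio, 304 / 85)

  # per-case path counts and event sums (printed Sum column)
  by_case <- split(as.data.frame(d), d$case_id)
  sums <- function(case, cls) {
    r <- by_case[[case]]
    sum(r$n_events[r$mutation_class == cls])
  }
  npaths <- function(case, cls) sum(by_case[[case]]$mutation_class == cls)
  expect_equal(c(npaths("phiX174_highT", "ti"), npaths("phiX174_highT", "tv")), c(17, 8))
  expect_equal(c(sums("phiX174_highT", "ti"), sums("phiX174_highT", "tv")), c(49, 23))
  expect_equal(c(npaths("lambda_J", "ti"), npaths("lambda_J", "tv")), c(16, 6))
  expect_equal(c(sums("lambda_J", "ti"), sums("lambda_J", "tv")), c(181, 42))
  expect_equal(c(npaths("paeruginosa_rif", "ti"), npaths("paeruginosa_rif", "tv")), c(7, 4))
  expect_equal(c(sums("paeruginosa_rif", "ti"), sums("paeruginosa_rif", "tv")), c(61, 11))
  expect_equal(c(npaths("phiX174_fitness", "ti"), sums("phiX174_fitness", "ti")), c(3, 13))
  expect_equal(c(npaths("ecoli_kntase", "tv"), sums("ecoli_kntase", "tv")), c(2, 9))
  # rifampicin transition event counts as printed
  rif <- by_case[["paeruginosa_rif"]]
  expect_setequal(rif$n_events[rif$mutation_class == "ti"], c(4, 35, 2, 5, 2, 4, 9))
})

test_that("the natural fixture reproduces the published case and total counts", {
  d <- load_fixture("natural")
  agg <- aggregate_paths(d)
  expect_equal(c(agg$ti_paths, agg$tv_paths), c(28, 27))
  expect_equal(c(agg$ti_events, agg$tv_events), c(132, 99))

  per_case <- aggregate(n_events ~ case_id + mutation_class,
                        data = as.data.frame(d), FUN = sum)
  get <- function(case, cls) {
    v <- per_case$n_events[per_case$case_id == case & per_case$mutation_class == cls]
    if (length(v)) v else 0L
  }
  published <- list(  # case -> c(ti_events, tv_events)
    insecticide = c(14, 15), tetrodotoxin = c(11, 12), glycoside = c(12, 15),
    herbicide = c(7, 18), altitude = c(17, 7), vision = c(7, 12),
    echolocation = c(6, 5), ritonavir = c(41, 4), ribonuclease = c(10, 0),
    benzimidazole = c(7, 11))
  for (case in names(published)) {
    expect_equal(c(get(case, "ti"), get(case, "tv")), published[[case]],
                 label = case)
  }
  # named sodium-pump paths carried through from the curation
  gly <- as.data.frame(d)[d$case_id == "glycoside", ]
  expect_setequal(gly$path_label,
                  c("G120R", "Q111R", "I315V", "N122D",
                    "Q111L", "L111V", "P118A", "N122H"))
  expect_equal(gly$n_events[gly$path_label == "Q111L"], 7)
})

test_that("the excluded aphid parallels live in their own fixture with a reason", {
  d <- load_fixture("excluded")
  expect_equal(nrow(d), 2)
  expect_setequal(d$path_label, c("T797A", "N122Y"))
  expect_equal(d$mutation_class[d$path_label == "T797A"], "ti")
  expect_equal(d$mutation_class[d$path_label == "N122Y"], "tv")
  expect_true("reason" %in% names(d))
  expect_match(d$reason[1], "not counted")
  # they are absent from the analyzed natural fixture
  expect_false(any(c("T797A", "N122Y") %in% load_fixture("natural")$path_label))
})

test_that("paths TSV round-trips and preserves unknown columns", {
  d <- load_fixture("experimental")
  tmp <- tempfile(fileext = ".tsv")
  write_paths_tsv(d, tmp)
  d2 <- read_paths_tsv(tmp, name = "experimental")
  expect_equal(as.data.frame(d2), as.data.frame(d))
  expect_equal(aggregate_paths(d2), aggregate_paths(d))

  exc <- load_fixture("excluded")  # carries the extra `reason` column
  write_paths_tsv(exc, tmp)
  expect_true("reason" %in% names(read_paths_tsv(tmp)))
})

test_that("malformed paths TSVs fail with the offending line", {
  d <- as.data.frame(load_fixture("natural"))
  write_tsv <- function(df) {
    tmp <- tempfile(fileext = ".tsv")
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    tmp
  }
  bad <- d; bad$n_events[3] <- 0
  expect_error(read_paths_tsv(write_tsv(bad)), "line 4.*n_events")
  bad <- d; bad$mutation_class[1] <- "transversion"
  expect_error(read_paths_tsv(write_tsv(bad)), "line 2.*mutation_class")
  expect_error(read_paths_tsv(write_tsv(d[, -6])), "missing required column")
  # header-only file is a valid empty dataset
  empty <- read_paths_tsv(write_tsv(d[0, ]))
  expect_equal(nrow(empty), 0)
  expect_error(read_paths_tsv(tempfile()), "not found")
})

test_that("cutoff filtering is monotone and k = 2 is the identity on fixtures", {
  for (name in c("experimental", "natural")) {
    d <- load_fixture(name)
    expect_equal(as.data.frame(apply_cutoff(d, 2)), as.data.frame(d))
    prev <- aggregate_paths(d)
    for (k in 3:9) {
      agg <- aggregate_paths(apply_cutoff(d, k))
      expect_lte(agg$ti_paths, prev$ti_paths)
      expect_lte(agg$tv_paths, prev$tv_paths)
      expect_lte(agg$ti_events, prev$ti_events)
      expect_lte(agg$tv_events, prev$tv_events)
      prev <- agg
    }
  }
  expect_error(apply_cutoff(load_fixture("natural"), 1), ">= 2")
})

test_that("singleton records are storable but excluded from aggregation", {
  d <- make_dataset(c(3, 1), c(2, 1))
  agg <- aggregate_paths(d)
  expect_equal(c(agg$ti_paths, agg$tv_paths), c(1, 1))
  expect_equal(c(agg$ti_events, agg$tv_events), c(3, 2))
})

test_that("ratios use Inf for empty denominators, never an error", {
  agg <- aggregate_paths(make_dataset(c(2, 3), integer(0)))
  expect_identical(agg$event_ratio, Inf)
  expect_identical(agg$path_ratio, Inf)
})
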