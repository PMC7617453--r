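test_that("peptide evidence is assigned to species with parent sets", {
  lib <- toy_library(
    host_proteins = list(m1 = 1:3),
    graft_proteins = list(h1 = c(3, 5, 6))
  )
  asn <- assign_peptides(toy_evidence(c(1, 2)), lib)
  expect_true(all(asn$class == "unique_to_mouse"))

  asn2 <- assign_peptides(toy_evidence(3), lib)
  expect_equal(asn2$class, "shared")
  par <- attr(asn2, "parents")
  expect_setequal(par$species, c("mouse", "human"))

  expect_warning(
    asn3 <- assign_peptides(tibble::tibble(peptide = "GGGGGGG", intensity = 1), lib),
    "no observed peptide matched"
  )
  expect_equal(asn3$class, "unmatched")
  expect_equal(attr(asn3, "unmatched_fraction"), 1)
})

test_that("species classification follows the strict and relaxed rules", {
  lib <- toy_library(
    host_proteins = list(m1 = 1:2, m2 = c(3, 4)),
    graft_proteins = list(h1 = c(4, 8, 9))
  )
  # m1: two host-unique peptides -> host_exclusive
  # m2: one host-unique + one shared -> conserved
  # h1: shared + graft-unique -> conserved
  asn <- assign_peptides(toy_evidence(c(1, 2, 3, 4, 8, 9)), lib)
  calls <- classify_proteins(asn, host = "mouse")
  got <- setNames(calls$species_class, calls$group_id)
  expect_equal(got[["m1"]], "host_exclusive")
  expect_equal(got[["m2"]], "conserved")
  expect_equal(got[["h1"]], "conserved")

  relaxed <- classify_proteins(asn, host = "mouse", mode = "relaxed")
  gotr <- setNames(relaxed$species_class, relaxed$group_id)
  expect_equal(gotr[["m2"]], "host_exclusive")
  expect_equal(gotr[["h1"]], "graft_exclusive")

  expect_error(classify_proteins(asn, host = "mouse", min_peptides = 0), ">= 1")
  expect_error(classify_proteins(asn, host = "rat"), "library tags")
})

test_that("nested peptide sets collapse into one parsimony group", {
  lib <- toy_library(
    host_proteins = list(big = 1:4, small = 2:3),
    graft_proteins = list(h1 = 10:11)
  )
  asn <- assign_peptides(toy_evidence(1:4), lib)
  calls <- classify_proteins(asn, host = "mouse")
  expect_equal(calls$group_id, "big")
  expect_equal(calls$members[[1]], "small")
})

test_that("greedy grouping matches exhaustive minimal set cover on small instances", {
  withr::with_seed(21, {
    for (rep in 1:30) {
      n_prot <- sample(3:8, 1)
      n_pep <- sample(4:10, 1)
      sets <- lapply(seq_len(n_prot), function(i) {
        unique(sample(paste0("pep", seq_len(n_pep)), sample(1:4, 1)))
      })
      names(sets) <- paste0("prot", seq_len(n_prot))
      inc_el <- unlist(sets, use.names = FALSE)
      inc_set <- rep(names(sets), lengths(sets))
      greedy <- xenoprot:::greedy_set_cover(inc_el, inc_set)
      # covers everything, at the exhaustive minimum size
      expect_true(all(inc_el %in% unlist(sets[greedy])))
      expect_equal(length(greedy), oracle_min_cover_size(sets))
    }
  })
})

test_that("iBAQ follows its defining ratios and normalization", {
  lib <- toy_library(
    host_proteins = list(m1 = 1:4),
    graft_proteins = list(h1 = 5:6, h2 = 7:10)
  )
  # m1: 4 expected peptides, summed intensity 400 -> iBAQ 100
  ev <- dplyr::bind_rows(
    toy_evidence(1:4, intensity = 100),
    toy_evidence(5:6, intensity = c(150, 50)), # h1: 200 / 2 = 100
    toy_evidence(7:10, intensity = 200) # h2: 800 / 4 = 200
  )
  asn <- assign_peptides(ev, lib)
  calls <- classify_proteins(asn, host = "mouse")
  q <- quantify_ibaq(calls, asn, lib)
  got <- setNames(q$iBAQ, q$group_id)
  expect_equal(got[["m1"]], 100)
  expect_equal(got[["h1"]], 100)
  expect_equal(got[["h2"]], 200)
  # 1:1:2 -> ppm 250k / 250k / 500k, and ppm sums to 1e6
  ppm <- setNames(q$iBAQ_ppm, q$group_id)
  expect_equal(ppm[["m1"]], 250000)
  expect_equal(ppm[["h2"]], 500000)
  expect_equal(sum(q$iBAQ_ppm), 1e6, tolerance = 1e-9)
  expect_equal(q$obs_exp_ratio, rep(1, 3))

  # single quantified protein: ppm = 1e6, score = 6
  asn1 <- assign_peptides(toy_evidence(1:4, 25), lib)
  q1 <- quantify_ibaq(classify_proteins(asn1, host = "mouse"), asn1, lib)
  expect_equal(q1$iBAQ_ppm, 1e6)
  expect_equal(q1$iBAQ_score, 6)
})

test_that("quantities and enrichment calls are invariant to intensity scaling", {
  lib <- toy_library(
    host_proteins = list(m1 = 1:3, m2 = 4:7, m3 = 8:12),
    graft_proteins = list(h1 = 13:17, h2 = 18:20)
  )
  withr::with_seed(3, {
    ev <- toy_evidence(1:20, intensity = stats::runif(20, 10, 1000))
  })
  run <- function(evidence) {
    asn <- assign_peptides(evidence, lib)
    call_enriched(quantify_ibaq(classify_proteins(asn, host = "mouse"), asn, lib))
  }
  base <- run(ev)
  scaled <- run(dplyr::mutate(ev, intensity = intensity * 737.3))
  expect_equal(scaled$iBAQ_ppm, base$iBAQ_ppm, tolerance = 1e-12)
  expect_equal(rank(scaled$iBAQ_score), rank(base$iBAQ_score))
  expect_equal(scaled$obs_exp_ratio, base$obs_exp_ratio)
  expect_equal(scaled$enriched, base$enriched)
})

test_that("enrichment needs both metrics strictly above the class means", {
  lib <- toy_library(
    host_proteins = list(m1 = 1:2),
    graft_proteins = list(h1 = 3:6, h2 = 7:10, h3 = 11:14)
  )
  # h1 dominates both metrics: all 4 peptides seen at high intensity;
  # h2 and h3 each seen with 2 of 4 peptides at low intensity
  ev <- dplyr::bind_rows(
    toy_evidence(1:2, 50),
    toy_evidence(3:6, 1000),
    toy_evidence(7:8, 10),
    toy_evidence(11:12, 10)
  )
  asn <- assign_peptides(ev, lib)
  q <- quantify_ibaq(classify_proteins(asn, host = "mouse"), asn, lib)
  e <- call_enriched(q)
  graft <- tibble::as_tibble(e)[e$species_class == "graft_exclusive", ]
  expect_equal(graft$enriched, c(TRUE, FALSE, FALSE))

  # degenerate class of one protein: enrichment undefined
  host <- tibble::as_tibble(e)[e$species_class == "host_exclusive", ]
  expect_true(is.na(host$enriched))
  thr <- enrichment_thresholds(e)
  expect_false(thr$defined[thr$species_class == "host_exclusive"])
})

test_that("category composition and marker overlap count as expected", {
  calls <- tibble::tibble(
    group_id = sprintf("P%02d", 1:14),
    species = "mouse", species_class = "host_exclusive",
    enriched = c(rep(TRUE, 12), FALSE, NA)
  )
  class(calls) <- c("protein_calls", class(calls))
  cmap <- tibble::tibble(
    protein_id = sprintf("P%02d", 1:5),
    category = "translation"
  )
  comp <- category_composition(calls, cmap)
  expect_equal(comp$percent[comp$category == "translation"], 100 * 5 / 12,
    tolerance = 1e-10
  )
  expect_equal(comp$n[comp$category == "other"], 7L)
  expect_equal(sum(comp$percent), 100)

  none <- category_composition(dplyr::mutate(calls, enriched = FALSE), cmap)
  expect_equal(nrow(none), 0)

  expect_equal(marker_overlap(c("A", "B", "C"), c("a", "b"))$n_detected, 2)
  expect_equal(marker_overlap(c("A"), c("x", "y"))$n_detected, 0)
  expect_equal(marker_overlap(c("A"), c("x", "y"))$missing, c("x", "y"))
  det <- c(sprintf("M%03d", 1:93), sprintf("X%03d", 1:50))
  res <- marker_overlap(det, sprintf("M%03d", 1:100))
  expect_equal(res$n_detected, 93)
  expect_length(res$missing, 7)
})
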