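# Small-scale configuration used throughout: full study-scale generation is
# exercised by the acceptance suite.
small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(
      seed = seed, n_conserved = 40, n_host_specific = 10,
      n_graft_specific = 10, n_transferred = 2
    ),
    list(...)
  )
  do.call(sim_config, args)
}

test_that("every generator is a pure function of its configuration", {
  cfg <- small_cfg(seed = 9)
  expect_identical(make_proteomes(cfg), make_proteomes(cfg))
  pr <- make_proteomes(cfg)
  lib <- build_peptide_libraries(pr$proteome_host, pr$proteome_graft)
  expect_identical(
    simulate_xenograft(cfg, pr, lib),
    simulate_xenograft(cfg, pr, lib)
  )
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
  expect_identical(simulate_points(cfg), simulate_points(cfg))
  # and a different seed changes the draw
  expect_false(identical(
    simulate_counts(cfg),
    simulate_counts(cfg, seed = 10)
  ))
  # byte-identical FASTA from the same seed
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_proteome_fasta(make_proteomes(cfg)$proteome_host, f1)
  write_proteome_fasta(make_proteomes(cfg)$proteome_host, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("substitution-rate limits behave as expected", {
  pr0 <- make_proteomes(small_cfg(seed = 2, substitution_rate = 0))
  expect_identical(
    pr0$proteome_host$sequence[1:40],
    pr0$proteome_graft$sequence[1:40]
  )
  lib0 <- build_peptide_libraries(pr0$proteome_host, pr0$proteome_graft)
  # unique peptides can only descend from species-specific proteins
  uniq <- lib0$peptides$il_key[lib0$peptides$species_class != "shared"]
  par <- lib0$parents[lib0$parents$il_key %in% uniq, ]
  expect_true(all(grepl("^[HG]", par$protein_id)))

  pr1 <- make_proteomes(small_cfg(seed = 2, substitution_rate = 1))
  lib1 <- build_peptide_libraries(pr1$proteome_host, pr1$proteome_graft)
  # essentially no shared peptides between the fully diverged orthologs;
  # chance collisions are confined to sub-observable short fragments
  obs <- lib1$peptides[lib1$peptides$observable, ]
  expect_lt(mean(obs$species_class == "shared"), 0.005)
})

test_that("generator summary statistics match the configured values", {
  cfg <- sim_config(seed = 4, n_conserved = 300, n_host_specific = 0, n_graft_specific = 0)
  pr <- make_proteomes(cfg)
  # log-normal length: E[len] = 350 * exp(0.35^2 / 2)
  expect_equal(mean(nchar(pr$proteome_graft$sequence)), 350 * exp(0.35^2 / 2),
    tolerance = 0.05
  )
  # realized substitution fraction ~ substitution_rate
  sub_frac <- mean(mapply(function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, pr$proteome_graft$sequence, pr$proteome_host$sequence))
  expect_equal(sub_frac, 0.12, tolerance = 0.05)
})

test_that("the noiseless xenograft recovers iBAQ proportional to true abundance", {
  cfg <- small_cfg(
    seed = 5,
    intensity_cv = 1e-12, detection_slope = 400,
    detection_midpoint = 1e-8, host_background_fraction = 0.05
  )
  pr <- make_proteomes(cfg)
  lib <- build_peptide_libraries(pr$proteome_host, pr$proteome_graft)
  sim <- simulate_xenograft(cfg, pr, lib)
  asn <- assign_peptides(sim$evidence, lib)
  calls <- classify_proteins(asn, host = "mouse", min_peptides = 1)
  q <- quantify_ibaq(calls, asn, lib)
  truth <- sim$truth
  merged <- dplyr::inner_join(
    tibble::as_tibble(q)[q$quantifiable, c("group_id", "iBAQ")],
    truth[truth$present, c("protein_id", "abundance")],
    by = c(group_id = "protein_id")
  )
  # ortholog pairs share peptide intensity; species-specific proteins are exact
  spec <- merged[grepl("^[HG]", merged$group_id), ]
  expect_gt(nrow(spec), 5)
  expect_equal(spec$iBAQ, spec$abundance, tolerance = 1e-6)
})

test_that("transfer planting respects its bounds and ground truth", {
  cfg <- small_cfg(seed = 6)
  pr <- make_proteomes(cfg)
  lib <- build_peptide_libraries(pr$proteome_host, pr$proteome_graft)
  sim <- simulate_xenograft(cfg, pr, lib)
  expect_equal(sum(sim$truth$transferred), 2)
  med <- median(sim$truth$abundance[sim$truth$species == "human"])
  expect_equal(
    sort(unique(sim$truth$abundance[sim$truth$transferred])),
    8 * med
  )
  expect_error(
    simulate_xenograft(small_cfg(seed = 1, n_transferred = 99), pr, lib),
    "host-specific protein pool"
  )
  # a pure-graft control contributes no host material at all
  ctrl <- small_cfg(seed = 6, n_transferred = 0, host_background_fraction = 0)
  sim0 <- simulate_xenograft(ctrl, pr, lib)
  expect_equal(sum(sim0$truth$present[sim0$truth$species == "mouse"]), 0)
})

test_that("spectral-count simulation plants the stated effects and missingness pattern", {
  cfg <- sim_config(
    seed = 7, counts_n_proteins = 500,
    counts_effect_fraction = 0.1, counts_effect_log2fc = 2
  )
  sim <- simulate_counts(cfg)
  expect_equal(dim(sim$counts), c(500, 6))
  expect_equal(sum(sim$truth$effect), 50)
  expect_setequal(unique(abs(sim$truth$true_log2fc[sim$truth$effect])), 2)
  # missingness concentrates in low-abundance proteins
  zero_rate <- rowMeans(sim$counts == 0)
  lowhalf <- sim$truth$baseline_mean <= median(sim$truth$baseline_mean)
  expect_gt(mean(zero_rate[lowhalf]), mean(zero_rate[!lowhalf]))
})

test_that("attraction pulls query cells toward references; CSR does not", {
  shifts <- vapply(1:5, function(s) {
    sim <- simulate_points(sim_config(seed = s, attraction_scale = 25))
    dq <- nn_distances(sim$points, "query", "reference")$distance
    db <- nn_distances(sim$points, "background", "reference")$distance
    median(dq) - median(db)
  }, numeric(1))
  expect_true(all(shifts < 0))

  sim0 <- simulate_points(sim_config(seed = 3, attraction_scale = Inf))
  r <- proximity_test(sim0$points, n_perm = 399, seed = 3)
  expect_gt(r$ks$p_permutation, 0.01)
})
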