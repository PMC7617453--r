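test_that("identical proteomes under different tags yield no unique peptides", {
  withr::with_seed(1, {
    seqs <- replicate(5, random_aa_seq(80))
  })
  pa <- tibble::tibble(species = "mouse", protein_id = paste0("m", 1:5), sequence = seqs)
  pb <- tibble::tibble(species = "human", protein_id = paste0("h", 1:5), sequence = seqs)
  lib <- build_peptide_libraries(pa, pb)
  expect_true(all(lib$peptides$species_class == "shared"))
})

test_that("a single substitution makes exactly the overlapping peptides unique", {
  base <- "MAEFLDTKGVWSTPEKLLNHEAYR"
  mut <- base
  substr(mut, 11, 11) <- "Q" # inside the second tryptic peptide GVWSTPEK
  pa <- tibble::tibble(species = "mouse", protein_id = "m1", sequence = base)
  pb <- tibble::tibble(species = "human", protein_id = "h1", sequence = mut)
  lib <- build_peptide_libraries(pa, pb, max_missed = 2)

  dig_a <- xenoprot:::il_collapse(oracle_digest(base, 2)$peptide)
  dig_b <- xenoprot:::il_collapse(oracle_digest(mut, 2)$peptide)
  expect_setequal(
    lib$peptides$il_key[lib$peptides$species_class == "unique_to_mouse"],
    setdiff(dig_a, dig_b)
  )
  expect_setequal(
    lib$peptides$il_key[lib$peptides$species_class == "unique_to_human"],
    setdiff(dig_b, dig_a)
  )
  expect_setequal(
    lib$peptides$il_key[lib$peptides$species_class == "shared"],
    intersect(dig_a, dig_b)
  )
  # and the unique ones are exactly those covering the substituted position
  ov <- oracle_digest(base, 2)
  expect_setequal(
    lib$peptides$il_key[lib$peptides$species_class == "unique_to_mouse"],
    unique(xenoprot:::il_collapse(ov$peptide[ov$start <= 11 & ov$end >= 11]))
  )
})

test_that("peptides differing only by I/L are shared", {
  pa <- tibble::tibble(species = "mouse", protein_id = "m1", sequence = "IGK")
  pb <- tibble::tibble(species = "human", protein_id = "h1", sequence = "LGK")
  lib <- build_peptide_libraries(pa, pb)
  expect_equal(lib$peptides$species_class, "shared")
  expect_equal(sort(lib$parents$species), c("human", "mouse"))
})

test_that("unique-class peptides never occur in the other species' digest", {
  withr::with_seed(5, {
    pa <- tibble::tibble(
      species = "mouse", protein_id = paste0("m", 1:10),
      sequence = replicate(10, random_aa_seq(sample(40:90, 1)))
    )
    pb <- tibble::tibble(
      species = "human", protein_id = paste0("h", 1:10),
      sequence = replicate(10, random_aa_seq(sample(40:90, 1)))
    )
  })
  lib <- build_peptide_libraries(pa, pb, max_missed = 2)
  dig_b <- unique(unlist(lapply(pb$sequence, function(s) {
    xenoprot:::il_collapse(oracle_digest(s, 2)$peptide)
  })))
  dig_a <- unique(unlist(lapply(pa$sequence, function(s) {
    xenoprot:::il_collapse(oracle_digest(s, 2)$peptide)
  })))
  ua <- lib$peptides$il_key[lib$peptides$species_class == "unique_to_mouse"]
  ub <- lib$peptides$il_key[lib$peptides$species_class == "unique_to_human"]
  expect_false(any(ua %in% dig_b))
  expect_false(any(ub %in% dig_a))
  expect_setequal(lib$peptides$il_key, union(dig_a, dig_b))
})

test_that("observable peptide counts follow the window filter", {
  lib <- toy_library(
    host_proteins = list(m1 = 1:4),
    graft_proteins = list(h1 = 5:6)
  )
  expect_equal(count_observable_peptides(lib, "m1"), 4L)
  expect_equal(count_observable_peptides(lib, "h1"), 2L)
  expect_error(count_observable_peptides(lib, "nope"), "unknown")

  # all peptides below the length window: zero observable, non-quantifiable
  pa <- tibble::tibble(species = "mouse", protein_id = "m1", sequence = "AAKGGKCCK")
  pb <- tibble::tibble(species = "human", protein_id = "h1", sequence = make_protein(1:2))
  lib2 <- build_peptide_libraries(pa, pb)
  expect_equal(count_observable_peptides(lib2, "m1"), 0L)

  # toy windows: count equals a brute-force filter of the digest
  withr::with_seed(9, s <- random_aa_seq(120))
  pa <- tibble::tibble(species = "mouse", protein_id = "m1", sequence = s)
  lib3 <- build_peptide_libraries(pa, pb,
    length_window = c(5, 12),
    mass_window = c(500, 1500)
  )
  d <- oracle_digest(s, 0)
  keys <- unique(xenoprot:::il_collapse(d$peptide))
  masses <- vapply(keys, function(k) {
    sum(xenoprot:::AA_MONO_MASS[strsplit(k, "")[[1]]]) + 18.0105646863
  }, numeric(1))
  want <- sum(nchar(keys) >= 5 & nchar(keys) <= 12 & masses >= 500 & masses <= 1500)
  expect_equal(count_observable_peptides(lib3, "m1"), want)
})

test_that("library export and import round-trip", {
  lib <- toy_library(
    host_proteins = list(m1 = 1:3, m2 = c(3, 7)),
    graft_proteins = list(h1 = c(2, 9), h2 = 10:12)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_library(lib, path)
  back <- read_peptide_library(path)
  expect_equal(back$peptides$il_key, lib$peptides$il_key)
  expect_equal(back$peptides$species_class, lib$peptides$species_class)
  expect_equal(back$peptides$observable, lib$peptides$observable)
  expect_equal(back$peptides$mass, lib$peptides$mass, tolerance = 1e-5)
  expect_equal(
    dplyr::arrange(back$parents, il_key, species, protein_id),
    dplyr::arrange(lib$parents, il_key, species, protein_id)
  )
  expect_equal(back$params$max_missed, lib$params$max_missed)
  expect_equal(
    count_observable_peptides(back, c("m1", "m2", "h1", "h2")),
    count_observable_peptides(lib, c("m1", "m2", "h1", "h2"))
  )
})

test_that("degenerate inputs are rejected", {
  pa <- tibble::tibble(species = "mouse", protein_id = "m1", sequence = "AAKAAR")
  expect_error(build_peptide_libraries(pa, pa), "distinct species tags")
  empty <- pa[0, ]
  expect_error(build_peptide_libraries(pa, empty), "empty")
  bad <- tibble::tibble(species = "human", protein_id = "h1", sequence = "AABKAA")
  expect_error(build_peptide_libraries(pa, bad), "invalid residue 'B' at position 3")
  lib <- build_peptide_libraries(pa, bad, on_invalid = "skip_peptide")
  expect_false(any(grepl("B", lib$peptides$il_key)))
})
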