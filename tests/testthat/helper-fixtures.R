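# Designed toy peptides/proteins for deconvolution unit tests.
#
# make_peptide(i) yields distinct 7-residue tryptic peptides ("XXXXXX" + K)
# whose mass falls inside the default 700-4600 Da observability window and
# whose body contains no K/R/I (so digestion and I/L collapse are trivial).

TOY_RESIDUES <- c("L", "V", "F", "E", "M", "H", "W")

make_peptide <- function(i) {
  stopifnot(i >= 1, i <= 7^6)
  digits <- integer(6)
  x <- i - 1
  for (d in 1:6) {
    digits[d] <- x %% 7
    x <- x %/% 7
  }
  paste0(paste(TOY_RESIDUES[digits + 1], collapse = ""), "K")
}

# A protein made of the given toy peptides, in order.
make_protein <- function(pep_ids) {
  paste(vapply(pep_ids, make_peptide, character(1)), collapse = "")
}

# Build a two-species toy library from named lists of peptide-id vectors.
toy_library <- function(host_proteins, graft_proteins, ...) {
  ph <- tibble::tibble(
    species = "mouse",
    protein_id = names(host_proteins),
    sequence = vapply(host_proteins, make_protein, character(1))
  )
  pg <- tibble::tibble(
    species = "human",
    protein_id = names(graft_proteins),
    sequence = vapply(graft_proteins, make_protein, character(1))
  )
  build_peptide_libraries(ph, pg, ...)
}

toy_evidence <- function(pep_ids, intensity = 100) {
  tibble::tibble(
    peptide = vapply(pep_ids, make_peptide, character(1)),
    intensity = rep_len(intensity, length(pep_ids))
  )
}
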