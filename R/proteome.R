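#' Read a proteome from a FASTA file
#'
#' Reads protein sequences with [Biostrings::readAAStringSet()] and returns the
#' tidy proteome table used throughout the package. Accessions are parsed from
#' UniProt-style headers: the token between the first two `|` when present,
#' otherwise the first whitespace-delimited token.
#'
#' @param path Path to a (possibly gzipped) protein FASTA file.
#' @param species Short species tag attached to every entry (e.g. `"human"`).
#'
#' @return A tibble with columns `species`, `protein_id`, `sequence`.
#' @export
read_proteome_fasta <- function(path, species) {
  stopifnot(is.character(species), length(species) == 1, nzchar(species))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) {
    rlang::abort(sprintf("no sequences found in '%s'", path))
  }
  ids <- parse_fasta_accession(names(aa))
  out <- tibble::tibble(
    species = species,
    protein_id = ids,
    sequence = as.character(aa)
  )
  validate_proteome(out)
  out
}

parse_fasta_accession <- function(headers) {
  has_pipe <- stringr::str_detect(headers, stringr::fixed("|"))
  acc <- stringr::str_extract(headers, "^[^\\s]+")
  piped <- stringr::str_match(headers, "^[^|]*\\|([^|\\s]+)\\|")[, 2]
  ifelse(has_pipe & !is.na(piped), piped, acc)
}

#' Write a proteome table to FASTA
#'
#' @param proteome Tibble with `protein_id` and `sequence` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- proteome$protein_id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

validate_proteome <- function(proteome, arg = "proteome") {
  req <- c("species", "protein_id", "sequence")
  missing_cols <- setdiff(req, names(proteome))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf(
      "`%s` lacks column(s): %s", arg, paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(proteome) == 0) {
    rlang::abort(sprintf("`%s` is empty", arg))
  }
  if (anyDuplicated(proteome$protein_id)) {
    dup <- proteome$protein_id[duplicated(proteome$protein_id)][1]
    rlang::abort(sprintf("duplicate protein_id in `%s`: '%s'", arg, dup))
  }
  if (any(!nzchar(proteome$sequence))) {
    rlang::abort(sprintf("`%s` contains empty sequences", arg))
  }
  invisible(proteome)
}

# Report the first invalid residue across a proteome (NULL if clean).
first_invalid_residue <- function(proteome) {
  pat <- sprintf("[^%s]", paste(AA_ALPHABET, collapse = ""))
  hit <- stringr::str_locate(toupper(proteome$sequence), pat)[, 1]
  i <- which(!is.na(hit))[1]
  if (is.na(i)) {
    return(NULL)
  }
  list(
    protein_id = proteome$protein_id[i], position = hit[i],
    residue = substr(toupper(proteome$sequence[i]), hit[i], hit[i])
  )
}
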