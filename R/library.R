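#' Build species-unique peptide libraries from two proteomes
#'
#' Digests both proteomes in silico, collapses I/L (isobaric), indexes every
#' peptide with all of its parent proteins from both species, and classifies
#' each peptide as unique to one species or shared. Uniqueness is evaluated
#' over the union of all missed-cleavage variants (0..`max_missed`) of both
#' proteomes, so a peptide unique at 0 missed cleavages cannot collide with a
#' missed-cleavage peptide of the other species. A peptide is *observable*
#' when its length and monoisotopic mass fall inside the configured windows;
#' observable fully cleaved peptides are the iBAQ denominator.
#'
#' @param proteome_a,proteome_b Proteome tibbles (`species`, `protein_id`,
#'   `sequence`) with distinct species tags, e.g. from [read_proteome_fasta()].
#' @param max_missed Maximum missed cleavage sites (default 2).
#' @param length_window Observable peptide length window in residues,
#'   default `c(7, 30)`.
#' @param mass_window Observable monoisotopic mass window in Da,
#'   default `c(700, 4600)`.
#' @param rule Cleavage rule passed to the digestion engine.
#' @param on_invalid Policy for residues outside the 20-letter alphabet:
#'   `"error"` (default, reports protein and position) or `"skip_peptide"`.
#'
#' @return A `peptide_library` object: a list with
#'   * `peptides`: tibble keyed by `il_key` with `sequence` (an example
#'     original sequence), `length`, `mass`, `species_class`
#'     (`unique_to_<tag>` or `"shared"`), `observable`, `min_missed`;
#'   * `parents`: long tibble (`il_key`, `species`, `protein_id`, `n_missed`)
#'     with the minimal missed-cleavage count per parent;
#'   * `proteins`: per-protein observable fully cleaved peptide counts
#'     (the iBAQ/expected-count denominators);
#'   * `params`: the configuration used.
#' @export
build_peptide_libraries <- function(proteome_a, proteome_b, max_missed = 2,
                                    length_window = c(7, 30),
                                    mass_window = c(700, 4600),
                                    rule = c("trypsin", "trypsin/P"),
                                    on_invalid = c("error", "skip_peptide")) {
  rule <- match.arg(rule)
  on_invalid <- match.arg(on_invalid)
  validate_proteome(proteome_a, "proteome_a")
  validate_proteome(proteome_b, "proteome_b")
  tag_a <- unique(proteome_a$species)
  tag_b <- unique(proteome_b$species)
  if (length(tag_a) != 1 || length(tag_b) != 1) {
    rlang::abort("each proteome must carry a single species tag")
  }
  if (identical(tag_a, tag_b)) {
    rlang::abort("proteomes must have distinct species tags")
  }
  for (p in list(proteome_a, proteome_b)) {
    bad <- first_invalid_residue(p)
    if (!is.null(bad) && on_invalid == "error") {
      rlang::abort(sprintf(
        "invalid residue '%s' at position %d of protein '%s'",
        bad$residue, bad$position, bad$protein_id
      ))
    }
  }

  dig <- dplyr::bind_rows(
    digest_proteome(proteome_a, max_missed, rule),
    digest_proteome(proteome_b, max_missed, rule)
  )
  if (on_invalid == "skip_peptide") {
    pat <- sprintf("[^%s]", paste(AA_ALPHABET, collapse = ""))
    dig <- dig[!stringr::str_detect(dig$peptide, pat), , drop = FALSE]
    if (nrow(dig) == 0) rlang::abort("no valid peptides left after skipping")
  }
  dig$il_key <- il_collapse(dig$peptide)

  # data.table keyed aggregation: the digest of two mammalian-scale proteomes
  # runs to millions of rows, far past what per-group dplyr closures handle
  dt <- data.table::as.data.table(dig)
  parents_dt <- dt[, list(n_missed = min(n_missed)),
    keyby = c("il_key", "species", "protein_id")
  ]
  pep_dt <- dt[, list(
    sequence = peptide[1L], mass = mass[1L],
    min_missed = min(n_missed)
  ), keyby = "il_key"]
  npar <- parents_dt[, list(n_parents = .N), keyby = "il_key"]
  pep_dt[, n_parents := npar[["n_parents"]]]
  keys_a <- unique(dt[["il_key"]][dt[["species"]] == tag_a])
  peptides <- tibble::as_tibble(pep_dt) %>%
    dplyr::mutate(
      in_a = .data$il_key %in% keys_a,
      in_b = .data$il_key %in% unique(dt[["il_key"]][dt[["species"]] == tag_b]),
      length = nchar(.data$il_key),
      species_class = dplyr::case_when(
        .data$in_a & .data$in_b ~ "shared",
        .data$in_a ~ paste0("unique_to_", tag_a),
        TRUE ~ paste0("unique_to_", tag_b)
      ),
      observable = .data$length >= length_window[1] &
        .data$length <= length_window[2] &
        .data$mass >= mass_window[1] &
        .data$mass <= mass_window[2]
    ) %>%
    dplyr::select(
      "il_key", "sequence", "length", "mass",
      "species_class", "observable", "min_missed", "n_parents"
    )

  observable_keys <- peptides$il_key[peptides$observable]
  parents_dt[, obs := il_key %in% observable_keys]
  prot_dt <- parents_dt[, list(
    n_observable = sum(obs & n_missed == 0),
    n_observable_any_missed = sum(obs)
  ), by = c("species", "protein_id")]
  parents_dt[, obs := NULL]
  parents <- tibble::as_tibble(parents_dt)
  proteins <- tibble::as_tibble(prot_dt)
  # proteins whose digest yields nothing inside the windows are retained with
  # n_observable = 0 and flagged non-quantifiable downstream
  all_prot <- dplyr::bind_rows(
    proteome_a[, c("species", "protein_id")],
    proteome_b[, c("species", "protein_id")]
  )
  proteins <- all_prot %>%
    dplyr::left_join(proteins, by = c("species", "protein_id")) %>%
    dplyr::mutate(dplyr::across(
      c("n_observable", "n_observable_any_missed"),
      ~ tidyr::replace_na(.x, 0L)
    ))

  structure(
    list(
      peptides = peptides,
      parents = parents, # keyed (sorted) by il_key, species, protein_id
      proteins = proteins,
      params = list(
        tag_a = tag_a, tag_b = tag_b, max_missed = max_missed,
        length_window = length_window, mass_window = mass_window,
        rule = rule, on_invalid = on_invalid, version = 1L
      )
    ),
    class = "peptide_library"
  )
}

digest_proteome <- function(proteome, max_missed, rule) {
  d <- digest_many(toupper(proteome$sequence), proteome$protein_id, max_missed, rule)
  d$species <- proteome$species[1]
  d
}

#' @export
print.peptide_library <- function(x, ...) {
  p <- x$params
  cls <- table(x$peptides$species_class)
  cat(sprintf(
    "<peptide_library> %s vs %s | %d peptides (%s) | max_missed=%d, length %d-%d, mass %.0f-%.0f Da\n",
    p$tag_a, p$tag_b, nrow(x$peptides),
    paste(sprintf("%s: %d", names(cls), cls), collapse = ", "),
    p$max_missed, p$length_window[1], p$length_window[2],
    p$mass_window[1], p$mass_window[2]
  ))
  invisible(x)
}

#' Count theoretically observable peptides of proteins
#'
#' Number of distinct I/L-collapsed peptides of a protein that fall inside the
#' library's observability windows, counted at 0 missed cleavages by default
#' (the standard iBAQ denominator and the "expected" count of the
#' observed/expected ratio).
#'
#' @param library A `peptide_library`.
#' @param protein_id Character vector of protein accessions to look up; `NULL`
#'   returns all proteins.
#' @param include_missed Count missed-cleavage variants too (default `FALSE`).
#'
#' @return If `protein_id` is given, an integer vector in the same order;
#'   otherwise a tibble (`species`, `protein_id`, `n_observable`).
#' @export
count_observable_peptides <- function(library, protein_id = NULL,
                                      include_missed = FALSE) {
  stopifnot(inherits(library, "peptide_library"))
  col <- if (include_missed) "n_observable_any_missed" else "n_observable"
  tab <- library$proteins
  if (is.null(protein_id)) {
    return(dplyr::select(tab,
      "species", "protein_id",
      n_observable = dplyr::all_of(col)
    ))
  }
  idx <- match(protein_id, tab$protein_id)
  if (anyNA(idx)) {
    rlang::abort(sprintf(
      "unknown protein(s): %s",
      paste(protein_id[is.na(idx)], collapse = ", ")
    ))
  }
  as.integer(tab[[col]][idx])
}

LIBRARY_FORMAT_HEADER <- "# xenoprot_peptide_library_v1"

#' Export / import a peptide library as tab-separated text
#'
#' The on-disk format is a tab-separated table (`il_key`, `sequence_example`,
#' `species_class`, `parents`, `observable_flag`, `mass`, `n_missed`) preceded
#' by a versioned header line carrying the build parameters. `parents` packs
#' each parent as `species:protein_id:n_missed`, `;`-separated.
#'
#' @param library A `peptide_library`.
#' @param path Output (input) file path.
#' @return `write_peptide_library()` returns `path` invisibly;
#'   `read_peptide_library()` returns a `peptide_library`.
#' @export
write_peptide_library <- function(library, path) {
  stopifnot(inherits(library, "peptide_library"))
  p <- library$params
  hdr <- sprintf(
    "%s tag_a=%s tag_b=%s max_missed=%d min_len=%d max_len=%d min_mass=%g max_mass=%g rule=%s",
    LIBRARY_FORMAT_HEADER, p$tag_a, p$tag_b, p$max_missed,
    p$length_window[1], p$length_window[2],
    p$mass_window[1], p$mass_window[2], p$rule
  )
  packed <- library$parents %>%
    dplyr::mutate(tok = sprintf("%s:%s:%d", .data$species, .data$protein_id, .data$n_missed)) %>%
    dplyr::group_by(.data$il_key) %>%
    dplyr::summarise(parents = paste(.data$tok, collapse = ";"), .groups = "drop")
  tab <- library$peptides %>%
    dplyr::left_join(packed, by = "il_key") %>%
    dplyr::transmute(
      il_key = .data$il_key, sequence_example = .data$sequence,
      species_class = .data$species_class, parents = .data$parents,
      observable_flag = .data$observable,
      mass = sprintf("%.5f", .data$mass), n_missed = .data$min_missed
    )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' @rdname write_peptide_library
#' @export
read_peptide_library <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, LIBRARY_FORMAT_HEADER)) {
    rlang::abort("not a xenoprot peptide library file (missing version header)")
  }
  kv <- stringr::str_match_all(hdr, "(\\S+)=(\\S+)")[[1]]
  par <- stats::setNames(kv[, 3], kv[, 2])
  tab <- utils::read.table(path,
    sep = "\t", skip = 1, header = TRUE,
    colClasses = c(
      "character", "character", "character",
      "character", "logical", "numeric", "integer"
    )
  )
  parents <- tab %>%
    dplyr::select("il_key", "parents") %>%
    tidyr::separate_longer_delim("parents", ";") %>%
    tidyr::separate_wider_delim("parents",
      ":",
      names = c("species", "protein_id", "n_missed")
    ) %>%
    dplyr::mutate(n_missed = as.integer(.data$n_missed)) %>%
    tibble::as_tibble()
  length_window <- c(as.integer(par[["min_len"]]), as.integer(par[["max_len"]]))
  mass_window <- c(as.numeric(par[["min_mass"]]), as.numeric(par[["max_mass"]]))
  peptides <- tibble::tibble(
    il_key = tab$il_key, sequence = tab$sequence_example,
    length = nchar(tab$il_key), mass = tab$mass,
    species_class = tab$species_class, observable = tab$observable_flag,
    min_missed = tab$n_missed,
    n_parents = as.integer(table(parents$il_key)[tab$il_key])
  )
  observable_keys <- peptides$il_key[peptides$observable]
  proteins <- parents %>%
    dplyr::group_by(.data$species, .data$protein_id) %>%
    dplyr::summarise(
      n_observable = sum(.data$n_missed == 0 & .data$il_key %in% observable_keys),
      n_observable_any_missed = sum(.data$il_key %in% observable_keys),
      .groups = "drop"
    )
  structure(
    list(
      peptides = peptides, parents = parents, proteins = proteins,
      params = list(
        tag_a = par[["tag_a"]], tag_b = par[["tag_b"]],
        max_missed = as.integer(par[["max_missed"]]),
        length_window = length_window, mass_window = mass_window,
        rule = par[["rule"]], on_invalid = "error", version = 1L
      )
    ),
    class = "peptide_library"
  )
}
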