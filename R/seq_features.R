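# Transcript-feature comparisons (GC content, UTR lengths) between gene sets
# and generic hypergeometric over-representation analysis.

#' GC content of nucleotide sequences
#'
#' Percentage of G+C among unambiguous bases; `N` is excluded from the
#' denominator. Case-insensitive; `U` and `T` are interchangeable.
#'
#' @param sequence Character vector of nucleotide sequences over
#'   `{A, C, G, T, U, N}`.
#' @return Numeric vector of GC percentages (0-100).
#' @examples
#' gc_content(c("GCGC", "ATGCN"))
#' @export
gc_content <- function(sequence) {
  s <- toupper(sequence)
  bad <- stringr::str_detect(s, "[^ACGTUN]")
  if (any(bad)) {
    rlang::abort(sprintf(
      "invalid nucleotide character in sequence %d", which(bad)[1]
    ))
  }
  gc <- stringr::str_count(s, "[GC]")
  denom <- stringr::str_count(s, "[ACGTU]")
  if (any(denom == 0)) {
    rlang::abort(sprintf(
      "sequence %d has no unambiguous bases", which(denom == 0)[1]
    ))
  }
  100 * gc / denom
}

#' Build a gene-feature table from transcript FASTA plus UTR coordinates
#'
#' Computes per-transcript GC content and UTR lengths from sequence. The
#' coordinate table gives 1-based inclusive positions of the untranslated
#' regions within each transcript (`utr5_start`, `utr5_end`, `utr3_start`,
#' `utr3_end`); a zero-length UTR is encoded by `end < start`.
#'
#' @param fasta_path Transcript FASTA file.
#' @param utr_coords Data frame with `gene_id` (matching FASTA accessions) and
#'   the four coordinate columns.
#' @return A gene-feature tibble (`gene_id`, `utr5_length`, `utr3_length`,
#'   `gc_percent`).
#' @export
gene_features_from_fasta <- function(fasta_path, utr_coords) {
  req <- c("gene_id", "utr5_start", "utr5_end", "utr3_start", "utr3_end")
  stopifnot(all(req %in% names(utr_coords)))
  dna <- Biostrings::readDNAStringSet(fasta_path)
  ids <- parse_fasta_accession(names(dna))
  seqs <- stats::setNames(as.character(dna), ids)
  missing <- setdiff(utr_coords$gene_id, ids)
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "transcript(s) absent from FASTA: %s",
      paste(missing, collapse = ", ")
    ))
  }
  tibble::tibble(
    gene_id = utr_coords$gene_id,
    utr5_length = pmax(0L, utr_coords$utr5_end - utr_coords$utr5_start + 1L),
    utr3_length = pmax(0L, utr_coords$utr3_end - utr_coords$utr3_start + 1L),
    gc_percent = gc_content(seqs[utr_coords$gene_id])
  )
}

#' Compare a transcript feature between two gene sets
#'
#' Welch (unequal-variance) unpaired two-tailed t-test of a feature column
#' between the genes of `set_a` and `set_b`.
#'
#' @param table Gene-feature tibble with a `gene_id` column and the feature.
#' @param set_a,set_b Character vectors of gene ids (each must match >= 2
#'   rows of `table`).
#' @param feature Column to compare, e.g. `"utr5_length"`, `"utr3_length"`,
#'   `"gc_percent"`.
#'
#' @return One-row tibble: `feature`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `n_a`, `n_b`, `t`, `df`, `p_value`.
#' @export
compare_feature <- function(table, set_a, set_b, feature) {
  if (!feature %in% names(table)) {
    rlang::abort(sprintf("feature '%s' absent from table", feature))
  }
  xa <- table[[feature]][table$gene_id %in% set_a]
  xb <- table[[feature]][table$gene_id %in% set_b]
  if (length(xa) < 2 || length(xb) < 2) {
    rlang::abort("each gene set must match at least 2 table rows")
  }
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0 && mean(xa) == mean(xb)) {
    # degenerate but well-defined: identical constant groups
    ht <- list(statistic = c(t = 0), parameter = c(df = length(xa) + length(xb) - 2), p.value = 1)
  } else {
    ht <- stats::t.test(xa, xb, var.equal = FALSE)
  }
  tibble::tibble(
    feature = feature,
    mean_a = mean(xa), mean_b = mean(xb),
    sd_a = stats::sd(xa), sd_b = stats::sd(xb),
    n_a = length(xa), n_b = length(xb),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the selection contains more term
#' genes than expected under hypergeometric sampling from the universe
#' (upper tail, `P[X >= k]`). Terms with no universe genes are skipped;
#' q-values are Benjamini-Hochberg across tested terms.
#'
#' @param selection Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe Character vector of background genes.
#' @param annotation Data frame mapping `term` to `gene_id`; genes outside the
#'   universe are ignored.
#'
#' @return Tibble per term: `term`, `k` (hits in selection), `K` (term size in
#'   universe), `n` (selection size), `N` (universe size), `fold_enrichment`
#'   (`(k/n)/(K/N)`), `p_value`, `q_value`, sorted by p.
#' @export
ora <- function(selection, universe, annotation) {
  stopifnot(all(c("term", "gene_id") %in% names(annotation)))
  selection <- unique(selection)
  universe <- unique(universe)
  offenders <- setdiff(selection, universe)
  if (length(offenders) > 0) {
    rlang::abort(sprintf(
      "selection not a subset of universe; offender(s): %s",
      paste(utils::head(offenders, 5), collapse = ", ")
    ))
  }
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  ann <- dplyr::distinct(tibble::as_tibble(ann[, c("term", "gene_id")]))
  N <- length(universe)
  n <- length(selection)
  res <- ann %>%
    dplyr::group_by(.data$term) %>%
    dplyr::summarise(
      K = dplyr::n(),
      k = sum(.data$gene_id %in% selection),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$K > 0) %>%
    dplyr::mutate(
      n = n, N = N,
      fold_enrichment = (.data$k / n) / (.data$K / N),
      p_value = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
        lower.tail = FALSE
      ),
      q_value = stats::p.adjust(.data$p_value, method = "BH")
    ) %>%
    dplyr::arrange(.data$p_value, .data$term) %>%
    dplyr::select(
      "term", "k", "K", "n", "N",
      "fold_enrichment", "p_value", "q_value"
    )
  res
}
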