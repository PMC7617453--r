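#' In-silico tryptic digestion of a protein sequence
#'
#' Cleaves a protein sequence with trypsin-like specificity and enumerates all
#' peptides with up to `max_missed` missed cleavage sites. The classical rule
#' (`"trypsin"`) cuts C-terminal to lysine (K) or arginine (R) except when the
#' next residue is proline (P); `"trypsin/P"` drops the proline restriction.
#'
#' Peptides are returned in deterministic order: by position along the protein
#' (N- to C-terminal), then by number of missed cleavages. Every peptide with
#' `n_missed = k` is the exact concatenation of `k + 1` adjacent fully cleaved
#' fragments, and the fully cleaved (`n_missed = 0`) fragments partition the
#' input sequence.
#'
#' @param sequence Single amino-acid string over the 20-letter alphabet.
#' @param max_missed Maximum number of missed cleavage sites (default 2, the
#'   common database-search setting).
#' @param rule Cleavage rule, `"trypsin"` (K/R not before P) or `"trypsin/P"`.
#' @param on_invalid What to do with residues outside the 20-letter alphabet:
#'   `"error"` (default) aborts reporting the first offending position;
#'   `"skip_peptide"` silently drops every peptide containing such a residue.
#'
#' @return A tibble with one row per peptide: `peptide`, `il_key` (sequence
#'   with I collapsed to L), `start`, `end` (1-based residue coordinates),
#'   `n_missed`, and `mass` (monoisotopic, Da).
#'
#' @examples
#' digest_protein("MKRAPK", max_missed = 1)
#' @export
digest_protein <- function(sequence, max_missed = 2,
                           rule = c("trypsin", "trypsin/P"),
                           on_invalid = c("error", "skip_peptide")) {
  rule <- match.arg(rule)
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.character(sequence), length(sequence) == 1, !is.na(sequence))
  if (nchar(sequence) == 0) {
    rlang::abort("`sequence` must be non-empty.")
  }
  if (max_missed < 0) {
    rlang::abort("`max_missed` must be >= 0.")
  }
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% AA_ALPHABET)
  if (length(bad) > 0 && on_invalid == "error") {
    rlang::abort(sprintf(
      "invalid residue '%s' at position %d (and %d more)",
      res[bad[1]], bad[1], length(bad) - 1L
    ))
  }
  out <- digest_one(sequence, res, max_missed, rule)
  if (length(bad) > 0) {
    # skip_peptide policy: drop peptides overlapping any invalid residue
    keep <- !purrr::map2_lgl(out$start, out$end, function(s, e) any(bad >= s & bad <= e))
    out <- out[keep, , drop = FALSE]
  }
  out$il_key <- il_collapse(out$peptide)
  out$mass <- peptide_masses(out$start, out$end, res)
  tibble::as_tibble(out[, c("peptide", "il_key", "start", "end", "n_missed", "mass")])
}

# Core cleavage engine shared by the scalar and the batch interface.
# `res` is the residue vector of `sequence`. Invalid residues never cleave.
digest_one <- function(sequence, res, max_missed, rule) {
  n <- length(res)
  cut_after <- which(res == "K" | res == "R")
  if (rule == "trypsin" && length(cut_after) > 0) {
    cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  }
  # fully cleaved fragment boundaries
  ends0 <- unique(c(cut_after, n))
  starts0 <- c(1L, utils::head(ends0, -1L) + 1L)
  nf <- length(ends0)
  starts <- integer(0); ends <- integer(0); miss <- integer(0)
  for (k in 0:min(max_missed, nf - 1L)) {
    idx <- seq_len(nf - k)
    starts <- c(starts, starts0[idx])
    ends <- c(ends, ends0[idx + k])
    miss <- c(miss, rep.int(k, nf - k))
  }
  ord <- order(starts, miss)
  starts <- starts[ord]; ends <- ends[ord]; miss <- miss[ord]
  data.frame(
    peptide = substring(sequence, starts, ends),
    start = starts, end = ends, n_missed = miss,
    stringsAsFactors = FALSE
  )
}

# Vectorised peptide masses from residue prefix sums: O(protein length),
# independent of how many (possibly overlapping) peptides are requested.
peptide_masses <- function(starts, ends, res) {
  m <- AA_MONO_MASS[res]
  # invalid residues contribute 0; callers drop peptides containing them
  m[is.na(m)] <- 0
  pre <- c(0, cumsum(m))
  pre[ends + 1L] - pre[starts] + WATER_MONO_MASS
}

# Batch digestion used by library construction: one pass over a character
# vector of sequences, returning a single data frame. Assumes sequences were
# validated upstream.
digest_many <- function(sequences, ids, max_missed, rule) {
  pieces <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    res <- strsplit(sequences[[i]], "", fixed = TRUE)[[1]]
    d <- digest_one(sequences[[i]], res, max_missed, rule)
    d$mass <- peptide_masses(d$start, d$end, res)
    d$protein_id <- ids[[i]]
    pieces[[i]] <- d
  }
  dplyr::bind_rows(pieces)
}
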