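# Readers for the package's tab-separated interchange formats.

#' Read a peptide-evidence table
#'
#' Tab-separated with columns `peptide` and `intensity` (optionally
#' `sample_id`, `spectral_count`). A MaxQuant-style peptide table (columns
#' `Sequence`, `Intensity`) is mapped onto the same schema with
#' `format = "maxquant"`. Missing intensities (`NA`) are substituted with 0
#' at load time.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"maxquant"`.
#' @return Evidence tibble.
#' @export
read_evidence <- function(path, format = c("tsv", "maxquant")) {
  format <- match.arg(format)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "maxquant") {
    cols <- names(tab)
    seq_col <- cols[tolower(cols) == "sequence"][1]
    int_col <- cols[tolower(cols) == "intensity"][1]
    if (is.na(seq_col) || is.na(int_col)) {
      rlang::abort("MaxQuant table needs 'Sequence' and 'Intensity' columns")
    }
    tab <- tibble::tibble(peptide = tab[[seq_col]], intensity = tab[[int_col]])
  }
  tab$intensity[is.na(tab$intensity)] <- 0
  validate_evidence(tab)
}

#' Write a protein-call table as tab-separated text
#'
#' @param calls A `protein_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_calls <- function(calls, path) {
  out <- tibble::as_tibble(calls)
  if ("members" %in% names(out)) {
    out$members <- purrr::map_chr(out$members, paste, collapse = ";")
  }
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a spectral-count matrix and its sample design
#'
#' `read_counts()` expects a tab-separated protein-by-sample table whose
#' first column holds protein ids; `NA` counts are substituted with 0 at
#' load time. `read_design()` expects two columns, `sample_id` and `group`.
#'
#' @param path File path.
#' @return `read_counts()`: a numeric matrix; `read_design()`: a tibble.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  tab[-1][is.na(tab[-1])] <- 0
  as_count_matrix(tab)
}

#' @rdname read_counts
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab))) {
    rlang::abort("design file needs `sample_id` and `group` columns")
  }
  tibble::as_tibble(tab)
}

#' Read a 2-D cell-coordinate table
#'
#' Tab-separated columns `id`, `x`, `y`, `class` (micrometre coordinates of
#' segmented cells, e.g. exported from an image-analysis point list).
#'
#' @param path File path.
#' @return Point tibble.
#' @export
read_points <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_points(tab)
}

#' Read a gene-set list (one identifier per line)
#'
#' @param path File path; blank lines and `#` comments are skipped.
#' @return Character vector of identifiers.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a term-to-gene annotation table
#'
#' Two tab-separated columns: `term` and `gene_id`.
#'
#' @param path File path.
#' @return Annotation tibble.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term", "gene_id") %in% names(tab))) {
    rlang::abort("annotation file needs `term` and `gene_id` columns")
  }
  tibble::as_tibble(tab)
}
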