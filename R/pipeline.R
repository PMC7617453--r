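# End-to-end orchestration of the xenograft deconvolution analysis, input
# validation, and the reproducibility manifest.

#' Run the full xenograft proteome-deconvolution analysis
#'
#' Chains library construction, peptide assignment, parsimony classification,
#' iBAQ quantification and enrichment calling, and — when the optional inputs
#' are supplied — functional-category composition, over-representation
#' analysis, and transcript-feature comparison of the enriched set against
#' the remaining quantified proteins. Optional stages degrade gracefully: a
#' missing annotation simply skips ORA with a warning rather than aborting.
#'
#' @param proteome_host,proteome_graft Proteome tibbles (`species`,
#'   `protein_id`, `sequence`).
#' @param evidence Peptide-evidence tibble (see [read_evidence()]).
#' @param category_map Optional `protein_id`/`category` tibble for
#'   [category_composition()].
#' @param annotation Optional `term`/`gene_id` tibble for [ora()] over the
#'   enriched set (universe = all quantified groups).
#' @param feature_table Optional gene-feature tibble for [compare_feature()]
#'   of the enriched set versus the other quantified proteins.
#' @param features Feature columns to compare when `feature_table` is given.
#' @param min_peptides,mode,max_missed,length_window,mass_window,rule
#'   Passed to the respective stages.
#' @param library Optional pre-built `peptide_library` (skips digestion).
#'
#' @return A `pdx_analysis` object: list with `calls` (quantified, enriched
#'   `protein_calls`), `assignments`, `library`, `composition`, `ora`,
#'   `feature_tests`, and `manifest` (configuration snapshot, input
#'   checksums, per-stage status). `tidy()` returns the calls table,
#'   `glance()` the run summary.
#' @export
run_pdx_analysis <- function(proteome_host, proteome_graft, evidence,
                             category_map = NULL, annotation = NULL,
                             feature_table = NULL,
                             features = c("utr5_length", "utr3_length", "gc_percent"),
                             min_peptides = 2, mode = "strict",
                             max_missed = 2, length_window = c(7, 30),
                             mass_window = c(700, 4600), rule = "trypsin",
                             library = NULL) {
  stages <- list()
  note <- function(stage, status) {
    stages[[stage]] <<- status
  }
  run_stage <- function(stage, expr) {
    out <- tryCatch(expr, error = function(e) {
      note(stage, paste("failed:", conditionMessage(e)))
      rlang::abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    note(stage, "ok")
    out
  }

  host_tag <- unique(proteome_host$species)
  if (is.null(library)) {
    library <- run_stage("build_libraries", build_peptide_libraries(
      proteome_host, proteome_graft,
      max_missed = max_missed,
      length_window = length_window, mass_window = mass_window, rule = rule
    ))
  } else {
    note("build_libraries", "skipped (pre-built library supplied)")
  }
  assignments <- run_stage("assign_peptides", assign_peptides(evidence, library))
  calls <- run_stage("classify_proteins", classify_proteins(
    assignments,
    host = host_tag, min_peptides = min_peptides, mode = mode
  ))
  calls <- run_stage("quantify_ibaq", quantify_ibaq(calls, assignments, library))
  calls <- run_stage("call_enriched", call_enriched(calls))

  composition <- NULL
  if (!is.null(category_map)) {
    composition <- run_stage(
      "category_composition",
      category_composition(calls, category_map)
    )
  } else {
    note("category_composition", "skipped (no category map)")
  }

  ora_result <- NULL
  enriched_ids <- calls$group_id[!is.na(calls$enriched) & calls$enriched]
  if (!is.null(annotation)) {
    if (length(enriched_ids) == 0) {
      rlang::warn("no enriched proteins; skipping over-representation analysis")
      note("ora", "skipped (empty enriched set)")
    } else {
      ora_result <- run_stage("ora", ora(
        enriched_ids, calls$group_id[calls$quantifiable], annotation
      ))
    }
  } else {
    note("ora", "skipped (no annotation)")
  }

  feature_tests <- NULL
  if (!is.null(feature_table)) {
    rest <- setdiff(calls$group_id[calls$quantifiable], enriched_ids)
    if (length(enriched_ids) >= 2 && length(rest) >= 2) {
      feature_tests <- run_stage("compare_features", purrr::map_dfr(
        intersect(features, names(feature_table)),
        ~ compare_feature(feature_table, enriched_ids, rest, .x)
      ))
    } else {
      note("compare_features", "skipped (too few enriched proteins)")
    }
  } else {
    note("compare_features", "skipped (no feature table)")
  }

  manifest <- build_manifest(
    params = list(
      min_peptides = min_peptides, mode = mode, max_missed = max_missed,
      length_window = length_window, mass_window = mass_window, rule = rule,
      host = host_tag
    ),
    inputs = list(
      proteome_host = proteome_host, proteome_graft = proteome_graft,
      evidence = evidence, category_map = category_map,
      annotation = annotation, feature_table = feature_table
    ),
    stages = stages
  )
  structure(
    list(
      calls = calls, assignments = assignments, library = library,
      composition = composition, ora = ora_result,
      feature_tests = feature_tests, manifest = manifest
    ),
    class = "pdx_analysis"
  )
}

# A run manifest: configuration snapshot, checksums of every input, and the
# per-stage status. Two runs with identical manifest inputs produce
# identical deterministic outputs (the whole chain is seed-free).
build_manifest <- function(params, inputs, stages) {
  checksums <- purrr::map(inputs, function(x) {
    if (is.null(x)) NULL else rlang::hash(x)
  })
  list(
    package_version = as.character(utils::packageVersion("xenoprot")),
    params = params,
    input_checksums = purrr::compact(checksums),
    stages = stages
  )
}

#' @export
print.pdx_analysis <- function(x, ...) {
  cc <- attr(x$calls, "class_counts")
  cat(sprintf(
    "<pdx_analysis> %d protein groups (%s) | %d enriched\n",
    nrow(x$calls),
    paste(sprintf("%s: %d", names(cc), cc), collapse = ", "),
    sum(x$calls$enriched, na.rm = TRUE)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pdx_analysis <- function(x, ...) tibble::as_tibble(x$calls)

#' @exportS3Method generics::glance
glance.pdx_analysis <- function(x, ...) {
  cc <- attr(x$calls, "class_counts")
  tibble::tibble(
    n_groups = nrow(x$calls),
    n_host_exclusive = as.integer(cc[["host_exclusive"]]),
    n_graft_exclusive = as.integer(cc[["graft_exclusive"]]),
    n_conserved = as.integer(cc[["conserved"]]),
    n_enriched = sum(x$calls$enriched, na.rm = TRUE),
    unmatched_fraction = attr(x$assignments, "unmatched_fraction")
  )
}

#' Scatter plot of the enrichment plane
#'
#' Observed/expected peptide ratio against iBAQ score for each quantified
#' protein group, with class means drawn as dashed thresholds and enriched
#' proteins highlighted.
#'
#' @param object A `pdx_analysis`.
#' @param species_class Which class to display (default `"host_exclusive"`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pdx_analysis <- function(object, species_class = "host_exclusive", ...) {
  d <- tibble::as_tibble(object$calls)
  d <- d[d$species_class == species_class & d$quantifiable, , drop = FALSE]
  thr <- enrichment_thresholds(object$calls)
  thr <- thr[thr$species_class == species_class, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$iBAQ_score, y = .data$obs_exp_ratio,
    colour = .data$enriched
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = thr$mean_iBAQ_score, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thr$mean_obs_exp_ratio, linetype = "dashed") +
    ggplot2::labs(
      x = "iBAQ score (log10 ppm)", y = "observed/expected peptides",
      colour = "enriched", title = species_class
    ) +
    ggplot2::theme_minimal()
}

#' Validate pipeline input files
#'
#' Schema checks for the package's input formats, reporting the location of
#' every violation instead of stopping at the first: FASTA records without
#' sequence, invalid residues, negative intensities, unknown point classes,
#' out-of-bounds coordinates, and missing columns.
#'
#' @param fasta,evidence,points,counts Optional file paths; only supplied
#'   inputs are checked.
#' @param bounds Optional `c(xmax, ymax)` for coordinate checks.
#' @return Tibble of violations (`input`, `where`, `message`); zero rows
#'   means all supplied inputs are well-formed.
#' @export
validate_inputs <- function(fasta = NULL, evidence = NULL, points = NULL,
                            counts = NULL, bounds = NULL) {
  v <- list()
  bad <- function(input, where, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      input = input, where = where, message = message
    )
  }
  if (!is.null(fasta)) {
    lines <- readLines(fasta)
    headers <- which(startsWith(lines, ">"))
    if (length(headers) == 0) {
      bad("fasta", fasta, "no FASTA records found")
    } else {
      ends <- c(headers[-1] - 1L, length(lines))
      for (i in seq_along(headers)) {
        body <- if (ends[i] > headers[i]) lines[(headers[i] + 1L):ends[i]] else character(0)
        seqs <- paste(body, collapse = "")
        rec <- sub("^>\\s*", "", lines[headers[i]])
        if (!nzchar(seqs)) {
          bad("fasta", rec, "record has no sequence")
        } else {
          pat <- sprintf("[^%s]", paste(AA_ALPHABET, collapse = ""))
          hit <- stringr::str_locate(toupper(seqs), pat)[, 1]
          if (!is.na(hit)) {
            bad("fasta", rec, sprintf("invalid residue at position %d", hit))
          }
        }
      }
    }
  }
  if (!is.null(evidence)) {
    tab <- utils::read.delim(evidence, stringsAsFactors = FALSE)
    if (!all(c("peptide", "intensity") %in% names(tab))) {
      bad("evidence", evidence, "missing `peptide`/`intensity` columns")
    } else {
      neg <- which(!is.na(tab$intensity) & tab$intensity < 0)
      for (r in neg) bad("evidence", sprintf("row %d", r), "negative intensity")
    }
  }
  if (!is.null(points)) {
    tab <- utils::read.delim(points, stringsAsFactors = FALSE)
    req <- c("id", "x", "y", "class")
    if (!all(req %in% names(tab))) {
      bad("points", points, sprintf(
        "missing column(s): %s",
        paste(setdiff(req, names(tab)), collapse = ", ")
      ))
    } else {
      unknown <- which(!tab$class %in% c("query", "reference", "background"))
      for (r in unknown) {
        bad("points", sprintf("row %d", r), sprintf("unknown class '%s'", tab$class[r]))
      }
      if (!is.null(bounds)) {
        oob <- which(tab$x < 0 | tab$y < 0 | tab$x > bounds[1] | tab$y > bounds[2])
        for (r in oob) bad("points", sprintf("row %d", r), "coordinate out of bounds")
      }
    }
  }
  if (!is.null(counts)) {
    tab <- utils::read.delim(counts, stringsAsFactors = FALSE)
    num <- tab[, -1, drop = FALSE]
    if (ncol(num) == 0 || !all(vapply(num, is.numeric, logical(1)))) {
      bad("counts", counts, "no numeric sample columns")
    } else {
      neg <- which(as.matrix(num) < 0)
      if (length(neg) > 0) bad("counts", "matrix", "negative counts present")
    }
  }
  if (length(v) == 0) {
    tibble::tibble(input = character(0), where = character(0), message = character(0))
  } else {
    dplyr::bind_rows(v)
  }
}
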