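#' Assign observed peptide evidence to species
#'
#' Matches each observed peptide (I/L-collapsed) against a peptide library and
#' labels it `unique_to_<species>`, `shared`, or `unmatched`. Rows are
#' aggregated to one per (peptide, sample) by summing intensity, and — by
#' default — pooled across samples before downstream quantification.
#'
#' @param evidence Tibble of peptide-level evidence with columns `peptide` and
#'   `intensity` (arbitrary MS intensity units, >= 0); optional `sample_id`
#'   and `spectral_count`. See [read_evidence()].
#' @param library A `peptide_library` from [build_peptide_libraries()].
#' @param pool_samples Sum intensities per peptide across samples before
#'   assignment (default `TRUE`, matching pooled gel-band designs). With
#'   `FALSE` the assignment keeps one row per (peptide, sample).
#'
#' @return A `peptide_assignments` object: tibble with `peptide`, `il_key`,
#'   `intensity`, `class`, and `n_parents`; the parent map, library parameters
#'   and the unmatched fraction travel as attributes. All observed peptides
#'   unmatched is reported with a warning, not an error.
#' @export
assign_peptides <- function(evidence, library, pool_samples = TRUE) {
  stopifnot(inherits(library, "peptide_library"))
  evidence <- validate_evidence(evidence)
  by <- if (pool_samples || !"sample_id" %in% names(evidence)) {
    "peptide"
  } else {
    c("peptide", "sample_id")
  }
  evidence <- tibble::as_tibble(data.table::as.data.table(evidence)[,
    list(intensity = sum(intensity)),
    keyby = by
  ])
  evidence$il_key <- il_collapse(toupper(evidence$peptide))
  hit <- match(evidence$il_key, library$peptides$il_key)
  out <- evidence %>%
    dplyr::mutate(
      class = dplyr::coalesce(library$peptides$species_class[hit], "unmatched"),
      n_parents = dplyr::coalesce(library$peptides$n_parents[hit], 0L)
    ) %>%
    dplyr::arrange(.data$il_key)
  unmatched_fraction <- mean(out$class == "unmatched")
  if (unmatched_fraction == 1) {
    rlang::warn("no observed peptide matched the library")
  }
  parents <- library$parents[library$parents$il_key %in% out$il_key, , drop = FALSE]
  structure(out,
    class = c("peptide_assignments", class(out)),
    parents = parents,
    library_params = library$params,
    unmatched_fraction = unmatched_fraction
  )
}

validate_evidence <- function(evidence) {
  if (!all(c("peptide", "intensity") %in% names(evidence))) {
    rlang::abort("evidence needs `peptide` and `intensity` columns")
  }
  if (nrow(evidence) == 0) rlang::abort("evidence table is empty")
  if (any(!is.finite(evidence$intensity)) || any(evidence$intensity < 0)) {
    bad <- which(!is.finite(evidence$intensity) | evidence$intensity < 0)[1]
    rlang::abort(sprintf("non-finite or negative intensity at row %d", bad))
  }
  tibble::as_tibble(evidence)
}

#' Group proteins by parsimony and classify them by species of origin
#'
#' Protein inference by greedy minimal set cover over the observed peptide
#' evidence: proteins that are the sole parent of an observed peptide are
#' forced into the cover, then proteins explaining the most still-unexplained
#' peptides are added (ties broken by total observed peptides, then
#' accession). Proteins whose observed peptide set is nested inside a group's
#' set are recorded as subsumed members of that group.
#'
#' A group is `host_exclusive` when **all** of its distinct observed peptides
#' are unique to the host library (the strictest reading of "exclusively
#' mapping" to one species), `graft_exclusive` symmetrically, and `conserved`
#' otherwise. `mode = "relaxed"` instead requires at least one host-unique and
#' no graft-unique peptide (and symmetrically). Groups with fewer than
#' `min_peptides` distinct observed peptides are dropped.
#'
#' @param assignments A `peptide_assignments` object.
#' @param host Species tag of the host (e.g. `"mouse"`); the other library
#'   tag is the graft.
#' @param min_peptides Minimum distinct observed peptides per retained group
#'   (default 2, the usual protein-acceptance threshold).
#' @param mode `"strict"` (default) or `"relaxed"` species-class rule.
#'
#' @return A `protein_calls` tibble: `group_id` (representative accession),
#'   `species` (of the representative), `species_class`,
#'   `n_observed_peptides`, and `members` (list-column of subsumed
#'   accessions). Class counts are attached as attribute `class_counts`.
#' @export
classify_proteins <- function(assignments, host, min_peptides = 2,
                              mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(assignments, "peptide_assignments"))
  if (min_peptides < 1) rlang::abort("`min_peptides` must be >= 1")
  params <- attr(assignments, "library_params")
  tags <- c(params$tag_a, params$tag_b)
  if (!host %in% tags) {
    rlang::abort(sprintf(
      "`host` must be one of the library tags: %s",
      paste(tags, collapse = ", ")
    ))
  }
  graft <- setdiff(tags, host)
  parents <- attr(assignments, "parents")
  obs <- dplyr::distinct(
    tibble::as_tibble(assignments)[assignments$class != "unmatched", "il_key"]
  )
  inc <- dplyr::semi_join(parents, obs, by = "il_key") %>%
    dplyr::mutate(protein = paste(.data$species, .data$protein_id, sep = "\r"))

  cover <- greedy_set_cover(inc$il_key, inc$protein)

  cls <- assignments %>%
    tibble::as_tibble() %>%
    dplyr::distinct(.data$il_key, .data$class)
  grp <- inc %>%
    dplyr::filter(.data$protein %in% cover) %>%
    dplyr::left_join(cls, by = "il_key")

  host_lab <- paste0("unique_to_", host)
  graft_lab <- paste0("unique_to_", graft)
  calls <- grp %>%
    dplyr::group_by(.data$species, .data$protein_id, .data$protein) %>%
    dplyr::summarise(
      n_observed_peptides = dplyr::n_distinct(.data$il_key),
      n_host = sum(.data$class == host_lab),
      n_graft = sum(.data$class == graft_lab),
      .groups = "drop"
    ) %>%
    dplyr::mutate(species_class = if (mode == "strict") {
      dplyr::case_when(
        .data$n_host == .data$n_observed_peptides ~ "host_exclusive",
        .data$n_graft == .data$n_observed_peptides ~ "graft_exclusive",
        TRUE ~ "conserved"
      )
    } else {
      dplyr::case_when(
        .data$n_host >= 1 & .data$n_graft == 0 ~ "host_exclusive",
        .data$n_graft >= 1 & .data$n_host == 0 ~ "graft_exclusive",
        TRUE ~ "conserved"
      )
    })

  # subsumed (nested) proteins: every observed peptide inside a group's set
  members <- subsumed_members(inc, cover)
  calls <- calls %>%
    dplyr::left_join(members, by = "protein") %>%
    dplyr::mutate(members = purrr::map(.data$members, ~ .x %||% character(0))) %>%
    dplyr::filter(.data$n_observed_peptides >= min_peptides) %>%
    dplyr::transmute(
      group_id = .data$protein_id, species = .data$species,
      species_class = .data$species_class,
      n_observed_peptides = .data$n_observed_peptides,
      members = .data$members
    ) %>%
    dplyr::arrange(.data$group_id)
  counts <- table(factor(calls$species_class,
    levels = c("host_exclusive", "graft_exclusive", "conserved")
  ))
  structure(calls,
    class = c("protein_calls", class(calls)),
    host = host, graft = graft, mode = mode, min_peptides = min_peptides,
    class_counts = counts
  )
}

# Greedy set cover: peptides are elements, proteins are sets. Proteins that
# are the only parent of a peptide are in every cover and are taken first.
greedy_set_cover <- function(element, set) {
  stopifnot(length(element) == length(set))
  el <- factor(element)
  single <- names(which(tapply(set, el, function(s) length(unique(s))) == 1))
  forced <- unique(set[element %in% single])
  covered <- unique(element[set %in% forced])
  cover <- sort(forced)
  remaining <- !(element %in% covered)
  sizes <- table(set)
  while (any(remaining)) {
    cand <- table(set[remaining])
    best <- max(cand)
    top <- names(cand)[cand == best]
    if (length(top) > 1) {
      top <- top[order(-as.integer(sizes[top]), top)]
    }
    pick <- top[1]
    cover <- c(cover, pick)
    covered_now <- unique(element[set == pick])
    remaining <- remaining & !(element %in% covered_now)
  }
  sort(unique(cover))
}

subsumed_members <- function(inc, cover) {
  sets <- split(inc$il_key, inc$protein)
  non_cover <- setdiff(names(sets), cover)
  if (length(non_cover) == 0) {
    return(tibble::tibble(protein = character(0), members = list()))
  }
  # candidate groups for a protein: only cover proteins sharing >= 1 peptide
  in_cover <- inc$protein %in% cover
  cover_by_pep <- split(inc$protein[in_cover], inc$il_key[in_cover])
  hits <- purrr::map(non_cover, function(p) {
    s <- sets[[p]]
    cand <- unique(unlist(cover_by_pep[s], use.names = FALSE))
    cand[purrr::map_lgl(cand, function(g) all(s %in% sets[[g]]))]
  })
  tibble::tibble(
    protein = unlist(hits),
    member = rep(
      sub("^.*\r", "", non_cover),
      lengths(hits)
    )
  ) %>%
    dplyr::group_by(.data$protein) %>%
    dplyr::summarise(members = list(sort(unique(.data$member))), .groups = "drop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify protein groups by iBAQ
#'
#' iBAQ is the summed intensity of a group's assigned peptides divided by the
#' number of theoretically observable fully cleaved peptides of its
#' representative protein. iBAQ values are normalized to parts-per-million of
#' the summed iBAQ over all quantifiable groups, and the iBAQ score is
#' log10 of that ppm value (so a run with one quantified protein scores 6).
#' Shared peptides are credited in full to every parsimony group containing
#' them (no razor splitting). Groups with zero observable peptides are
#' flagged non-quantifiable and excluded from the normalization.
#'
#' @param calls A `protein_calls` tibble from [classify_proteins()].
#' @param assignments The `peptide_assignments` the calls were built from.
#' @param library The `peptide_library` used for assignment.
#' @param include_missed Use denominators that include missed-cleavage
#'   variants (default `FALSE`, the standard iBAQ definition).
#'
#' @return `calls` with added columns `n_expected_peptides`, `obs_exp_ratio`,
#'   `iBAQ`, `iBAQ_ppm`, `iBAQ_score`, `quantifiable`.
#' @export
quantify_ibaq <- function(calls, assignments, library, include_missed = FALSE) {
  stopifnot(inherits(calls, "protein_calls"), inherits(assignments, "peptide_assignments"))
  parents <- attr(assignments, "parents")
  intens <- assignments %>%
    tibble::as_tibble() %>%
    dplyr::group_by(.data$il_key) %>%
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  grp_int <- parents %>%
    dplyr::semi_join(
      tibble::tibble(species = calls$species, protein_id = calls$group_id),
      by = c("species", "protein_id")
    ) %>%
    dplyr::inner_join(intens, by = "il_key") %>%
    dplyr::group_by(.data$species, .data$protein_id) %>%
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")

  out <- calls %>%
    dplyr::left_join(grp_int, by = c(group_id = "protein_id", species = "species")) %>%
    dplyr::mutate(
      intensity = dplyr::coalesce(.data$intensity, 0),
      n_expected_peptides = count_observable_peptides(
        library, .data$group_id,
        include_missed = include_missed
      ),
      quantifiable = .data$n_expected_peptides > 0,
      obs_exp_ratio = ifelse(.data$quantifiable,
        .data$n_observed_peptides / .data$n_expected_peptides, NA_real_
      ),
      iBAQ = ifelse(.data$quantifiable,
        .data$intensity / .data$n_expected_peptides, NA_real_
      )
    )
  total <- sum(out$iBAQ[out$quantifiable])
  out <- out %>%
    dplyr::mutate(
      iBAQ_ppm = ifelse(.data$quantifiable, 1e6 * .data$iBAQ / total, NA_real_),
      iBAQ_score = ifelse(.data$quantifiable & .data$iBAQ_ppm > 0,
        log10(.data$iBAQ_ppm), NA_real_
      )
    ) %>%
    dplyr::select(-"intensity")
  keep_attrs(out, calls)
}

keep_attrs <- function(new, old) {
  for (a in c("host", "graft", "mode", "min_peptides", "class_counts", "enrichment_thresholds")) {
    attr(new, a) <- attr(old, a)
  }
  class(new) <- unique(c("protein_calls", class(new)))
  new
}

#' Call enriched (candidate transferred) proteins
#'
#' Within each species class separately, a protein is *enriched* when its iBAQ
#' score and its observed/expected peptide ratio are both strictly above the
#' arithmetic class means (`rule = "both"`, the default). The alternative
#' reading, sum of the two metrics above the mean sum, is available as
#' `rule = "sum"`. Classes with fewer than two quantifiable members have
#' undefined enrichment (`NA`) and are flagged in the attached thresholds.
#'
#' @param calls A quantified `protein_calls` tibble (see [quantify_ibaq()]).
#' @param class_filter Optional character vector restricting which species
#'   classes are evaluated; others get `NA`.
#' @param rule `"both"` (default) or `"sum"`.
#'
#' @return `calls` with an added logical `enriched` column; per-class
#'   thresholds travel as attribute `enrichment_thresholds` (also returned by
#'   [enrichment_thresholds()]).
#' @export
call_enriched <- function(calls, class_filter = NULL, rule = c("both", "sum")) {
  rule <- match.arg(rule)
  if (!"iBAQ_score" %in% names(calls)) {
    rlang::abort("run `quantify_ibaq()` before `call_enriched()`")
  }
  classes <- unique(calls$species_class)
  if (!is.null(class_filter)) classes <- intersect(classes, class_filter)
  thresholds <- purrr::map_dfr(classes, function(cl) {
    i <- calls$species_class == cl & calls$quantifiable &
      is.finite(calls$iBAQ_score) & is.finite(calls$obs_exp_ratio)
    tibble::tibble(
      species_class = cl, n = sum(i),
      mean_iBAQ_score = if (sum(i) >= 2) mean(calls$iBAQ_score[i]) else NA_real_,
      mean_obs_exp_ratio = if (sum(i) >= 2) mean(calls$obs_exp_ratio[i]) else NA_real_,
      defined = sum(i) >= 2
    )
  })
  out <- calls %>%
    dplyr::left_join(thresholds, by = "species_class") %>%
    dplyr::mutate(
      enriched = dplyr::case_when(
        !.data$defined | !.data$quantifiable ~ NA,
        rule == "both" ~ .data$iBAQ_score > .data$mean_iBAQ_score &
          .data$obs_exp_ratio > .data$mean_obs_exp_ratio,
        TRUE ~ (.data$iBAQ_score + .data$obs_exp_ratio) >
          (.data$mean_iBAQ_score + .data$mean_obs_exp_ratio)
      )
    ) %>%
    dplyr::select(-"mean_iBAQ_score", -"mean_obs_exp_ratio", -"n", -"defined")
  out <- keep_attrs(out, calls)
  attr(out, "enrichment_thresholds") <- thresholds
  out
}

#' @rdname call_enriched
#' @export
enrichment_thresholds <- function(calls) {
  attr(calls, "enrichment_thresholds")
}

#' Functional-category composition of the enriched set
#'
#' @param calls A `protein_calls` tibble with an `enriched` column.
#' @param category_map Tibble mapping `protein_id` to `category`; proteins
#'   without a mapping are binned as `"other"`.
#'
#' @return Tibble (`category`, `n`, `percent`) over enriched proteins;
#'   zero rows when nothing is enriched.
#' @export
category_composition <- function(calls, category_map) {
  stopifnot(all(c("protein_id", "category") %in% names(category_map)))
  enr <- calls[!is.na(calls$enriched) & calls$enriched, , drop = FALSE]
  if (nrow(enr) == 0) {
    return(tibble::tibble(
      category = character(0), n = integer(0),
      percent = numeric(0)
    ))
  }
  enr %>%
    tibble::as_tibble() %>%
    dplyr::left_join(category_map, by = c(group_id = "protein_id")) %>%
    dplyr::mutate(category = dplyr::coalesce(.data$category, "other")) %>%
    dplyr::count(.data$category, name = "n") %>%
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) %>%
    dplyr::arrange(dplyr::desc(.data$n), .data$category)
}

#' Overlap of detected proteins with a marker list
#'
#' Counts how many marker identifiers (accessions or gene symbols) are present
#' among the detected proteins; matching is case-insensitive.
#'
#' @param detected_proteins Character vector of detected identifiers.
#' @param marker_list Non-empty character vector of marker identifiers.
#'
#' @return List with `n_detected` (count of markers present) and `missing`
#'   (markers not found).
#' @export
marker_overlap <- function(detected_proteins, marker_list) {
  if (length(marker_list) == 0) rlang::abort("`marker_list` is empty")
  det <- toupper(detected_proteins)
  hit <- toupper(marker_list) %in% det
  list(n_detected = sum(hit), missing = marker_list[!hit])
}
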