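# Seeded synthetic-data generators with recorded ground truth: homologous
# proteome pairs, xenograft peptide-evidence runs with planted transferred
# proteins, spectral-count matrices with planted effects, and spatial point
# patterns with tunable niche attraction. Every generator is a pure function
# of its configuration (seed included).

#' Simulation configuration
#'
#' Bundles all generator parameters with defaults mirroring a desk-scale
#' xenograft MS experiment: ~1,900 conserved ortholog pairs plus ~120
#' host-detectable and 120 graft-specific proteins, log-normal protein
#' abundances spanning several decades, logistic abundance-dependent peptide
#' detection, multiplicative intensity noise, and a handful of host proteins
#' planted at high abundance in the graft cells.
#'
#' @param seed Integer master seed.
#' @param n_conserved Number of conserved (orthologous) protein pairs.
#' @param n_host_specific,n_graft_specific Species-specific protein counts.
#' @param substitution_rate Per-residue substitution probability between the
#'   two copies of a conserved pair (default 0.12, i.e. ~88% identity as for
#'   typical human-mouse orthologs).
#' @param length_meanlog,length_sdlog Log-normal protein length parameters
#'   (residues); defaults centre the median near 350 residues.
#' @param host_tag,graft_tag Species tags (defaults `"mouse"`, `"human"`).
#' @param n_transferred Host proteins planted in the graft sample.
#' @param transfer_abundance_multiplier Planted abundance as a fold over the
#'   median graft abundance (default 8).
#' @param abundance_sigma Log-normal sd of graft protein abundance (natural
#'   log units; default 2, ~3.5 decades across +/- 2 sd).
#' @param host_background_fraction Residual host material in the graft
#'   sample as a fraction of the median graft abundance (default 0.015);
#'   `0` means non-transferred host proteins are entirely absent.
#' @param host_background_sigma Log-normal sd (natural log) of the host
#'   background abundances (default 0.7, a narrow band emulating the
#'   detectability-truncated tail of a contaminant proteome).
#' @param detection_slope,detection_midpoint Logistic peptide detection
#'   versus log10 abundance: detection probability
#'   `plogis(slope * (log10(a) - log10(midpoint)))`.
#' @param intensity_cv Multiplicative (log-normal) intensity noise
#'   coefficient of variation.
#' @param counts_n_proteins,counts_n_per_group,counts_meanlog,counts_sdlog,
#'   counts_nb_size,counts_effect_fraction,counts_effect_log2fc,
#'   counts_dropout_midpoint,counts_dropout_slope Spectral-count simulation:
#'   negative-binomial counts for a two-group design with planted log2
#'   effects (half up, half down) and abundance-dependent dropout.
#' @param field Rectangular field size in micrometres, `c(width, height)`.
#' @param n_reference,n_query,n_background Spatial point counts.
#' @param attraction_scale Attraction length scale lambda in micrometres:
#'   query points are accepted with probability `exp(-d_nn / lambda)` where
#'   `d_nn` is the distance to the nearest reference; `Inf` gives complete
#'   spatial randomness.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_conserved = 1900L,
                       n_host_specific = 120L,
                       n_graft_specific = 120L,
                       substitution_rate = 0.12,
                       length_meanlog = log(350),
                       length_sdlog = 0.35,
                       host_tag = "mouse",
                       graft_tag = "human",
                       n_transferred = 8L,
                       transfer_abundance_multiplier = 8,
                       abundance_sigma = 2,
                       host_background_fraction = 0.015,
                       host_background_sigma = 0.7,
                       detection_slope = 2.5,
                       detection_midpoint = 0.5,
                       intensity_cv = 0.3,
                       counts_n_proteins = 1000L,
                       counts_n_per_group = 3L,
                       counts_meanlog = log(30),
                       counts_sdlog = 1,
                       counts_nb_size = 4,
                       counts_effect_fraction = 0,
                       counts_effect_log2fc = 2,
                       counts_dropout_midpoint = 4,
                       counts_dropout_slope = 1.5,
                       field = c(500, 500),
                       n_reference = 40L,
                       n_query = 200L,
                       n_background = 1000L,
                       attraction_scale = 25) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_conserved >= 0, cfg$n_host_specific >= 0, cfg$n_graft_specific >= 0,
    cfg$substitution_rate >= 0, cfg$substitution_rate <= 1,
    cfg$n_transferred >= 0, cfg$transfer_abundance_multiplier > 0,
    cfg$host_background_fraction >= 0, cfg$attraction_scale > 0,
    cfg$counts_effect_fraction >= 0, cfg$counts_effect_fraction <= 1
  )
  structure(cfg, class = "sim_config")
}

random_protein <- function(length_meanlog, length_sdlog) {
  for (try in 1:100) {
    len <- round(stats::rlnorm(1, length_meanlog, length_sdlog))
    if (len >= 1) {
      return(paste(
        sample(names(AA_FREQ), len, replace = TRUE, prob = AA_FREQ),
        collapse = ""
      ))
    }
  }
  rlang::abort("failed to draw a protein of positive length in 100 tries")
}

mutate_sequence <- function(sequence, rate) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(res)) < rate
  if (any(hit)) {
    res[hit] <- vapply(res[hit], function(a) {
      sample(setdiff(AA_ALPHABET, a), 1)
    }, character(1))
  }
  paste(res, collapse = "")
}

#' Generate a pair of homologous proteomes with ground truth
#'
#' Conserved pairs are built by drawing a sequence from empirical amino-acid
#' background frequencies and applying independent per-residue substitutions
#' (uniform over the other 19 residues, no indels) to create the ortholog;
#' species-specific proteins are drawn independently.
#'
#' @param config A [sim_config()].
#' @return List with `proteome_host`, `proteome_graft` (proteome tibbles) and
#'   `truth` (per protein: `species`, `protein_id`, `kind`, `ortholog_id`).
#' @export
make_proteomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    draw <- function(n) {
      vapply(
        seq_len(n),
        function(i) random_protein(config$length_meanlog, config$length_sdlog),
        character(1)
      )
    }
    cons_graft <- draw(config$n_conserved)
    cons_host <- vapply(cons_graft, mutate_sequence,
      character(1),
      rate = config$substitution_rate,
      USE.NAMES = FALSE
    )
    host_spec <- draw(config$n_host_specific)
    graft_spec <- draw(config$n_graft_specific)

    cons_id <- sprintf("C%05d", seq_len(config$n_conserved))
    proteome_graft <- tibble::tibble(
      species = config$graft_tag,
      protein_id = c(
        paste0(cons_id, "_", config$graft_tag),
        sprintf("G%05d_%s", seq_len(config$n_graft_specific), config$graft_tag)
      ),
      sequence = c(cons_graft, graft_spec)
    )
    proteome_host <- tibble::tibble(
      species = config$host_tag,
      protein_id = c(
        paste0(cons_id, "_", config$host_tag),
        sprintf("H%05d_%s", seq_len(config$n_host_specific), config$host_tag)
      ),
      sequence = c(cons_host, host_spec)
    )
    truth <- dplyr::bind_rows(
      tibble::tibble(
        species = config$graft_tag,
        protein_id = proteome_graft$protein_id,
        kind = rep(c("conserved", "graft_specific"),
          c(config$n_conserved, config$n_graft_specific)
        ),
        ortholog_id = c(paste0(cons_id, "_", config$host_tag),
          rep(NA_character_, config$n_graft_specific)
        )
      ),
      tibble::tibble(
        species = config$host_tag,
        protein_id = proteome_host$protein_id,
        kind = rep(c("conserved", "host_specific"),
          c(config$n_conserved, config$n_host_specific)
        ),
        ortholog_id = c(paste0(cons_id, "_", config$graft_tag),
          rep(NA_character_, config$n_host_specific)
        )
      )
    )
    list(
      proteome_host = proteome_host,
      proteome_graft = proteome_graft,
      truth = truth
    )
  })
}

#' Simulate a xenograft label-free MS run with planted transferred proteins
#'
#' Graft proteins receive log-normal abundances (median 1). `n_transferred`
#' host proteins, sampled from the host-specific pool, are planted at
#' `transfer_abundance_multiplier` times the median graft abundance; the
#' remaining host proteins are present at
#' `host_background_fraction` times their own narrow log-normal draw
#' (residual stromal carry-over), or entirely absent when that fraction is 0.
#' Each observable fully cleaved peptide of a present protein is detected
#' with logistic probability in log10 abundance; a detected peptide's
#' intensity is the protein abundance times multiplicative log-normal noise,
#' and peptides shared between present proteins are emitted once with summed
#' contributions.
#'
#' @param config A [sim_config()]; `config$seed` drives the run.
#' @param proteomes Output of [make_proteomes()].
#' @param library A `peptide_library` built from the two proteomes.
#' @param seed Optional seed overriding `config$seed` (lets one proteome/
#'   library pair serve many evidence replicates).
#'
#' @return List with `evidence` (tibble: `peptide`, `intensity`, `sample_id`)
#'   and `truth` (per protein: presence, true abundance, transferred flag;
#'   plus attribute-free `peptide_truth` mapping evidence rows to source
#'   proteins).
#' @export
simulate_xenograft <- function(config, proteomes, library, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(library, "peptide_library"))
  seed <- seed %||% config$seed
  host_spec_ids <- proteomes$truth$protein_id[
    proteomes$truth$kind == "host_specific"
  ]
  if (config$n_transferred > length(host_spec_ids)) {
    rlang::abort("n_transferred exceeds the host-specific protein pool")
  }
  withr::with_seed(seed, {
    graft <- proteomes$proteome_graft
    abund_graft <- stats::rlnorm(nrow(graft), 0, config$abundance_sigma)
    med <- stats::median(abund_graft)

    transferred <- sample(host_spec_ids, config$n_transferred)
    host <- proteomes$proteome_host
    abund_host <- rep(0, nrow(host))
    is_spec <- host$protein_id %in% host_spec_ids
    if (config$host_background_fraction > 0) {
      abund_host[is_spec] <- config$host_background_fraction * med *
        stats::rlnorm(sum(is_spec), 0, config$host_background_sigma)
    }
    abund_host[host$protein_id %in% transferred] <-
      config$transfer_abundance_multiplier * med

    pid <- c(graft$protein_id, host$protein_id)
    prot <- tibble::tibble(
      species = c(graft$species, host$species),
      protein_id = pid,
      abundance = c(abund_graft, abund_host),
      transferred = pid %in% transferred
    )
    present <- prot[prot$abundance > 0, , drop = FALSE]

    obs_pep <- library$parents %>%
      dplyr::filter(.data$n_missed == 0) %>%
      dplyr::semi_join(
        library$peptides[library$peptides$observable, "il_key"],
        by = "il_key"
      ) %>%
      dplyr::inner_join(present, by = c("species", "protein_id"))

    p_detect <- stats::plogis(config$detection_slope *
      (log10(obs_pep$abundance) - log10(config$detection_midpoint)))
    detected <- stats::runif(nrow(obs_pep)) < p_detect
    hits <- obs_pep[detected, , drop = FALSE]
    sdlog_noise <- sqrt(log(1 + config$intensity_cv^2))
    hits$intensity <- hits$abundance *
      stats::rlnorm(nrow(hits), 0, sdlog_noise)

    seq_lookup <- library$peptides[, c("il_key", "sequence")]
    evidence <- hits %>%
      dplyr::group_by(.data$il_key) %>%
      dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") %>%
      dplyr::left_join(seq_lookup, by = "il_key") %>%
      dplyr::transmute(
        peptide = .data$sequence, intensity = .data$intensity,
        sample_id = "S1"
      ) %>%
      dplyr::arrange(.data$peptide)

    peptide_truth <- hits %>%
      dplyr::select("il_key", "species", "protein_id") %>%
      dplyr::arrange(.data$il_key, .data$species, .data$protein_id)

    truth <- prot %>%
      dplyr::mutate(present = .data$abundance > 0) %>%
      dplyr::left_join(
        dplyr::count(hits, .data$species, .data$protein_id,
          name = "n_detected_peptides"
        ),
        by = c("species", "protein_id")
      ) %>%
      dplyr::mutate(n_detected_peptides = dplyr::coalesce(.data$n_detected_peptides, 0L))

    list(evidence = evidence, truth = truth, peptide_truth = peptide_truth)
  })
}

#' Simulate a spectral-count matrix with planted group effects
#'
#' Negative-binomial counts for a two-group design. A
#' `counts_effect_fraction` of proteins receive a log2 effect of
#' `counts_effect_log2fc` in the second group (alternating sign), and
#' low-abundance observations drop out with logistic probability, mimicking
#' missingness of weak spectral counts.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return List with `counts` (matrix), `groups` (per-sample labels) and
#'   `truth` (per protein: `effect`, `true_log2fc`, baseline mean).
#' @export
simulate_counts <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  withr::with_seed(seed, {
    np <- config$counts_n_proteins
    ns <- config$counts_n_per_group
    mu0 <- stats::rlnorm(np, config$counts_meanlog, config$counts_sdlog)
    n_eff <- round(config$counts_effect_fraction * np)
    effect <- rep(FALSE, np)
    true_lfc <- rep(0, np)
    if (n_eff > 0) {
      idx <- sample.int(np, n_eff)
      effect[idx] <- TRUE
      true_lfc[idx] <- config$counts_effect_log2fc *
        rep_len(c(1, -1), n_eff)
    }
    groups <- rep(c("A", "B"), each = ns)
    mu <- cbind(
      matrix(mu0, np, ns),
      matrix(mu0 * 2^true_lfc, np, ns)
    )
    counts <- matrix(
      stats::rnbinom(np * 2 * ns, mu = mu, size = config$counts_nb_size),
      np, 2 * ns
    )
    p_keep <- stats::plogis(config$counts_dropout_slope *
      (log2(mu + 1) - log2(config$counts_dropout_midpoint)))
    dropped <- matrix(stats::runif(length(mu)) > p_keep, np, 2 * ns)
    counts[dropped] <- 0L
    rownames(counts) <- sprintf("protein_%04d", seq_len(np))
    colnames(counts) <- paste0(groups, rep(seq_len(ns), 2))
    list(
      counts = counts, groups = groups,
      truth = tibble::tibble(
        protein_id = rownames(counts),
        baseline_mean = mu0, effect = effect, true_log2fc = true_lfc
      )
    )
  })
}

#' Simulate a spatial point pattern with optional niche attraction
#'
#' Reference and background cells are uniform in the rectangular field
#' (complete spatial randomness). Query cells are either uniform
#' (`attraction_scale = Inf`) or drawn by rejection sampling with acceptance
#' probability `exp(-d_nn / attraction_scale)` toward the reference cells.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @param max_tries Rejection-sampling budget per accepted query point on
#'   average (default 1000); exceeding it aborts with guidance to increase
#'   `attraction_scale` or reference density.
#' @return List with `points` (tibble: `id`, `x`, `y`, `class`) and `truth`
#'   (the generative class and acceptance model per point).
#' @export
simulate_points <- function(config, seed = NULL, max_tries = 1000) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  withr::with_seed(seed, {
    fx <- config$field[1]
    fy <- config$field[2]
    runifxy <- function(n) {
      tibble::tibble(x = stats::runif(n, 0, fx), y = stats::runif(n, 0, fy))
    }
    ref <- runifxy(config$n_reference)
    bg <- runifxy(config$n_background)
    lambda <- config$attraction_scale
    if (is.finite(lambda)) {
      qx <- numeric(0)
      qy <- numeric(0)
      tries <- 0
      budget <- max_tries * config$n_query
      while (length(qx) < config$n_query) {
        need <- config$n_query - length(qx)
        prop <- runifxy(max(need * 4L, 64L))
        tries <- tries + nrow(prop)
        if (tries > budget) {
          rlang::abort(paste(
            "rejection sampling budget exceeded;",
            "increase `attraction_scale`, `n_reference`, or `max_tries`"
          ))
        }
        d <- nn_dist_xy(prop$x, prop$y, ref$x, ref$y)
        acc <- stats::runif(nrow(prop)) < exp(-d / lambda)
        qx <- c(qx, prop$x[acc])
        qy <- c(qy, prop$y[acc])
      }
      qry <- tibble::tibble(x = qx[seq_len(config$n_query)], y = qy[seq_len(config$n_query)])
    } else {
      qry <- runifxy(config$n_query)
    }
    pts <- dplyr::bind_rows(
      dplyr::mutate(ref, class = "reference"),
      dplyr::mutate(qry, class = "query"),
      dplyr::mutate(bg, class = "background")
    )
    pts <- tibble::tibble(
      id = sprintf("pt%05d", seq_len(nrow(pts))),
      x = pts$x, y = pts$y, class = pts$class
    )
    list(
      points = pts,
      truth = tibble::tibble(
        id = pts$id, class = pts$class,
        attraction_scale = ifelse(pts$class == "query", lambda, Inf)
      )
    )
  })
}
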