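# Niche-proximity statistics on 2-D cell coordinates: nearest-neighbor
# distances, two-sample Kolmogorov-Smirnov and Anderson-Darling tests, and the
# query-vs-background proximity report.

validate_points <- function(points) {
  req <- c("id", "x", "y", "class")
  missing_cols <- setdiff(req, names(points))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf(
      "point table lacks column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(!is.finite(points$x)) || any(!is.finite(points$y))) {
    rlang::abort("non-finite coordinates in point table")
  }
  tibble::as_tibble(points)
}

#' Nearest-neighbor distances between two point classes
#'
#' Euclidean distance from each point of `from_class` to its nearest point of
#' `to_class`, in the coordinate units of the table (micrometres for imaging
#' data). Output order is deterministic (by point id).
#'
#' @param points Tibble with columns `id`, `x`, `y`, `class`.
#' @param from_class,to_class Class labels (e.g. `"query"`, `"reference"`).
#'
#' @return Tibble (`id`, `distance`) with one row per `from_class` point.
#' @export
nn_distances <- function(points, from_class = "query", to_class = "reference") {
  points <- validate_points(points)
  from <- points[points$class == from_class, , drop = FALSE]
  to <- points[points$class == to_class, , drop = FALSE]
  if (nrow(from) == 0 || nrow(to) == 0) {
    rlang::abort(sprintf(
      "empty class: %s",
      paste(c(from_class, to_class)[c(nrow(from) == 0, nrow(to) == 0)], collapse = ", ")
    ))
  }
  from <- from[order(from$id), , drop = FALSE]
  tibble::tibble(
    id = from$id,
    distance = nn_dist_xy(from$x, from$y, to$x, to$y)
  )
}

# Chunked vectorised nearest-neighbor distances (keeps the distance block
# below ~8e6 doubles regardless of input size).
nn_dist_xy <- function(x1, y1, x2, y2) {
  n <- length(x1)
  out <- numeric(n)
  chunk <- max(1L, floor(8e6 / length(x2)))
  for (s in seq(1L, n, by = chunk)) {
    i <- s:min(n, s + chunk - 1L)
    d2 <- outer(x1[i], x2, "-")^2 + outer(y1[i], y2, "-")^2
    out[i] <- sqrt(do.call(pmin, as.data.frame(d2)))
  }
  out
}

# Two-sample KS statistic D = sup |ECDF1 - ECDF2|, tie-safe.
ks_stat <- function(x, y) {
  m <- length(x)
  n <- length(y)
  w <- c(x, y)
  ord <- order(w)
  steps <- cumsum(ifelse(ord <= m, 1 / m, -1 / n))
  ws <- w[ord]
  # evaluate only where the next combined value differs (tie groups collapse)
  last_of_run <- c(ws[-1] != ws[-length(ws)], TRUE)
  max(abs(steps[last_of_run]))
}

# Tie-safe two-sample Anderson-Darling statistic: discrete version of
# A2 = mn/N * integral (F - G)^2 / (H (1 - H)) dH over the combined ECDF H,
# summed at the distinct combined values with H < 1. Equals the classical
# rank formula when there are no ties.
ad_stat <- function(x, y) {
  m <- length(x)
  n <- length(y)
  N <- m + n
  z <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(z)
  Gy <- stats::ecdf(y)(z)
  H <- (m * Fx + n * Gy) / N
  h <- diff(c(0, H)) # mass of H at each distinct value
  keep <- H < 1
  (m * n / N) * sum(((Fx - Gy)^2 / (H * (1 - H)) * h)[keep])
}

perm_pvalue <- function(stat_fun, x, y, n_perm, seed) {
  obs <- stat_fun(x, y)
  m <- length(x)
  w <- c(x, y)
  count <- withr::with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(w), m)
      if (stat_fun(w[idx], w[-idx]) >= obs - 1e-12) hits <- hits + 1L
    }
    hits
  })
  (1 + count) / (n_perm + 1)
}

#' Two-sample Kolmogorov-Smirnov test with permutation p-value
#'
#' Computes `D = sup |ECDF1 - ECDF2|`, the asymptotic p-value from the KS
#' limiting distribution, and a seeded permutation p-value from label
#' shuffles (`p = (1 + #{D* >= D}) / (n_perm + 1)`).
#'
#' @param sample1,sample2 Numeric vectors (each of length >= 2).
#' @param n_perm Number of permutations (default 10000); `0` skips the
#'   permutation p-value.
#' @param seed Seed for the permutation shuffles.
#'
#' @return One-row tibble: `statistic`, `p_asymptotic`, `p_permutation`,
#'   `n1`, `n2`, `n_perm`.
#' @export
ks_two_sample <- function(sample1, sample2, n_perm = 10000, seed = 1L) {
  if (length(sample1) < 2 || length(sample2) < 2) {
    rlang::abort("each sample needs >= 2 observations")
  }
  D <- ks_stat(sample1, sample2)
  p_asym <- suppressWarnings(
    stats::ks.test(sample1, sample2, exact = FALSE)$p.value
  )
  p_perm <- if (n_perm > 0) {
    perm_pvalue(ks_stat, sample1, sample2, n_perm, seed)
  } else {
    NA_real_
  }
  tibble::tibble(
    statistic = D, p_asymptotic = p_asym, p_permutation = p_perm,
    n1 = length(sample1), n2 = length(sample2), n_perm = n_perm
  )
}

#' Two-sample Anderson-Darling test with permutation p-value
#'
#' Rank-based two-sample Anderson-Darling statistic (the ECDF-integral form,
#' which weights tail discrepancies more heavily than KS) with a seeded
#' permutation p-value. The comparison-of-two-samples reading is used
#' throughout: the test asks whether the two distance distributions differ,
#' not whether either is normal.
#'
#' @inheritParams ks_two_sample
#' @return One-row tibble: `statistic` (A^2), `p_permutation`, `n1`, `n2`,
#'   `n_perm`.
#' @export
ad_two_sample <- function(sample1, sample2, n_perm = 10000, seed = 1L) {
  if (length(sample1) < 2 || length(sample2) < 2) {
    rlang::abort("each sample needs >= 2 observations")
  }
  tibble::tibble(
    statistic = ad_stat(sample1, sample2),
    p_permutation = if (n_perm > 0) {
      perm_pvalue(ad_stat, sample1, sample2, n_perm, seed)
    } else {
      NA_real_
    },
    n1 = length(sample1), n2 = length(sample2), n_perm = n_perm
  )
}

#' Niche-proximity test of query cells against reference cells
#'
#' Computes nearest-neighbor distances from query cells to reference (niche)
#' cells and from matched background cells to the same references, then
#' compares the two distance distributions by two-sample KS and
#' Anderson-Darling tests. Background cells are subsampled without
#' replacement to the query count (seeded); if there are fewer background
#' than query cells, all are used with a warning. A left shift of the query
#' distances (negative median difference) indicates attraction of query
#' cells to the niche.
#'
#' @param points Tibble (`id`, `x`, `y`, `class`) with classes `query`,
#'   `reference`, `background`.
#' @param n_perm Permutations for both tests (default 10000).
#' @param seed Seed controlling the background subsample and the permutation
#'   shuffles.
#'
#' @return A `proximity_test` object. [generics::tidy()] gives one row per
#'   test, [generics::glance()] a one-row summary including the median
#'   difference in micrometres, [ggplot2::autoplot()] the two ECDFs.
#' @export
proximity_test <- function(points, n_perm = 10000, seed = 1L) {
  points <- validate_points(points)
  for (cl in c("query", "reference", "background")) {
    if (!any(points$class == cl)) {
      rlang::abort(sprintf("class '%s' missing from point table", cl))
    }
  }
  dq <- nn_distances(points, "query", "reference")$distance
  db_all <- nn_distances(points, "background", "reference")$distance
  if (length(db_all) < length(dq)) {
    rlang::warn("fewer background than query cells; using all background cells")
    db <- db_all
  } else {
    db <- withr::with_seed(seed, sample(db_all, length(dq)))
  }
  ks <- ks_two_sample(dq, db, n_perm = n_perm, seed = seed)
  ad <- ad_two_sample(dq, db, n_perm = n_perm, seed = seed)
  structure(
    list(
      distances = tibble::tibble(
        class = rep(c("query", "background"), c(length(dq), length(db))),
        distance = c(dq, db)
      ),
      ks = ks, ad = ad,
      median_difference = stats::median(dq) - stats::median(db),
      n_query = length(dq), n_background = length(db),
      n_reference = sum(points$class == "reference"),
      n_perm = n_perm, seed = seed
    ),
    class = "proximity_test"
  )
}

#' @export
print.proximity_test <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<proximity_test> %d query vs %d background cells, %d reference cells\n",
      "  KS D = %.3f (perm p = %.2g), AD A2 = %.3f (perm p = %.2g)\n",
      "  median(query) - median(background) = %.1f um\n"
    ),
    x$n_query, x$n_background, x$n_reference,
    x$ks$statistic, x$ks$p_permutation, x$ad$statistic, x$ad$p_permutation,
    x$median_difference
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.proximity_test <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$ks, test = "ks", .before = 1),
    dplyr::mutate(x$ad, test = "anderson_darling", .before = 1)
  )
}

#' @exportS3Method generics::glance
glance.proximity_test <- function(x, ...) {
  tibble::tibble(
    n_query = x$n_query, n_background = x$n_background,
    n_reference = x$n_reference,
    ks_statistic = x$ks$statistic,
    ks_p_permutation = x$ks$p_permutation,
    ks_p_asymptotic = x$ks$p_asymptotic,
    ad_statistic = x$ad$statistic,
    ad_p_permutation = x$ad$p_permutation,
    median_difference = x$median_difference
  )
}

#' ECDF plot of query and background niche distances
#'
#' @param object A `proximity_test`.
#' @param ... Ignored.
#' @return A ggplot object showing the two cumulative distance distributions.
#' @exportS3Method ggplot2::autoplot
autoplot.proximity_test <- function(object, ...) {
  ggplot2::ggplot(
    object$distances,
    ggplot2::aes(x = .data$distance, colour = .data$class)
  ) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(
      x = "nearest-neighbor distance to reference cells (µm)",
      y = "cumulative frequency", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
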