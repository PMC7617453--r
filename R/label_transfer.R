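# Differential analysis of labeled nascent-proteome spectral counts and
# robust standardized log2-ratio (Zq-style) reporting.

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    idcol <- which(!vapply(counts, is.numeric, logical(1)))[1]
    if (!is.na(idcol)) {
      ids <- as.character(counts[[idcol]])
      counts <- as.matrix(counts[, -idcol, drop = FALSE])
      rownames(counts) <- ids
    } else {
      counts <- as.matrix(counts)
    }
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("protein_%04d", seq_len(nrow(counts)))
  }
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0)) {
    rlang::abort("counts must be finite and non-negative (substitute NA with 0 at load time)")
  }
  counts
}

#' Normalize a spectral-count matrix by total counts
#'
#' Scales each sample (column) so that all column totals equal the mean raw
#' column total — a total-count normalization in the spirit of "normalized
#' spectrum counts". Zeros are preserved; they keep marking missing proteins
#' for downstream imputation. The operation is idempotent.
#'
#' @param counts Proteins-by-samples matrix of non-negative spectral counts,
#'   or a data frame whose first non-numeric column holds protein ids.
#'
#' @return A real-valued matrix with equal column totals.
#' @export
normalize_counts <- function(counts) {
  m <- as_count_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    rlang::abort(sprintf(
      "all-zero sample column(s): %s",
      paste(colnames(m)[totals == 0], collapse = ", ")
    ))
  }
  sweep(m, 2, mean(totals) / totals, `*`)
}

#' Left-censored imputation of missing log2 abundances
#'
#' Replaces missing entries (`NA`) of a log2-scale matrix with draws from a
#' down-shifted normal distribution per sample:
#' `Normal(sample mean - shift * sd, (width * sd)^2)`. This mimics the usual
#' minimum-value-region imputation for left-censored label-free data
#' (defaults: shift 1.8 and width 0.3 standard deviations).
#'
#' @param log2_mat Numeric matrix on log2 scale with `NA` marking missing
#'   values (zeros must be converted to `NA` beforehand; see
#'   [moderated_test()] which handles this).
#' @param shift,width Down-shift and width of the imputation distribution in
#'   units of the per-sample standard deviation.
#' @param seed Integer seed; the draw is fully reproducible and the caller's
#'   RNG state is left untouched.
#'
#' @return The matrix with missing entries imputed.
#' @export
impute_missing <- function(log2_mat, shift = 1.8, width = 0.3, seed = 1L) {
  stopifnot(is.matrix(log2_mat))
  miss <- is.na(log2_mat)
  if (!any(miss)) {
    return(log2_mat)
  }
  n_obs <- colSums(!miss)
  if (any(n_obs < 2)) {
    rlang::abort(sprintf(
      "sample(s) with fewer than 2 observed values: %s",
      paste(colnames(log2_mat)[n_obs < 2], collapse = ", ")
    ))
  }
  withr::with_seed(seed, {
    for (j in seq_len(ncol(log2_mat))) {
      mj <- miss[, j]
      if (!any(mj)) next
      mu <- mean(log2_mat[!mj, j])
      sd_j <- stats::sd(log2_mat[!mj, j])
      log2_mat[mj, j] <- stats::rnorm(sum(mj), mu - shift * sd_j, width * sd_j)
    }
  })
  log2_mat
}

#' Moderated t-test between two groups of samples
#'
#' Empirical-Bayes moderated two-sample t-test on (optionally normalized,
#' log2-transformed, imputed) spectral counts. Per-protein residual variances
#' are shrunk toward a common prior by a method-of-moments fit of a scaled
#' inverse-chi-square distribution to the observed variances (matching the
#' moments of log variances against a log-F distribution), and the t statistic
#' gains the prior degrees of freedom. When the fit is degenerate (variance of
#' log variances at or below its sampling floor, or too few proteins) the test
#' falls back to the ordinary t-test and flags it.
#'
#' @param counts Proteins-by-samples count matrix (or data frame; see
#'   [normalize_counts()]).
#' @param groups Character/factor vector of group labels, one per sample.
#' @param contrast Length-2 character vector `c(A, B)`; log2 fold changes are
#'   reported as `A - B`.
#' @param normalize,impute Run total-count normalization and left-censored
#'   imputation first (defaults `TRUE`).
#' @param shift,width Imputation parameters, see [impute_missing()].
#' @param seed Seed for the imputation draw.
#' @param prior_df Optional fixed prior degrees of freedom overriding the
#'   method-of-moments estimate (`0` gives the ordinary t-test, `Inf` the
#'   pooled-variance z-like limit); mainly for numerical checks.
#'
#' @return A `moderated_fit` object. [generics::tidy()] returns the
#'   per-protein table (`protein_id`, `log2FC`, `t`, `df`, `p_value`,
#'   `q_value`, `imputed_fraction_a`, `imputed_fraction_b`);
#'   [generics::glance()] the fit summary (prior df, prior variance, fallback
#'   flag); [ggplot2::autoplot()] a volcano plot.
#' @export
moderated_test <- function(counts, groups, contrast, normalize = TRUE,
                           impute = TRUE, shift = 1.8, width = 0.3,
                           seed = 1L, prior_df = NULL) {
  m <- as_count_matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) {
    rlang::abort("`groups` must have one label per sample column")
  }
  if (length(contrast) != 2 || !all(contrast %in% groups)) {
    rlang::abort(sprintf(
      "contrast groups not found among group labels (%s)",
      paste(unique(groups), collapse = ", ")
    ))
  }
  keep <- groups %in% contrast
  m <- m[, keep, drop = FALSE]
  groups <- groups[keep]
  n1 <- sum(groups == contrast[1])
  n2 <- sum(groups == contrast[2])
  if (n1 < 2 || n2 < 2) rlang::abort("need >= 2 samples per group")

  if (normalize) m <- normalize_counts(m)
  lm2 <- log2(m)
  lm2[!is.finite(lm2)] <- NA # zeros are missing markers
  miss <- is.na(lm2)
  if (impute) {
    lm2 <- impute_missing(lm2, shift = shift, width = width, seed = seed)
  } else {
    lm2[is.na(lm2)] <- 0
  }

  i1 <- groups == contrast[1]
  i2 <- groups == contrast[2]
  mean1 <- rowMeans(lm2[, i1, drop = FALSE])
  mean2 <- rowMeans(lm2[, i2, drop = FALSE])
  lfc <- mean1 - mean2
  df_res <- n1 + n2 - 2
  ss <- rowSums((lm2[, i1, drop = FALSE] - mean1)^2) +
    rowSums((lm2[, i2, drop = FALSE] - mean2)^2)
  s2 <- ss / df_res

  if (is.null(prior_df)) {
    fit <- fit_scaled_invchisq(s2, df_res)
  } else {
    fit <- list(
      df_prior = prior_df,
      var_prior = if (is.finite(prior_df) && prior_df == 0) NA_real_ else mean(s2),
      fallback = FALSE
    )
  }
  if (fit$fallback || (is.finite(fit$df_prior) && fit$df_prior <= 0)) {
    s2_post <- s2
    df_total <- rep(df_res, length(s2))
    fit$fallback <- TRUE
    fit$df_prior <- 0
  } else if (!is.finite(fit$df_prior)) {
    s2_post <- rep(fit$var_prior, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (fit$df_prior * fit$var_prior + df_res * s2) /
      (fit$df_prior + df_res)
    df_total <- rep(fit$df_prior + df_res, length(s2))
  }

  tstat <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[!is.finite(tstat)] <- 1
  q <- stats::p.adjust(p, method = "BH")

  result <- tibble::tibble(
    protein_id = rownames(m),
    log2FC = unname(lfc), t = unname(tstat), df = df_total,
    p_value = unname(p), q_value = unname(q),
    imputed_fraction_a = unname(rowMeans(miss[, i1, drop = FALSE])),
    imputed_fraction_b = unname(rowMeans(miss[, i2, drop = FALSE]))
  )
  structure(
    list(
      result = result, contrast = contrast,
      df_prior = fit$df_prior, var_prior = fit$var_prior,
      df_residual = df_res, fallback = fit$fallback,
      n_samples = c(n1, n2), seed = seed
    ),
    class = "moderated_fit"
  )
}

# Method-of-moments fit of a scaled inverse-chi-square prior to observed
# sample variances: moments of log(s2) against the log-F distribution
# (Smyth-style). Returns df_prior = Inf when the spread of log variances is
# at or below the pure-sampling floor trigamma(df/2).
fit_scaled_invchisq <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10) {
    return(list(df_prior = 0, var_prior = NA_real_, fallback = TRUE))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(z)
  excess <- ev - trigamma(df / 2)
  if (!is.finite(excess)) {
    return(list(df_prior = 0, var_prior = NA_real_, fallback = TRUE))
  }
  if (excess <= 0) {
    # no evidence of variance heterogeneity: infinitely strong prior
    var_prior <- exp(mean(e))
    return(list(df_prior = Inf, var_prior = var_prior, fallback = FALSE))
  }
  df_prior <- 2 * trigamma_inverse(excess)
  var_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, var_prior = var_prior, fallback = FALSE)
}

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x) {
  if (x > 1e7) {
    return(1 / sqrt(x))
  }
  if (x < 1e-6) {
    return(1 / x)
  }
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf(
    "<moderated_fit> %s - %s | %d proteins | prior df %.2f%s\n",
    x$contrast[1], x$contrast[2], nrow(x$result), x$df_prior,
    if (x$fallback) " (degenerate prior: ordinary t fallback)" else ""
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.moderated_fit <- function(x, ...) x$result

#' @exportS3Method generics::glance
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(
    contrast = paste(x$contrast, collapse = " - "),
    n_proteins = nrow(x$result),
    df_prior = x$df_prior, var_prior = x$var_prior,
    df_residual = x$df_residual, fallback = x$fallback,
    n_significant_q05 = sum(x$result$q_value < 0.05, na.rm = TRUE)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a moderated-t fit
#'
#' @param object A `moderated_fit`.
#' @param q_cutoff Highlight proteins with BH q-value below this (default 0.05).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.moderated_fit <- function(object, q_cutoff = 0.05, ...) {
  d <- object$result
  d$significant <- d$q_value < q_cutoff
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$log2FC,
    y = -log10(.data$p_value),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = sprintf("log2 fold change (%s - %s)", object$contrast[1], object$contrast[2]),
      y = "-log10 p", colour = sprintf("q < %g", q_cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' Robust standardized log2-ratios (Zq-style)
#'
#' Standardizes protein log2-ratios to units of standard deviation using the
#' median and the scaled median absolute deviation (constant 1.4826):
#' `Zq = (x - median(x)) / (1.4826 * MAD)`. This is a robust simplification of
#' hierarchical ratio-standardization models: every output carries the
#' "Zq-style" label rather than claiming the full weighted model.
#'
#' @param log2_ratios Numeric vector with at least 3 finite values.
#'
#' @return Numeric vector of standardized ratios (attribute `label` =
#'   `"Zq-style"`).
#' @export
zq_standardize <- function(log2_ratios) {
  x <- log2_ratios
  if (sum(is.finite(x)) < 3) rlang::abort("need >= 3 finite log2-ratios")
  med <- stats::median(x[is.finite(x)])
  s <- stats::mad(x[is.finite(x)]) # constant 1.4826 built in
  if (s == 0) rlang::abort("MAD is zero; Zq undefined")
  structure((x - med) / s, label = "Zq-style")
}
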