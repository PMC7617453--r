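# Independent brute-force oracles used to validate the implementation.

# Position-scan digestion oracle: walks the sequence residue by residue,
# collects cleavage sites, then enumerates missed-cleavage concatenations.
oracle_digest <- function(sequence, max_missed, rule = "trypsin") {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cuts <- integer(0)
  for (i in seq_len(n)) {
    if (res[i] %in% c("K", "R")) {
      if (rule == "trypsin/P" || i == n || res[i + 1] != "P") {
        cuts <- c(cuts, i)
      }
    }
  }
  bounds <- sort(unique(c(cuts, n)))
  starts <- c(1L, utils::head(bounds, -1) + 1L)
  rows <- list()
  for (i in seq_along(bounds)) {
    for (k in 0:max_missed) {
      j <- i + k
      if (j <= length(bounds)) {
        rows[[length(rows) + 1]] <- data.frame(
          peptide = paste(res[starts[i]:bounds[j]], collapse = ""),
          start = starts[i], end = bounds[j], n_missed = k,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$n_missed), , drop = FALSE]
}

# Exhaustive minimal set cover size (elements = peptides, sets = proteins).
oracle_min_cover_size <- function(sets) {
  univ <- unique(unlist(sets, use.names = FALSE))
  ids <- names(sets)
  for (size in seq_along(ids)) {
    for (cb in utils::combn(ids, size, simplify = FALSE)) {
      if (all(univ %in% unlist(sets[cb], use.names = FALSE))) {
        return(size)
      }
    }
  }
  stop("no cover found")
}

# Benjamini-Hochberg from the definition: sorted p * n / rank with a
# running minimum from the largest p down.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Hypergeometric upper tail P[X >= k] by exhaustive enumeration of all
# n-subsets of an N-element universe whose first K elements are the term.
oracle_hyper_tail <- function(N, K, n, k) {
  subs <- utils::combn(N, n)
  overlaps <- colSums(subs <= K)
  mean(overlaps >= k)
}

# Classical two-sample Anderson-Darling rank formula (no ties).
oracle_ad_pettitt <- function(x, y) {
  m <- length(x)
  n <- length(y)
  N <- m + n
  w <- c(x, y)
  lab <- c(rep(1, m), rep(0, n))[order(w)]
  M <- cumsum(lab)
  i <- seq_len(N - 1)
  sum(((M[i] * N - i * m)^2) / (i * (N - i))) / (m * n)
}

# Exact permutation p-value by full enumeration of all group splits.
oracle_exact_perm_p <- function(stat_fun, x, y) {
  w <- c(x, y)
  m <- length(x)
  obs <- stat_fun(x, y)
  splits <- utils::combn(length(w), m, simplify = FALSE)
  hits <- vapply(
    splits,
    function(idx) stat_fun(w[idx], w[-idx]) >= obs - 1e-12,
    logical(1)
  )
  mean(hits)
}

random_aa_seq <- function(len) {
  paste(sample(names(xenoprot:::AA_FREQ), len,
    replace = TRUE,
    prob = xenoprot:::AA_FREQ
  ), collapse = "")
}
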