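#' @name popgen
#' @title Per-alignment population-genetic summaries
#'
#' @description
#' Summaries of within-population variation for one locus alignment or a
#' multi-locus concatenation: segregating sites, Watterson's theta (reported
#' per region, not per site), the mean and variance of pairwise differences,
#' the Hudson-Kaplan lower bound on the number of recombination events
#' (Rmin), and a moment estimate of the population recombination rate 4Ner
#' from the variance of pairwise differences.
#'
#' Missing-data policy: under the default complete-deletion policy, columns
#' containing a gap, `N`, or any ambiguity letter are removed before S,
#' pairwise differences and Rmin are computed, so the infinite-sites
#' machinery only sees clean columns.  Columns with more than two states
#' count toward S but are excluded from four-gamete tests.
NULL

# Character matrix restricted to the missing-data policy.
# complete: drop any column containing a character outside A/C/G/T.
# pairwise: keep all columns; treat non-ACGT as missing within each column.
clean_matrix <- function(seqs, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  m <- seq_matrix(seqs)
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  if (policy == "complete") {
    keep <- colSums(!valid) == 0
    pos <- which(keep)
    m <- m[, keep, drop = FALSE]
  } else {
    m[!valid] <- NA_character_
    pos <- seq_len(ncol(m))
  }
  attr(m, "positions") <- pos
  m
}

as_seq_vector <- function(aln) {
  if (is.data.frame(aln)) {
    if (!all(c("record_id", "seq") %in% names(aln))) {
      abort("alignment data frame needs columns record_id and seq")
    }
    setNames(aln$seq, aln$record_id)
  } else if (is.character(aln)) {
    if (is.null(names(aln))) names(aln) <- paste0("s", seq_along(aln))
    aln
  } else {
    abort("alignment must be a data frame or a named character vector")
  }
}

#' Count segregating sites
#'
#' A column segregates when it carries at least two distinct non-missing
#' states after applying the missing-data policy.
#'
#' @param aln Alignment: a tibble with `record_id`/`seq` columns or a named
#'   character vector of equal-length sequences.
#' @param policy `"complete"` (drop columns containing gaps/N/ambiguity,
#'   default) or `"pairwise"` (ignore missing characters within each column).
#' @return Integer count of segregating sites.
#' @export
segregating_sites <- function(aln, policy = c("complete", "pairwise")) {
  seqs <- as_seq_vector(aln)
  if (length(seqs) < 2) abort("segregating_sites needs at least 2 sequences")
  m <- clean_matrix(seqs, policy)
  if (ncol(m) == 0) return(0L)
  sum(apply(m, 2, function(col) length(unique(col[!is.na(col)])) >= 2))
}

#' Watterson's theta (per region)
#'
#' `theta_W = S / sum_{i=1}^{n-1} 1/i`.  Reported per region so that values
#' are on the scale of whole-locus summaries.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences.
#' @return Numeric theta estimate.
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) abort("watterson_theta requires n >= 2")
  if (S < 0) abort("S must be non-negative")
  S / sum(1 / seq_len(n - 1))
}

#' Mean and variance of pairwise differences
#'
#' Differences are counted per unordered sequence pair on complete-deletion
#' columns; the variance uses the population (divide-by-m) convention over
#' the `m = n(n-1)/2` pairs, matching the raw second moment used by the
#' recombination-rate moment estimator.
#'
#' @inheritParams segregating_sites
#' @return Named numeric vector `c(ave_pwd, var_pwd)`.
#' @export
pairwise_diff_stats <- function(aln) {
  seqs <- as_seq_vector(aln)
  if (length(seqs) < 2) abort("pairwise_diff_stats needs at least 2 sequences")
  m <- clean_matrix(seqs, "complete")
  d <- hamming_matrix(setNames(apply(m, 1, paste, collapse = ""), names(seqs)))
  pw <- d[upper.tri(d)]
  c(ave_pwd = mean(pw), var_pwd = mean((pw - mean(pw))^2))
}

# Biallelic column indices (in cleaned-matrix coordinates) and their
# 0/1 encodings.
biallelic_sites <- function(m) {
  states <- apply(m, 2, function(col) length(unique(col)))
  idx <- which(states == 2)
  enc <- lapply(idx, function(j) as.integer(m[, j] != m[1, j]))
  list(idx = idx, enc = enc, positions = attr(m, "positions")[idx])
}

# All four gametes present at a pair of 0/1-encoded sites?
four_gametes <- function(x, y) {
  length(unique(x * 2L + y)) == 4L
}

#' Hudson-Kaplan minimum number of recombination events (Rmin)
#'
#' Applies the four-gamete test to every pair of biallelic sites (after
#' complete deletion; columns with more than two states are excluded, per
#' infinite-sites practice) and counts the maximum number of disjoint
#' incompatible intervals by the Hudson-Kaplan interval-removal scan.  Zero
#' when no site pair exhibits all four gametes.
#'
#' @inheritParams segregating_sites
#' @return Integer lower bound on the number of recombination events.
#' @export
rmin_four_gamete <- function(aln) {
  seqs <- as_seq_vector(aln)
  if (length(seqs) < 2) return(0L)
  m <- clean_matrix(seqs, "complete")
  ba <- biallelic_sites(m)
  k <- length(ba$idx)
  if (k < 2) return(0L)
  # incompatible intervals (site index pairs in alignment coordinates)
  ints <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (four_gametes(ba$enc[[i]], ba$enc[[j]])) {
        ints[[length(ints) + 1L]] <- c(ba$positions[i], ba$positions[j])
      }
    }
  }
  if (length(ints) == 0) return(0L)
  iv <- do.call(rbind, ints)
  # Hudson-Kaplan scan: greedily pick disjoint open intervals by right end
  iv <- iv[order(iv[, 2], iv[, 1]), , drop = FALSE]
  rmin <- 0L
  last_right <- -Inf
  for (r in seq_len(nrow(iv))) {
    if (iv[r, 1] >= last_right) {
      rmin <- rmin + 1L
      last_right <- iv[r, 2]
    }
  }
  rmin
}

# Hudson (1983) correlation of pair coalescence times for two sites at
# scaled crossing-over distance c.
coal_time_corr <- function(c) (c + 18) / (c^2 + 13 * c + 18)

# Average of the two-site correlation over all ordered site pairs (including
# the diagonal) of an L-site region with total map length C.
mean_site_corr <- function(C, L) {
  if (L <= 1) return(1)
  d <- seq_len(L - 1)
  (L + 2 * sum((L - d) * coal_time_corr(C * d / L))) / L^2
}

# Model expectation of the across-pair variance of pairwise differences for
# sample size n, per-region theta, region length L and per-region
# recombination rate C.  At C = 0 this reduces to the classical
# no-recombination expectation (single-pair variance theta + theta^2 minus
# Tajima's variance of the mean pairwise difference); the theta^2
# (coalescent-covariance) terms are attenuated by the mean two-site
# correlation of coalescence times under recombination.
expected_var_pwd <- function(C, theta, n, L) {
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  (1 - b1) * theta + (1 - b2) * theta^2 * mean_site_corr(C, L)
}

#' Moment estimate of the population recombination rate 4Ner
#'
#' Solves for the per-region recombination rate `C` at which the
#' model-expected across-pair variance of pairwise differences (given `n`
#' and theta estimated from the mean pairwise difference) equals the
#' observed variance.  The expectation is monotone decreasing in `C`, so the
#' solution is found by bisection; the estimate is clamped to 0 when the
#' observed variance meets or exceeds the no-recombination expectation, and
#' to the upper search bound (flagged via the `"boundary"` attribute) when
#' the observed variance lies below the expectation at the bound.
#'
#' @inheritParams segregating_sites
#' @param tol Bisection tolerance.
#' @return Numeric 4Ner per region, or flagged `NA` when there are no
#'   segregating sites.
#' @export
wakeley_moment_C <- function(aln, tol = 1e-6) {
  seqs <- as_seq_vector(aln)
  n <- length(seqs)
  if (n < 3) abort("wakeley_moment_C needs at least 3 sequences")
  S <- segregating_sites(aln)
  if (S == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no segregating sites"
    return(out)
  }
  m <- clean_matrix(seqs, "complete")
  L <- ncol(m)
  pw <- pairwise_diff_stats(aln)
  theta <- pw[["ave_pwd"]]
  v_obs <- pw[["var_pwd"]]
  if (theta <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero mean pairwise difference"
    return(out)
  }
  f <- function(C) expected_var_pwd(C, theta, n, L) - v_obs
  if (f(0) <= 0) return(0)
  upper <- 10 * theta * L
  if (f(upper) > 0) {
    out <- upper
    attr(out, "boundary") <- TRUE
    return(out)
  }
  stats::uniroot(f, c(0, upper), tol = tol)$root
}

#' Summarise one alignment or concatenation
#'
#' Fills every field of the per-region summary: `n`, `L`, `S`, Watterson's
#' theta, mean/variance of pairwise differences, Rmin, the 4Ner moment
#' estimate, and the `R/theta` range taken as the min and max of
#' `rmin/theta_w` and `r_wakeley/theta_w`.  `n_override` supports the
#' convention of quoting theta for a de-duplicated (or expanded) sequence
#' count while the column statistics come from the alignment at hand.
#'
#' @inheritParams segregating_sites
#' @param locus Label for the `locus` column of the output.
#' @param n_override Optional sequence count used in the harmonic sum of
#'   Watterson's theta in place of the alignment's own `n`.
#' @return One-row tibble (`locus`, `n`, `n_theta`, `L`, `S`, `theta_w`,
#'   `ave_pwd`, `var_pwd`, `rmin`, `r_wakeley`, `r_over_theta_low`,
#'   `r_over_theta_high`).
#' @export
summarize_popgen <- function(aln, locus = "region", n_override = NULL) {
  seqs <- as_seq_vector(aln)
  if (length(seqs) < 2) abort("summarize_popgen needs at least 2 sequences")
  n <- length(seqs)
  n_theta <- n_override %||% n
  m <- clean_matrix(seqs, "complete")
  S <- segregating_sites(aln)
  theta <- watterson_theta(S, n_theta)
  pw <- pairwise_diff_stats(aln)
  rmin <- rmin_four_gamete(aln)
  rw <- if (n >= 3 && S > 0) wakeley_moment_C(aln) else NA_real_
  ratios <- c(if (theta > 0) rmin / theta,
              if (theta > 0 && !is.na(rw)) rw / theta)
  tibble(
    locus = locus, n = n, n_theta = n_theta, L = ncol(m), S = S,
    theta_w = theta, ave_pwd = pw[["ave_pwd"]], var_pwd = pw[["var_pwd"]],
    rmin = rmin, r_wakeley = as.numeric(rw),
    r_over_theta_low = if (length(ratios)) min(ratios) else NA_real_,
    r_over_theta_high = if (length(ratios)) max(ratios) else NA_real_
  )
}

#' Per-locus and concatenation summary table
#'
#' One row per locus plus one row for the concatenation over `loci_order`,
#' mirroring the layout of whole-study recombination/mutation tables.
#'
#' @param aln Long alignment tibble (`locus`, `record_id`, `seq`).
#' @param loci_order Loci to include, in concatenation order.
#' @param concat_label Label for the concatenation row.
#' @return Tibble of [summarize_popgen()] rows.
#' @export
popgen_table <- function(aln, loci_order = unique(aln$locus),
                         concat_label = paste0("concat", length(loci_order))) {
  assert_alignment_tbl(aln)
  conc <- concat_alignment(aln, loci_order)
  rows <- map(loci_order, function(lc) {
    summarize_popgen(locus_seqs(aln, lc), locus = lc)
  })
  bind_rows(summarize_popgen(conc, locus = concat_label), bind_rows(rows))
}
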