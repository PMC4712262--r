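#' Build a PE-by-habitat contingency table
#'
#' Rows are putative ecotypes with more than `min_group` records; columns
#' are habitat labels.
#'
#' @param pe_map Tibble (`record_id`, `pe`).
#' @param metadata Tibble with `record_id` and `habitat`.
#' @param min_group Minimum records per retained PE row (default 5, i.e.
#'   groups with more than 5 sequences are kept).
#' @return Integer matrix (PE x habitat).
#' @export
habitat_contingency <- function(pe_map, metadata, min_group = 5L) {
  joined <- inner_join(pe_map, metadata, by = "record_id")
  tab <- table(joined$pe, joined$habitat)
  tab <- tab[rowSums(tab) > min_group, , drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("contingency table needs at least 2 PEs and 2 habitats after filtering")
  }
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

# log null probability of a table with fixed margins
log_table_prob <- function(m) {
  sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
    lgamma(sum(m) + 1) - sum(lgamma(m + 1))
}

#' Fisher's exact test of contingency (r x c)
#'
#' For 2x2 tables the p-value is computed by full hypergeometric
#' enumeration (two-sided: the total probability of tables, with the same
#' margins, no more probable than the observed one).  For larger tables a
#' Monte-Carlo estimate is used: `mc_reps` tables are drawn from the
#' fixed-margin null and the p-value is the fraction whose probability is
#' less than or equal to the observed table's.
#'
#' @param tab Integer matrix of counts (e.g. from [habitat_contingency()]).
#' @param mc_reps Monte-Carlo replicates for tables larger than 2x2.
#' @param seed Optional seed for the Monte-Carlo draw.
#' @return The p-value, with attribute `method` (`"exact"` or
#'   `"monte-carlo"`).
#' @export
fisher_exact_rxc <- function(tab, mc_reps = 1e5, seed = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != floor(tab))) abort("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate table: zero row or column margin")
  }
  eps <- 1e-7
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
    k <- lo:hi
    logp <- stats::dhyper(k, r1, n - r1, c1, log = TRUE)
    obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1, log = TRUE)
    p <- sum(exp(logp[logp <= obs + eps]))
    attr(p, "method") <- "exact"
    return(p)
  }
  draw <- function() {
    sims <- stats::r2dtable(mc_reps, rowSums(tab), colSums(tab))
    lp <- vapply(sims, log_table_prob, numeric(1))
    mean(lp <= log_table_prob(tab) + eps)
  }
  p <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(p, "method") <- "monte-carlo"
  p
}

#' Likelihood-ratio (G) test of independence
#'
#' `G = 2 * sum obs * ln(obs / exp)` with `(r - 1)(c - 1)` degrees of
#' freedom against the chi-square reference; zero observed cells contribute
#' nothing.
#'
#' @param tab Integer matrix of counts.
#' @return Tibble (`statistic`, `df`, `p.value`).
#' @export
g_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("G test needs at least 2 rows and 2 columns")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate table: zero row or column margin")
  }
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  terms <- ifelse(tab > 0, tab * log(tab / e), 0)
  g <- 2 * sum(terms)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  tibble(statistic = g, df = df,
         p.value = stats::pchisq(g, df, lower.tail = FALSE))
}

#' Retain high-frequency amplicon sequences
#'
#' Keeps sequences whose copy number, summed over all samples, reaches the
#' threshold (default 50 identical copies across all combined samples).
#'
#' @param reads Tibble with columns `seq` and `count` (and optionally
#'   sample/section columns, ignored for the sum).
#' @param min_copies Total-copy threshold.
#' @return Tibble (`seq`, `total_count`) of retained sequences.
#' @export
filter_high_frequency <- function(reads, min_copies = 50L) {
  if (nrow(reads) == 0) return(tibble(seq = character(0), total_count = integer(0)))
  if (any(reads$count < 1)) abort("read counts must be >= 1")
  reads |>
    group_by(.data$seq) |>
    summarise(total_count = sum(.data$count), .groups = "drop") |>
    filter(.data$total_count >= min_copies)
}

#' Correct single-base homopolymer indels against a reference
#'
#' Pyrosequencing reads carry homopolymer over- and under-calls.  Each read
#' is aligned to the supplied in-frame reference; single-base insertions in
#' the read are removed and single-base deletions are restored from the
#' reference, recovering the reading frame.  Reads with multi-base indels
#' are returned unchanged and flagged (they will fall to unassigned under
#' exact matching).
#'
#' @param reads Character vector of read sequences.
#' @param reference Reference sequence defining the reading frame.
#' @return Tibble (`seq`, `corrected`, `multi_indel`).
#' @export
correct_homopolymers <- function(reads, reference) {
  out <- map(reads, function(rd) {
    al <- Biostrings::pairwiseAlignment(rd, reference, type = "global",
                                        gapOpening = 4, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    runs <- rle(paste0(ifelse(p == "-", "D", ""), ifelse(s == "-", "I", "")))
    if (any(nchar(runs$values) > 0 & runs$lengths > 1)) {
      return(tibble(seq = rd, corrected = rd, multi_indel = TRUE))
    }
    keep <- s != "-"                  # drop single-base insertions in read
    p2 <- p[keep]; s2 <- s[keep]
    p2[p2 == "-"] <- s2[p2 == "-"]    # restore single-base deletions
    tibble(seq = rd, corrected = paste(p2, collapse = ""), multi_indel = FALSE)
  })
  bind_rows(out)
}

#' Match amplicon reads to sequence types and putative ecotypes
#'
#' Exact-match assignment within a shared, trimmed coordinate window: a
#' read identical to the (trimmed) sequences of STs belonging to exactly
#' one PE is assigned to that PE; reads matching STs of several PEs are
#' ambiguous; reads matching no ST are novel.  Both classes are reported as
#' unassigned.
#'
#' @param reads Tibble (`seq`, ...) of retained high-frequency reads.
#' @param st_seqs Tibble (`st_id`, `seq`) of ST sequences at the same locus
#'   and in the same trimmed window.
#' @param pe_map Tibble (`st_id`, `pe`).
#' @param window Optional `c(start, end)` applied to both reads and ST
#'   sequences before matching.
#' @return The `reads` tibble with added `pe` (NA when unassigned) and
#'   `match_status` (`"assigned"`/`"ambiguous"`/`"novel"`).
#' @export
match_reads_to_pes <- function(reads, st_seqs, pe_map, window = NULL) {
  trim <- function(x) {
    if (is.null(window)) x else substr(x, window[1], window[2])
  }
  st_tbl <- st_seqs |>
    mutate(key = trim(toupper(.data$seq))) |>
    inner_join(pe_map, by = "st_id")
  lookup <- st_tbl |>
    group_by(.data$key) |>
    summarise(pes = list(unique(.data$pe)), .groups = "drop")
  pes_of <- setNames(lookup$pes, lookup$key)
  keys <- trim(toupper(reads$seq))
  hit <- pes_of[keys]
  status <- vapply(hit, function(p) {
    if (is.null(p) || all(is.na(p))) "novel"
    else if (length(p) > 1) "ambiguous"
    else "assigned"
  }, character(1))
  pe <- vapply(seq_along(hit), function(i) {
    if (status[i] == "assigned") hit[[i]] else NA_character_
  }, character(1))
  mutate(reads, pe = pe, match_status = unname(status))
}

#' Depth-resolved relative abundance profiles per PE
#'
#' For every PE and depth section, the fraction of assigned high-frequency
#' read copies belonging to the PE is computed per replicate core; the
#' profile reports the across-replicate mean and standard error
#' (`sd / sqrt(n_rep)`).  Ambiguous and novel reads are excluded from the
#' denominator; their overall fraction is reported via the
#' `unassigned_fraction` attribute.  Sections with no assigned reads in any
#' replicate are flagged.
#'
#' @param assignments Output of [match_reads_to_pes()] joined with per-read
#'   sampling columns `depth_section`, `replicate` and `count`.
#' @return Tibble (`pe`, `depth_section`, `mean_fraction`, `se`, `n_reads`,
#'   `flagged`).
#' @export
depth_profiles <- function(assignments) {
  need <- c("pe", "match_status", "depth_section", "replicate", "count")
  if (!all(need %in% names(assignments))) {
    abort(paste0("assignments needs columns: ", paste(need, collapse = ", ")))
  }
  unassigned <- assignments |>
    summarise(f = sum(.data$count[.data$match_status != "assigned"]) /
                sum(.data$count)) |>
    pull(.data$f)
  asg <- filter(assignments, .data$match_status == "assigned")
  if (nrow(asg) == 0) abort("no assigned reads")
  per_rep <- asg |>
    group_by(.data$depth_section, .data$replicate) |>
    mutate(total = sum(.data$count)) |>
    group_by(.data$pe, .data$depth_section, .data$replicate) |>
    summarise(fraction = sum(.data$count) / .data$total[1],
              n_reads = sum(.data$count), .groups = "drop")
  # PEs absent from a replicate have fraction 0 there
  grid <- tidyr::expand_grid(
    pe = unique(per_rep$pe),
    distinct(asg, .data$depth_section, .data$replicate)
  )
  per_rep <- left_join(grid, per_rep, by = c("pe", "depth_section", "replicate")) |>
    mutate(fraction = tidyr::replace_na(.data$fraction, 0),
           n_reads = tidyr::replace_na(.data$n_reads, 0L))
  out <- per_rep |>
    group_by(.data$pe, .data$depth_section) |>
    summarise(
      mean_fraction = mean(.data$fraction),
      se = stats::sd(.data$fraction) / sqrt(n()),
      n_reads = sum(.data$n_reads), .groups = "drop"
    ) |>
    mutate(flagged = .data$n_reads == 0)
  attr(out, "unassigned_fraction") <- unassigned
  attr(out, "per_replicate") <- per_rep
  out
}

#' Monotone depth-trend summary per PE
#'
#' Sign of the Spearman correlation between depth section and mean
#' fraction for each PE.
#'
#' @param profiles Output of [depth_profiles()].
#' @return Tibble (`pe`, `rho`, `trend`).
#' @export
depth_trends <- function(profiles) {
  profiles |>
    group_by(.data$pe) |>
    summarise(rho = suppressWarnings(
      stats::cor(.data$depth_section, .data$mean_fraction, method = "spearman")),
      .groups = "drop") |>
    mutate(trend = case_when(
      is.na(.data$rho) ~ "flat",
      .data$rho > 0 ~ "increasing",
      .data$rho < 0 ~ "decreasing",
      TRUE ~ "flat"
    ))
}

#' One-way ANOVA of per-replicate fractions across depth sections
#'
#' @param profiles Output of [depth_profiles()] (uses its per-replicate
#'   attribute).
#' @param pe PE label to test.
#' @return Tibble (`pe`, `statistic`, `df1`, `df2`, `p.value`).
#' @export
depth_anova <- function(profiles, pe) {
  per_rep <- attr(profiles, "per_replicate")
  if (is.null(per_rep)) abort("profiles must come from depth_profiles()")
  d <- filter(per_rep, .data$pe == !!pe)
  if (nrow(d) == 0) abort(paste0("no data for PE ", pe))
  fit <- stats::aov(fraction ~ factor(depth_section), data = d)
  s <- summary(fit)[[1]]
  tibble(pe = pe, statistic = s[["F value"]][1], df1 = s[["Df"]][1],
         df2 = s[["Df"]][2], p.value = s[["Pr(>F)"]][1])
}

#' Plot depth-resolved abundance profiles
#'
#' @param profiles Output of [depth_profiles()].
#' @return A ggplot object with one line per PE and standard-error bars.
#' @export
plot_depth_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$depth_section, y = .data$mean_fraction,
                               colour = .data$pe)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_fraction - .data$se,
                                          ymax = .data$mean_fraction + .data$se)) +
    ggplot2::labs(x = "depth section (80 µm)", y = "relative abundance",
                  colour = "PE") +
    ggplot2::theme_minimal()
}
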