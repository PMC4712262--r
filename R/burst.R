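#' Number of loci at which two allelic profiles differ
#'
#' @param a,b Integer vectors of allele numbers (same length, same locus
#'   order).
#' @return Integer count of differing loci; 0 iff the profiles are identical.
#' @export
locus_diff_count <- function(a, b) {
  if (length(a) != length(b)) abort("profiles have different lengths")
  sum(a != b)
}

st_profile_matrix <- function(sts) {
  loci <- attr(sts, "loci") %||% setdiff(names(sts), c("st_id", "count", "members"))
  m <- as.matrix(sts[loci])
  rownames(m) <- sts$st_id
  storage.mode(m) <- "integer"
  m
}

# Pairwise locus-difference edges up to max_diff between STs.
slv_edges <- function(sts, max_diff = 1L) {
  prof <- st_profile_matrix(sts)
  n <- nrow(prof)
  if (n < 2) {
    return(tibble(st_a = integer(0), st_b = integer(0), locus_diff = integer(0)))
  }
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(p) sum(prof[p[1], ] != prof[p[2], ]))
  keep <- diffs <= max_diff & diffs > 0
  tibble(
    st_a = sts$st_id[pairs[1, keep]],
    st_b = sts$st_id[pairs[2, keep]],
    locus_diff = as.integer(diffs[keep])
  )
}

#' Demarcate clonal complexes by single-locus-variant linkage
#'
#' Builds the SLV graph (STs whose profiles differ at exactly one locus,
#' regardless of how many SNPs the differing locus carries), then keeps the
#' connected components that contain a consensus ST plus at least `min_slv`
#' further variants.  In relaxed (sub-clonal-complex) mode, double-locus
#' variants also link (`allow_dlv = TRUE`), so strict-mode complexes are
#' sub-partitions of relaxed-mode ones.  Complex ids are assigned by
#' decreasing component size.
#'
#' @param sts ST tibble from [build_sequence_types()].
#' @param min_slv Minimum number of non-consensus variants per complex
#'   (default 3).
#' @param allow_dlv Also link double-locus variants (relaxed mode).
#' @return Tibble (`st_id`, `count`, `cc_id`, `slv_degree`, `is_consensus`);
#'   `cc_id` is `NA` for unlinked STs.  Attributes: `edges` (tibble `st_a`,
#'   `st_b`, `locus_diff`) and `complexes` (tibble `cc_id`, `consensus_st`,
#'   `n_members`, `n_slv`, `n_dlv`).
#' @export
demarcate_clonal_complexes <- function(sts, min_slv = 3L, allow_dlv = FALSE) {
  if (min_slv < 1) abort("config error: min_slv must be >= 1")
  if (nrow(sts) == 0) abort("no STs")
  edges <- slv_edges(sts, max_diff = if (allow_dlv) 2L else 1L)
  g <- igraph::graph_from_data_frame(
    edges[c("st_a", "st_b")],
    directed = FALSE,
    vertices = data.frame(name = as.character(sts$st_id))
  )
  comp <- igraph::components(g)$membership
  comp <- comp[as.character(sts$st_id)]
  slv_deg <- vapply(sts$st_id, function(s) {
    sum((edges$st_a == s | edges$st_b == s) & edges$locus_diff == 1L)
  }, integer(1))
  sizes <- table(comp)
  keep_comp <- as.integer(names(sizes)[sizes >= min_slv + 1L])
  # order retained components by decreasing size, then smallest member st_id
  ord <- order(-as.integer(sizes[as.character(keep_comp)]),
               vapply(keep_comp, function(k) min(sts$st_id[comp == k]), numeric(1)))
  keep_comp <- keep_comp[ord]
  cc_of <- rep(NA_character_, nrow(sts))
  consensus <- rep(FALSE, nrow(sts))
  complexes <- list()
  for (i in seq_along(keep_comp)) {
    idx <- which(comp == keep_comp[i])
    cc_id <- paste0("CC-", i)
    cc_of[idx] <- cc_id
    sub <- mutate(sts[idx, ], slv_degree = slv_deg[idx], cc_id = cc_id)
    f <- predict_founder(sub)
    consensus[idx[sub$st_id == f]] <- TRUE
    dl <- edges[edges$st_a %in% sts$st_id[idx] | edges$st_b %in% sts$st_id[idx], ]
    complexes[[i]] <- tibble(
      cc_id = cc_id, consensus_st = f, n_members = length(idx),
      n_slv = sum(dl$locus_diff == 1L), n_dlv = sum(dl$locus_diff == 2L)
    )
  }
  out <- sts |>
    select("st_id", "count") |>
    mutate(cc_id = cc_of, slv_degree = slv_deg, is_consensus = consensus)
  attr(out, "edges") <- edges
  attr(out, "complexes") <- if (length(complexes)) bind_rows(complexes) else
    tibble(cc_id = character(0), consensus_st = integer(0),
           n_members = integer(0), n_slv = integer(0), n_dlv = integer(0))
  attr(out, "relaxed") <- allow_dlv
  out
}

#' Predict the founder (consensus) ST of a clonal complex
#'
#' The founder is the member with the most single-locus-variant links; ties
#' are broken by the largest member count, then the lowest `st_id`.
#'
#' @param cc Tibble of complex members with columns `st_id`, `count`,
#'   `slv_degree`.
#' @return The founder `st_id`.
#' @export
predict_founder <- function(cc) {
  if (nrow(cc) == 0) abort("empty clonal complex")
  cc$st_id[order(-cc$slv_degree, -cc$count, cc$st_id)][1]
}

#' Export a population snapshot (edge list plus unlinked singletons)
#'
#' @param cc Result of [demarcate_clonal_complexes()].
#' @param edge_path,complex_path Output TSV paths.
#' @return Invisibly, a list with both tibbles.
#' @export
write_population_snapshot <- function(cc, edge_path, complex_path) {
  edges <- attr(cc, "edges")
  complexes <- attr(cc, "complexes")
  write_report_tsv(edges, edge_path)
  write_report_tsv(complexes, complex_path)
  invisible(list(edges = edges, complexes = complexes))
}

#' Plot clonal-complex membership
#'
#' Bar chart of complex sizes with the consensus ST labelled; unlinked STs
#' are collapsed into one bar.
#'
#' @param cc Result of [demarcate_clonal_complexes()].
#' @return A ggplot object.
#' @export
plot_clonal_complexes <- function(cc) {
  dat <- cc |>
    mutate(cc_id = ifelse(is.na(.data$cc_id), "unlinked", .data$cc_id)) |>
    count(.data$cc_id, wt = .data$count, name = "n_records")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cc_id, y = .data$n_records)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "clonal complex", y = "records") +
    ggplot2::theme_minimal()
}
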