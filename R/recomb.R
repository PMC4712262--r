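#' SNP profile of a variant against a dominant (reference) variant
#'
#' Compares each aligned position of the variant to the dominant variant,
#' locus by locus, and reports the position (1-based within the locus) and
#' substituted state of every mismatch.  Positions are strictly increasing
#' within each locus; the profile is empty at a locus iff the two sequences
#' are identical there.
#'
#' @param aln Long alignment tibble (`locus`, `record_id`, `seq`).
#' @param variant_id,dominant_id Record ids to compare.
#' @return Tibble (`variant_id`, `dominant_id`, `locus`, `position`,
#'   `dominant_state`, `variant_state`), zero rows when identical.
#' @export
snp_profile <- function(aln, variant_id, dominant_id) {
  assert_alignment_tbl(aln)
  loci_v <- sort(unique(aln$locus[aln$record_id == variant_id]))
  loci_d <- sort(unique(aln$locus[aln$record_id == dominant_id]))
  if (!identical(loci_v, loci_d) || length(loci_v) == 0) {
    abort("variant and dominant must be typed at the same loci")
  }
  rows <- map(loci_v, function(lc) {
    v <- toupper(aln$seq[aln$record_id == variant_id & aln$locus == lc][1])
    d <- toupper(aln$seq[aln$record_id == dominant_id & aln$locus == lc][1])
    if (nchar(v) != nchar(d)) abort(paste0("length mismatch at locus ", lc))
    vv <- strsplit(v, "")[[1]]
    dd <- strsplit(d, "")[[1]]
    pos <- which(vv != dd)
    tibble(locus = lc, position = pos, dominant_state = dd[pos], variant_state = vv[pos])
  })
  out <- bind_rows(rows)
  bind_cols(tibble(variant_id = rep(variant_id, nrow(out)),
                   dominant_id = rep(dominant_id, nrow(out))), out)
}

#' Detect putative recombination from SNP patterning
#'
#' Applies the multilocus rule that more than one SNP within any single
#' locus (relative to the dominant variant) indicates recombination rather
#' than mutation: loci carrying `>= min_snps` mismatches yield one event
#' each; loci with 0-1 mismatches yield nothing.
#'
#' @param profile SNP profile from [snp_profile()] (may cover several
#'   variants).
#' @param min_snps Minimum SNPs per locus for an event (default 2).
#' @return Event tibble (`method`, `locus`, `st_ids`, `snp_count`), one row
#'   per (variant, locus) with enough SNPs.
#' @export
detect_snp_recombination <- function(profile, min_snps = 2L) {
  if (nrow(profile) == 0) {
    return(tibble(method = character(0), locus = character(0),
                  st_ids = list(), snp_count = integer(0)))
  }
  profile |>
    group_by(.data$variant_id, .data$dominant_id, .data$locus) |>
    summarise(snp_count = n(), .groups = "drop") |>
    filter(.data$snp_count >= min_snps) |>
    mutate(method = "SNP",
           st_ids = map2(.data$variant_id, .data$dominant_id, c)) |>
    select("method", "locus", "st_ids", "snp_count")
}

#' Find SNP patterns shared across sequence types
#'
#' Groups per-locus SNP patterns that are identical (same positions and
#' substituted states) across two or more carriers.  When every carrier
#' belongs to one putative ecotype (or one clade of a supplied tree) the
#' shared pattern is consistent with a single historic event followed by
#' vertical inheritance (`clade_scope = "internal"`); otherwise the sharing
#' crosses PE boundaries and is flagged (`cross_pe = TRUE`).
#'
#' @param profiles SNP profile tibble covering several variants (rows from
#'   [snp_profile()]).
#' @param pe_map Tibble (`record_id`, `pe`) assigning carriers to putative
#'   ecotypes.
#' @param tree Optional rooted `phylo`; carriers forming a monophyletic
#'   group also count as one clade.
#' @param min_snps Only patterns with at least this many SNPs are scanned.
#' @return Event tibble (`method`, `locus`, `st_ids`, `snp_count`,
#'   `clade_scope`, `cross_pe`).
#' @export
shared_pattern_scan <- function(profiles, pe_map, tree = NULL, min_snps = 2L) {
  counted <- profiles |>
    group_by(.data$variant_id, .data$locus) |>
    summarise(
      pattern = paste(paste0(.data$position, ":", .data$variant_state), collapse = ";"),
      snp_count = n(), .groups = "drop"
    ) |>
    filter(.data$snp_count >= min_snps)
  shared <- counted |>
    group_by(.data$locus, .data$pattern, .data$snp_count) |>
    summarise(st_ids = list(sort(unique(.data$variant_id))), .groups = "drop") |>
    filter(lengths(.data$st_ids) >= 2)
  if (nrow(shared) == 0) {
    return(tibble(method = character(0), locus = character(0), st_ids = list(),
                  snp_count = integer(0), clade_scope = character(0),
                  cross_pe = logical(0)))
  }
  pe_of <- setNames(pe_map$pe, pe_map$record_id)
  shared |>
    mutate(
      n_pe = map_int(.data$st_ids, ~ length(unique(pe_of[.x]))),
      one_clade = map_lgl(.data$st_ids, function(ids) {
        if (!is.null(tree) && all(ids %in% tree$tip.label)) {
          is_monophyletic_tips(tree, ids)
        } else FALSE
      }),
      clade_scope = ifelse(.data$n_pe == 1 | .data$one_clade, "internal", "tip"),
      cross_pe = .data$n_pe > 1,
      method = "SNP"
    ) |>
    select("method", "locus", "st_ids", "snp_count", "clade_scope", "cross_pe")
}

#' @importFrom purrr map_lgl
is_monophyletic_tips <- function(tree, tips) {
  if (length(tips) == 1) return(TRUE)
  node <- ape::getMRCA(tree, tips)
  clade <- ape::extract.clade(tree, node)$tip.label
  setequal(clade, tips)
}

#' Assign each record's loci to the nearest reference lineage
#'
#' For every record and locus the reference lineage with the highest
#' sequence identity is reported.  A locus whose best lineage disagrees with
#' the record's assigned lineage (e.g. from 16S typing) flags a candidate
#' inter-lineage transfer; equidistant references flag the locus ambiguous.
#'
#' @param aln Long alignment tibble (`locus`, `record_id`, `seq`).
#' @param refs Tibble (`lineage`, `locus`, `seq`) of reference sequences in
#'   the same aligned coordinates.
#' @param lineage_of Optional tibble (`record_id`, `lineage`) with the
#'   records' assigned lineage.
#' @return Tibble (`record_id`, `locus`, `best_lineage`, `identity`,
#'   `ambiguous`, `transfer_flag`).
#' @export
assign_nearest_lineage <- function(aln, refs, lineage_of = NULL) {
  assert_alignment_tbl(aln)
  if (nrow(refs) == 0) abort("refs must be non-empty")
  assigned <- if (!is.null(lineage_of)) setNames(lineage_of$lineage, lineage_of$record_id)
  rows <- pmap(aln, function(locus, record_id, seq) {
    r <- refs[refs$locus == locus, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    ids <- vapply(r$seq, function(ref) {
      a <- strsplit(toupper(seq), "")[[1]]
      b <- strsplit(toupper(ref), "")[[1]]
      if (length(a) != length(b)) abort(paste0("reference length mismatch at ", locus))
      use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      if (!any(use)) return(NA_real_)
      mean(a[use] == b[use])
    }, numeric(1))
    best <- which(ids == max(ids, na.rm = TRUE))
    amb <- length(best) > 1
    bl <- r$lineage[best[1]]
    tibble(record_id = record_id, locus = locus, best_lineage = bl,
           identity = max(ids, na.rm = TRUE), ambiguous = amb,
           transfer_flag = !amb && !is.null(assigned) &&
             !is.na(assigned[record_id]) && bl != assigned[record_id])
  })
  bind_rows(rows)
}

#' Reconcile recombination-event lists across detection methods
#'
#' Events are compared by key `(locus, unordered ST set)`; breakpoint
#' positions play no role.  A key detected by two or more methods is an
#' overlapping event.  Unique counts follow the bookkeeping of multi-method
#' event tables: the top-priority method keeps all of its events (its
#' overlaps are not re-recorded under lower-priority methods), while every
#' other method contributes only events no other method detected.  The
#' total unique count is the sum of those per-method unique counts.
#'
#' @param events Event tibble with columns `method`, `locus`, `st_ids`
#'   (list column or comma-separated string).  External methods enter via
#'   the same columns (e.g. `method = "external:rdp4"`); they are never
#'   computed here.
#' @param priority Method priority order; methods absent from `events` are
#'   skipped.
#' @return Object of class `event_reconciliation`: list with `per_method`
#'   (tibble `method`, `n_events`, `n_unique`, `n_overlapping`) and
#'   `total_unique`.
#' @export
reconcile_events <- function(events,
                             priority = c("external:rdp4", "external:clonalframe", "SNP")) {
  if (nrow(events) == 0) abort("no events to reconcile")
  st_key <- if (is.list(events$st_ids)) {
    vapply(events$st_ids, function(s) paste(sort(unique(as.character(s))), collapse = ","), "")
  } else {
    vapply(strsplit(as.character(events$st_ids), ","),
           function(s) paste(sort(unique(trimws(s))), collapse = ","), "")
  }
  events$key <- paste0(events$locus, "|", st_key)
  methods_present <- unique(events$method)
  ord <- c(intersect(priority, methods_present), setdiff(methods_present, priority))
  key_methods <- events |>
    distinct(.data$method, .data$key) |>
    group_by(.data$key) |>
    summarise(methods = list(unique(.data$method)), .groups = "drop")
  n_det <- setNames(lengths(key_methods$methods), key_methods$key)
  per <- map(ord, function(m) {
    keys <- unique(events$key[events$method == m])
    n_overlap <- sum(n_det[keys] >= 2)
    n_unique <- if (m == ord[1]) length(keys) else sum(n_det[keys] == 1)
    tibble(method = m, n_events = length(keys),
           n_unique = n_unique, n_overlapping = n_overlap)
  }) |> bind_rows()
  structure(list(per_method = per, total_unique = sum(per$n_unique)),
            class = "event_reconciliation")
}

#' @export
print.event_reconciliation <- function(x, ...) {
  cat("Recombination event reconciliation\n")
  print(x$per_method)
  cat("Total unique events:", x$total_unique, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.event_reconciliation <- function(x, ...) x$per_method

#' @importFrom generics glance
#' @export
glance.event_reconciliation <- function(x, ...) {
  tibble(total_unique = x$total_unique,
         n_methods = nrow(x$per_method),
         n_overlapping = sum(x$per_method$n_overlapping))
}

#' Read an external recombination event list
#'
#' Import format for events produced by external detection tools: TSV with
#' columns `method`, `locus`, `st_ids` (comma-separated), and optionally
#' `snp_count`.
#'
#' @param path TSV path.
#' @return Event tibble with `st_ids` as a list column.
#' @export
read_event_list <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("method", "locus", "st_ids") %in% names(ev))) {
    abort("event list needs columns method, locus, st_ids")
  }
  ev$st_ids <- lapply(strsplit(as.character(ev$st_ids), ","), trimws)
  as_tibble(ev)
}
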