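#' Assign allele numbers within each locus
#'
#' Records whose aligned sequences are exactly identical (string equality
#' after upper-casing; gaps and ambiguity codes compare verbatim) receive the
#' same allele number.  Allele numbers are dense, `1..k` per locus, in order
#' of first appearance, so the assignment is deterministic given record
#' order.
#'
#' @param aln Long alignment tibble (`locus`, `record_id`, `seq`).
#' @return Tibble with columns `locus`, `record_id`, `allele`.  The attribute
#'   `representatives` holds a tibble (`locus`, `allele`, `seq`) with one
#'   representative sequence per allele.
#' @export
assign_alleles <- function(aln) {
  assert_alignment_tbl(aln)
  if (nrow(aln) == 0) abort("empty alignment")
  aln <- mutate(aln, seq = toupper(.data$seq))
  out <- aln |>
    group_by(.data$locus) |>
    mutate(allele = match(.data$seq, unique(.data$seq))) |>
    ungroup()
  reps <- out |>
    distinct(.data$locus, .data$allele, .data$seq) |>
    arrange(.data$locus, .data$allele)
  res <- select(out, "locus", "record_id", "allele")
  attr(res, "representatives") <- reps
  res
}

#' Build multi-locus sequence types from allele tables
#'
#' Records with identical allelic profiles at every locus of `loci_order`
#' share a sequence type (ST).  STs are numbered `1..m` by decreasing member
#' count, ties broken by first appearance.  Records missing any locus are
#' excluded from typing and reported via the `untyped` attribute.
#'
#' @param alleles Allele tibble from [assign_alleles()] (columns `locus`,
#'   `record_id`, `allele`), covering one or more loci.
#' @param loci_order Character vector of loci fixing the profile order.
#' @return Tibble with one row per ST: `st_id`, `count`, `members` (list
#'   column of record ids) and one allele column per locus (named by locus).
#' @export
build_sequence_types <- function(alleles, loci_order = unique(alleles$locus)) {
  stopifnot(all(c("locus", "record_id", "allele") %in% names(alleles)))
  unknown <- setdiff(loci_order, unique(alleles$locus))
  if (length(unknown) > 0) {
    abort(paste0("config error: loci_order names unknown loci: ",
                 paste(unknown, collapse = ", ")))
  }
  wide <- alleles |>
    filter(.data$locus %in% loci_order) |>
    tidyr::pivot_wider(names_from = "locus", values_from = "allele")
  complete <- stats::complete.cases(wide[loci_order])
  untyped <- wide$record_id[!complete]
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) == 0) abort("no record is typed at every locus in loci_order")
  key <- do.call(paste, c(wide[loci_order], sep = "/"))
  first_seen <- match(unique(key), key)
  prof <- wide[first_seen, loci_order, drop = FALSE]
  counts <- as.integer(table(factor(key, levels = unique(key))))
  ord <- order(-counts, seq_along(counts))
  members <- split(wide$record_id, factor(key, levels = unique(key)))
  out <- tibble(
    st_id = seq_along(ord),
    count = counts[ord],
    members = unname(members[ord])
  )
  out <- bind_cols(out, as_tibble(prof[ord, , drop = FALSE]))
  attr(out, "untyped") <- untyped
  attr(out, "loci") <- loci_order
  out
}

#' Expand an ST table to a record-to-ST map
#'
#' @param sts ST tibble from [build_sequence_types()].
#' @return Tibble with columns `record_id`, `st_id`.
#' @export
st_membership <- function(sts) {
  tidyr::unnest(select(sts, "st_id", "members"), "members") |>
    rename(record_id = "members") |>
    select("record_id", "st_id")
}

#' Classify STs of a group into dominant, subdominant and singleton variants
#'
#' Within a group (a putative ecotype or a clonal complex) the dominant
#' variant is the ST with the largest member count (ties broken by lowest
#' `st_id`); subdominant variants have `count >= 2` without being dominant;
#' the rest are singletons.  The roles partition the group.
#'
#' @param sts ST tibble (rows of [build_sequence_types()] output belonging to
#'   the group).
#' @return The input with an added `role` column
#'   (`"dominant"`/`"subdominant"`/`"singleton"`).
#' @export
find_dominant_variant <- function(sts) {
  if (nrow(sts) == 0) abort("empty ST group")
  dom <- sts$st_id[order(-sts$count, sts$st_id)][1]
  mutate(sts, role = case_when(
    .data$st_id == dom ~ "dominant",
    .data$count >= 2 ~ "subdominant",
    TRUE ~ "singleton"
  ))
}

#' Export an ST table in classic MLST profile format
#'
#' @param sts ST tibble from [build_sequence_types()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_st_table <- function(sts, path) {
  loci <- attr(sts, "loci") %||% setdiff(names(sts), c("st_id", "count", "members"))
  out <- sts |>
    mutate(member_ids = map_chr(.data$members, paste, collapse = ",")) |>
    select("st_id", "count", all_of(loci), "member_ids")
  write_report_tsv(out, path)
}
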