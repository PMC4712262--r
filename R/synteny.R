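#' Classify clone mate-pairs against a reference genome
#'
#' Each clone's two end placements (0-based half-open coordinates) are
#' compared with the expected library insert size.  The implied insert is
#' the distance from the leftmost start to the rightmost end.  Orientation
#' of the pair, read in genome coordinate order, is
#' `"normal"` (convergent: left end on `+`, right end on `-`),
#' `"anti-normal"` (divergent / outward-facing: left on `-`, right on `+`),
#' or `"same-strand"` (both ends on one strand); a `"-long"` suffix is
#' added when the implied insert exceeds `expected * (1 + tolerance)`.
#' A pair is syntenous iff its orientation is normal and the implied insert
#' lies within `expected * (1 ± tolerance)`; everything else (including
#' pairs on different reference sequences) is non-syntenous.  Clones with
#' an unmapped end are unclassifiable and reported separately.
#'
#' @param placements Tibble with columns `clone_id`, `end` (1 or 2), `ref`,
#'   `start` (0-based), `strand` (`"+"`/`"-"`), `length`.
#' @param expected_insert Expected insert size (nt), e.g. 90000.
#' @param tolerance_fraction Allowed fractional deviation (default 0.5).
#' @return Tibble, one row per clone: `clone_id`, `implied_insert`,
#'   `orientation_class`, `orientation_label`, `synteny_class`.  Attribute
#'   `unclassifiable` lists clones lacking a mapped end pair.
#' @export
classify_matepairs <- function(placements, expected_insert,
                               tolerance_fraction = 0.5) {
  if (expected_insert <= 0) abort("expected_insert must be positive")
  need <- c("clone_id", "end", "ref", "start", "strand", "length")
  if (!all(need %in% names(placements))) {
    abort(paste0("placements needs columns: ", paste(need, collapse = ", ")))
  }
  mapped <- filter(placements, !is.na(.data$start) & !is.na(.data$strand))
  counts <- count(mapped, .data$clone_id)
  ok_ids <- counts$clone_id[counts$n == 2]
  unclassifiable <- setdiff(unique(placements$clone_id), ok_ids)
  lo <- expected_insert * (1 - tolerance_fraction)
  hi <- expected_insert * (1 + tolerance_fraction)
  rows <- map(ok_ids, function(cid) {
    p <- arrange(filter(mapped, .data$clone_id == cid), .data$start)
    if (length(unique(p$ref)) > 1) {
      return(tibble(clone_id = cid, implied_insert = NA_real_,
                    orientation_class = "split-reference",
                    orientation_label = "split-reference",
                    synteny_class = "non-syntenous"))
    }
    insert <- max(p$start + p$length) - min(p$start)
    oc <- if (p$strand[1] == "+" && p$strand[2] == "-") "normal"
          else if (p$strand[1] == "-" && p$strand[2] == "+") "anti-normal"
          else "same-strand"
    label <- if (insert > hi) paste0(oc, "-long") else oc
    syn <- if (oc == "normal" && insert >= lo && insert <= hi)
      "syntenous" else "non-syntenous"
    tibble(clone_id = cid, implied_insert = insert, orientation_class = oc,
           orientation_label = label, synteny_class = syn)
  })
  out <- bind_rows(rows)
  attr(out, "unclassifiable") <- unclassifiable
  out
}

#' Summarise mate-pair classifications
#'
#' Fractions of syntenous clones and of each orientation label, plus the
#' count of anti-normal pairs (the inversion-associated signature).
#'
#' @param classified Output of [classify_matepairs()].
#' @return One-row tibble.
#' @export
synteny_summary <- function(classified) {
  n <- nrow(classified)
  tibble(
    n_clones = n,
    syntenous_fraction = mean(classified$synteny_class == "syntenous"),
    normal = sum(classified$orientation_class == "normal"),
    anti_normal = sum(classified$orientation_class == "anti-normal"),
    same_strand = sum(classified$orientation_class == "same-strand"),
    long = sum(grepl("-long$", classified$orientation_label))
  )
}
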