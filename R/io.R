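#' Read a per-locus alignment from FASTA
#'
#' Reads one locus of a multi-locus alignment.  Record identifiers are taken
#' as the full header token up to the first whitespace.  Sequences are
#' upper-cased; `A`, `C`, `G`, `T`, `-`, `N` and IUPAC ambiguity letters are
#' accepted.  All records must have identical length.
#'
#' @param path Path to a FASTA file containing aligned sequences.
#' @param locus_name Name of the locus; stored in the `locus` column.
#' @return A tibble with columns `locus`, `record_id`, `seq`, one row per
#'   record, in file order.
#' @export
read_locus_fasta <- function(path, locus_name) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no records in FASTA file: ", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate record ids in ", path, ": ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    tab <- table(lens)
    cand <- as.integer(names(tab)[tab == max(tab)])
    modal <- max(cand)  # ties resolve to the longest (full-length) records
    bad <- ids[lens != modal]
    abort(paste0("ragged alignment in ", path, " (expected ", modal,
                 " columns); offending records: ", paste(bad, collapse = ", ")))
  }
  ok <- grepl("^[ACGTUMRWSYKVHDBN-]*$", seqs)
  if (!all(ok)) {
    abort(paste0("non-nucleotide characters in records: ",
                 paste(ids[!ok], collapse = ", ")))
  }
  tibble(locus = locus_name, record_id = ids, seq = unname(seqs))
}

#' Write a per-locus alignment to FASTA
#'
#' @param aln Tibble with columns `record_id` and `seq` (a `locus` column is
#'   ignored beyond selecting `locus_name` rows when given).
#' @param path Output file path.
#' @param locus_name Optional locus to select from a multi-locus table.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(aln, path, locus_name = NULL, width = 70) {
  if (!is.null(locus_name)) aln <- aln[aln$locus == locus_name, , drop = FALSE]
  set <- Biostrings::BStringSet(setNames(aln$seq, aln$record_id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read amplicon reads with abundance annotation
#'
#' FASTA headers may carry a `;size=N` suffix (usearch/vsearch convention)
#' giving the copy number of the read; absent suffixes default to 1.
#'
#' @param path FASTA file of (possibly unaligned) reads.
#' @return Tibble with columns `record_id`, `seq`, `count`.
#' @export
read_amplicon_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no records in FASTA file: ", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  size <- rep(1L, length(ids))
  has <- grepl(";size=\\d+;?$", ids)
  size[has] <- as.integer(sub("^.*;size=(\\d+);?$", "\\1", ids[has]))
  ids <- sub(";size=\\d+;?$", "", ids)
  tibble(record_id = ids, seq = toupper(unname(as.character(set))), count = size)
}

#' Read sample metadata
#'
#' Reads a tab-separated metadata table with a header row.  Required column:
#' `record_id`.  Recognised optional columns: `habitat` (e.g. collection
#' temperature such as "60C"), `depth_section` (non-negative integer index of
#' an 80-um cryotome section), `replicate`, `source` ("BAC" or "amplicon").
#' Unknown habitat labels are preserved verbatim.
#'
#' @param path Path to a TSV file.
#' @return Tibble, one row per data row.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"record_id" %in% names(md)) {
    abort("metadata schema error: missing required column 'record_id'")
  }
  md$record_id <- as.character(md$record_id)
  if (any(is.na(md$record_id) | md$record_id == "")) {
    abort("metadata schema error: empty record_id in data rows")
  }
  if ("depth_section" %in% names(md)) {
    ds <- md$depth_section
    if (any(!is.na(ds) & (ds < 0 | ds != floor(ds)))) {
      abort("metadata validation error: depth_section must be a non-negative integer")
    }
    md$depth_section <- as.integer(ds)
  }
  as_tibble(md)
}

#' Write a tabular report
#'
#' All tabular outputs of the package are tab-separated UTF-8 with a header
#' row.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a newick tree and check leaves against record identifiers
#'
#' @param path Newick file.
#' @param record_ids Optional character vector of expected identifiers; leaves
#'   absent from it are reported with a warning.
#' @return An [ape::read.tree()] `phylo` object, with attribute
#'   `unmatched_leaves` listing leaves not found in `record_ids`.
#' @export
read_tree <- function(path, record_ids = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) abort(paste0("newick parse error in ", path, ": empty input"))
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) abort(paste0("newick parse error in ", path))
  unmatched <- character(0)
  if (!is.null(record_ids)) {
    unmatched <- setdiff(tree$tip.label, record_ids)
    if (length(unmatched) > 0) {
      warn(paste0("tree leaves not matching any record id: ",
                  paste(unmatched, collapse = ", ")))
    }
  }
  attr(tree, "unmatched_leaves") <- unmatched
  tree
}

#' Read a run configuration from YAML
#'
#' A run configuration fixes the ordered list of loci (the concatenation
#' order for the whole run), per-module thresholds and seeds, and the output
#' directory.
#'
#' @param path YAML file.
#' @return A list with at least `loci`; class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the 'yaml' package is required to read run configurations")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$loci) || length(cfg$loci) == 0) {
    abort("run config error: 'loci' must be a non-empty ordered list")
  }
  cfg$loci <- as.character(cfg$loci)
  structure(cfg, class = "run_config")
}

#' Concatenate loci into a single alignment
#'
#' Records present at every locus in `loci_order` are concatenated in that
#' order; records missing any locus are dropped and reported via the
#' `dropped` attribute.
#'
#' @param aln Long alignment tibble (`locus`, `record_id`, `seq`).
#' @param loci_order Character vector of loci, fixing concatenation order.
#' @return Tibble with columns `record_id`, `seq`; attribute `dropped` holds
#'   the excluded record ids.
#' @export
concat_alignment <- function(aln, loci_order = unique(aln$locus)) {
  assert_alignment_tbl(aln)
  missing_loci <- setdiff(loci_order, unique(aln$locus))
  if (length(missing_loci) > 0) {
    abort(paste0("config error: unknown loci in loci_order: ",
                 paste(missing_loci, collapse = ", ")))
  }
  wide <- aln |>
    filter(.data$locus %in% loci_order) |>
    tidyr::pivot_wider(names_from = "locus", values_from = "seq")
  complete <- stats::complete.cases(wide[loci_order])
  dropped <- wide$record_id[!complete]
  wide <- wide[complete, , drop = FALSE]
  out <- tibble(
    record_id = wide$record_id,
    seq = do.call(paste0, wide[loci_order])
  )
  attr(out, "dropped") <- dropped
  out
}
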