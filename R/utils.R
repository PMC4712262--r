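#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap walk
#' @importFrom stats setNames
NULL

# Split aligned sequences (equal length, upper case) into a character matrix,
# rows = records, columns = alignment positions.
seq_matrix <- function(seqs, ids = names(seqs)) {
  stopifnot(length(seqs) > 0)
  lens <- unique(nchar(seqs))
  if (length(lens) != 1) {
    abort("sequences have unequal lengths; alignment required")
  }
  m <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- ids
  m
}

# Long alignment tibble (locus, record_id, seq) -> named character vector for
# one locus.  Errors if the locus is absent.
locus_seqs <- function(aln, locus) {
  x <- aln[aln$locus == locus, , drop = FALSE]
  if (nrow(x) == 0) abort(paste0("locus '", locus, "' not present in alignment table"))
  setNames(x$seq, x$record_id)
}

assert_alignment_tbl <- function(aln, arg = "aln") {
  if (!is.data.frame(aln) || !all(c("locus", "record_id", "seq") %in% names(aln))) {
    abort(paste0("`", arg, "` must be a data frame with columns locus, record_id, seq"))
  }
  invisible(aln)
}

# Hamming distance matrix between equal-length sequences, computed only over
# polymorphic columns (monomorphic columns contribute nothing).
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  if (n == 1) return(matrix(0, 1, 1, dimnames = list(names(seqs), names(seqs))))
  m <- seq_matrix(seqs)
  poly <- which(apply(m, 2, function(col) length(unique(col)) > 1L))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (length(poly) == 0) return(d)
  mp <- m[, poly, drop = FALSE]
  matches <- matrix(0, n, n)
  for (st in unique(as.vector(mp))) {
    ind <- (mp == st) * 1
    matches <- matches + tcrossprod(ind)
  }
  d <- length(poly) - matches
  diag(d) <- 0
  d
}

# Deterministic child-stream seeds derived from one root seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

canonical_key <- function(locus, st_ids) {
  paste0(locus, "|", vapply(st_ids, function(s) paste(sort(unique(s)), collapse = ","), ""))
}
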