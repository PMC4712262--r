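# Independent brute-force oracles used across the suite.

# Minimum number of breakpoints stabbing every four-gamete-incompatible
# interval: exhaustive search over breakpoint placements of increasing size.
oracle_rmin <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 2) return(0L)
  nst <- apply(m, 2, function(col) length(unique(col)))
  ba <- which(nst == 2)
  if (length(ba) < 2) return(0L)
  ints <- list()
  for (a in seq_along(ba)[-length(ba)]) {
    for (b in (a + 1):length(ba)) {
      i <- ba[a]; j <- ba[b]
      x <- as.integer(m[, i] != m[1, i])
      y <- as.integer(m[, j] != m[1, j])
      if (length(unique(x * 2L + y)) == 4L) {
        ints[[length(ints) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(ints) == 0) return(0L)
  iv <- do.call(rbind, ints)
  # candidate breakpoint slots: between columns p and p+1
  slots <- sort(unique(c(iv[, 1], iv[, 2] - 1L)))
  for (k in 1:length(slots)) {
    combos <- utils::combn(slots, k)
    for (ci in seq_len(ncol(combos))) {
      bp <- combos[, ci]
      if (all(vapply(seq_len(nrow(iv)), function(r) {
        any(bp >= iv[r, 1] & bp <= iv[r, 2] - 1L)
      }, logical(1)))) {
        return(k)
      }
    }
  }
  stop("oracle failed")
}

# Connected components over ST profiles linked at <= max_diff differing loci,
# via breadth-first search.
oracle_cc_components <- function(prof, max_diff = 1L) {
  n <- nrow(prof)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in seq_len(n)) {
        if (is.na(comp[w])) {
          d <- sum(prof[v, ] != prof[w, ])
          if (d >= 1 && d <= max_diff) {
            comp[w] <- cur
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  comp
}

# Single-linkage cluster count at an identity cutoff via union-find.
oracle_cluster_count <- function(seqs, cutoff) {
  sv <- toupper(unname(seqs))
  n <- length(sv)
  L <- nchar(sv[1])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sum(strsplit(sv[i], "")[[1]] != strsplit(sv[j], "")[[1]])
      if (1 - d / L >= cutoff - 1e-12) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Random aligned sequence set over few sites (many incompatibilities likely).
random_binary_alignment <- function(n_seq, n_site) {
  seqs <- vapply(seq_len(n_seq), function(i) {
    paste(sample(c("A", "T"), n_site, replace = TRUE), collapse = "")
  }, character(1))
  setNames(seqs, paste0("s", seq_len(n_seq)))
}

# Random allelic-profile ST table in the package's ST-tibble shape.
random_st_table <- function(n_st, n_loci, max_allele = 3L) {
  prof <- matrix(sample.int(max_allele, n_st * n_loci, replace = TRUE),
                 nrow = n_st)
  prof <- prof[!duplicated(apply(prof, 1, paste, collapse = "/")), , drop = FALSE]
  colnames(prof) <- paste0("loc", seq_len(n_loci))
  out <- tibble::tibble(
    st_id = seq_len(nrow(prof)),
    count = sample.int(5L, nrow(prof), replace = TRUE),
    members = lapply(seq_len(nrow(prof)), function(i) paste0("r", i))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(prof))
  attr(out, "loci") <- colnames(prof)
  out
}
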