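#' Implant a gene-conversion tract
#'
#' Replaces recipient columns `[start, start + length - 1]` (1-based within
#' the locus) with the donor's, recording the number of sites actually
#' changed.  A donor identical across the tract yields a silent event
#' (recorded, `snp_count = 0`, undetectable).
#'
#' @param recipient,donor Aligned sequences of equal length.
#' @param start Tract start (1-based).
#' @param length Tract length (nt).
#' @return List with `seq` (modified recipient) and `snp_count`.
#' @export
implant_conversion_tract <- function(recipient, donor, start, length) {
  L <- nchar(recipient)
  if (nchar(donor) != L) abort("donor and recipient lengths differ")
  if (start < 1 || length < 1 || start + length - 1 > L) {
    abort("tract out of locus bounds")
  }
  idx <- start:(start + length - 1)
  r <- strsplit(recipient, "")[[1]]
  d <- strsplit(donor, "")[[1]]
  snp <- sum(r[idx] != d[idx])
  r[idx] <- d[idx]
  list(seq = paste(r, collapse = ""), snp_count = snp)
}

#' Generate an ecotype-structured multi-locus dataset with known truth
#'
#' Simulates one (or two, see `two_lineage`) clonal genealogy under the
#' Stable Ecotype Model, overlays mutations across `k` loci that share the
#' genealogy, implants within-lineage gene-conversion tracts at a rate tied
#' to the mutation count (`recomb_within_ratio`, the rho/theta analogue)
#' and rare between-lineage tracts (`recomb_between_ratio`, the fraction of
#' records carrying a cross-lineage transfer), and samples records into
#' habitats and depth sections with ecotype-specific weights.  All output
#' is bit-reproducible under `seed`.
#'
#' Defaults mirror a hot-spring cyanobacterial multi-locus study design:
#' seven loci of roughly 420-630 nt; a mutation intensity chosen so the
#' emitted sample's whole-alignment Watterson estimate lands near 0.01 per
#' site (the deep between-ecotype coalescence times inflate the observed
#' estimate well above the per-site intensity itself); within-lineage
#' recombination comparable to (0.6x) mutation; and about 2\% of records
#' with between-lineage transfer when two lineages are generated.
#'
#' @param n_records Records per lineage.
#' @param npop True number of ecotypes per lineage.
#' @param omega,sigma Ecotype formation and periodic selection rates.
#' @param theta_site Per-site scaled mutation intensity.
#' @param locus_lengths Named integer vector of locus lengths; names are
#'   the locus names.
#' @param recomb_within_ratio Expected within-lineage conversion events per
#'   mutation event.
#' @param recomb_between_ratio Expected fraction of records with a
#'   between-lineage conversion (two-lineage mode only).
#' @param tract_range Uniform range of tract lengths (nt), capped at the
#'   locus length.
#' @param p_clade_event Probability that a within-lineage event is
#'   implanted ancestrally (on a clade) rather than on a single tip.
#' @param habitat_labels Habitat labels (two by default).
#' @param habitat_bias Probability that a record of an odd-numbered ecotype
#'   is sampled from the first habitat (even-numbered ecotypes mirror it).
#' @param n_sections,n_replicates Depth sections and replicate cores.
#' @param depth_gradient Strength of the per-ecotype linear depth gradient
#'   (alternating sign across ecotypes; 0 = flat).
#' @param two_lineage Also generate a second, deeply diverged lineage
#'   ("B"), joined by mutating the ancestral sequence at
#'   `between_divergence` of sites.
#' @param between_divergence Ancestral divergence between the two lineages.
#' @param seed Root seed; all stage streams derive from it.
#' @return List of class `mlsa_synthetic`: `alignments` (long tibble
#'   `locus`, `record_id`, `seq`), `metadata` (tibble `record_id`,
#'   `habitat`, `depth_section`, `replicate`, `source`, `lineage`), and
#'   `truth` (list: `ecotype` tibble, `events` tibble, `params`).
#' @export
simulate_mlsa_dataset <- function(n_records = 60, npop = 5, omega = 0.05,
                                  sigma = 0.5, theta_site = 0.0015,
                                  locus_lengths = c(rbsK = 520, PK = 584,
                                                    hisF = 429, lepB = 420,
                                                    CHP = 629, aroA = 607,
                                                    dnaG = 547),
                                  recomb_within_ratio = 0.6,
                                  recomb_between_ratio = 0.02,
                                  tract_range = c(50, 500),
                                  p_clade_event = 0.5,
                                  habitat_labels = c("60C", "65C"),
                                  habitat_bias = 0.8,
                                  n_sections = 8, n_replicates = 3,
                                  depth_gradient = 0.8,
                                  two_lineage = FALSE,
                                  between_divergence = 0.05,
                                  seed = 1) {
  stopifnot(n_records >= 2, all(locus_lengths > 0), recomb_within_ratio >= 0,
            recomb_between_ratio >= 0)
  if (tract_range[1] > max(locus_lengths)) {
    abort("config error: minimum tract length exceeds every locus length")
  }
  loci <- names(locus_lengths)
  if (is.null(loci)) abort("locus_lengths must be named")
  L <- sum(locus_lengths)
  offsets <- cumsum(c(0, locus_lengths[-length(locus_lengths)]))
  names(offsets) <- loci

  withr::with_seed(seed, {
    lineages <- if (two_lineage) c("A", "B") else "A"
    sims <- list()
    anc_A <- NULL
    aln_rows <- list()
    truth_eco <- list()
    n_mut_total <- 0
    for (ln in lineages) {
      sim <- simulate_ecotype_coalescent(n_records, npop, omega, sigma,
                                         theta_site, L,
                                         seed = sample.int(2^30, 1))
      if (ln == "A") {
        anc_A <- sim$ancestral
      } else {
        # second lineage: force a deeply diverged ancestral sequence
        flip <- stats::runif(L) < between_divergence
        anc <- sim$ancestral
        anc[!flip] <- anc_A[!flip]
        bases <- c("A", "C", "G", "T")
        anc[flip] <- vapply(which(flip), function(i) {
          sample(setdiff(bases, anc_A[i]), 1)
        }, character(1))
        sim$ancestral <- anc
      }
      sims[[ln]] <- sim
      sq <- ecosim_sequences(sim, prefix = ln)
      n_mut_total <- n_mut_total + nrow(sim$mutations)
      truth_eco[[ln]] <- tibble(record_id = sq$record_id,
                                lineage = ln, ecotype = paste0(ln, sim$ecotype))
      aln_rows[[ln]] <- sq
    }

    # split concatenated sequences into loci
    split_loci <- function(sq) {
      bind_rows(lapply(loci, function(lc) {
        tibble(locus = lc, record_id = sq$record_id,
               seq = substr(sq$seq, offsets[lc] + 1, offsets[lc] + locus_lengths[lc]))
      }))
    }
    aln <- bind_rows(lapply(aln_rows, split_loci))

    seq_of <- function(rid, lc) aln$seq[aln$record_id == rid & aln$locus == lc]
    set_seq <- function(rid, lc, s) {
      aln$seq[aln$record_id %in% rid & aln$locus == lc] <<- s
    }
    lineage_of <- bind_rows(truth_eco)
    events <- list()

    draw_tract <- function(lc) {
      len <- sample(tract_range[1]:min(tract_range[2], locus_lengths[lc]), 1)
      start <- sample.int(locus_lengths[lc] - len + 1, 1)
      c(start, len)
    }

    # within-lineage conversions, count tied to the mutation count
    n_within <- stats::rpois(1, recomb_within_ratio * n_mut_total)
    for (i in seq_len(n_within)) {
      ln <- sample(lineages, 1)
      recs <- lineage_of$record_id[lineage_of$lineage == ln]
      lc <- sample(loci, 1, prob = locus_lengths)
      tr <- draw_tract(lc)
      ancestral_impl <- stats::runif(1) < p_clade_event
      sim <- sims[[ln]]
      recipients <- if (ancestral_impl && nrow(sim$edges) > 0) {
        e <- sim$edges$tips[[sample.int(nrow(sim$edges), 1)]]
        recs[e]
      } else {
        sample(recs, 1)
      }
      donor_id <- sample(setdiff(recs, recipients), 1)
      donor_seq <- seq_of(donor_id, lc)
      snp <- NA_integer_
      for (rid in recipients) {
        res <- implant_conversion_tract(seq_of(rid, lc), donor_seq, tr[1], tr[2])
        if (is.na(snp)) snp <- res$snp_count
        set_seq(rid, lc, res$seq)
      }
      events[[length(events) + 1L]] <- tibble(
        type = "within", lineage = ln, locus = lc, donor = donor_id,
        recipients = list(recipients), start = tr[1], tract_length = tr[2],
        snp_count = snp, clade_scope = if (length(recipients) > 1) "internal" else "tip"
      )
    }

    # rare between-lineage conversions
    if (two_lineage && recomb_between_ratio > 0) {
      n_between <- stats::rpois(1, recomb_between_ratio * n_records * length(lineages))
      for (i in seq_len(n_between)) {
        ln <- sample(lineages, 1)
        other <- setdiff(lineages, ln)
        rid <- sample(lineage_of$record_id[lineage_of$lineage == ln], 1)
        donor_id <- sample(lineage_of$record_id[lineage_of$lineage == other], 1)
        lc <- sample(loci, 1, prob = locus_lengths)
        tr <- draw_tract(lc)
        res <- implant_conversion_tract(seq_of(rid, lc), seq_of(donor_id, lc),
                                        tr[1], tr[2])
        set_seq(rid, lc, res$seq)
        events[[length(events) + 1L]] <- tibble(
          type = "between", lineage = ln, locus = lc, donor = donor_id,
          recipients = list(rid), start = tr[1], tract_length = tr[2],
          snp_count = res$snp_count, clade_scope = "tip"
        )
      }
    }

    # habitat- and depth-biased sampling
    eco_index <- as.integer(factor(lineage_of$ecotype))
    p_hab1 <- ifelse(eco_index %% 2 == 1, habitat_bias, 1 - habitat_bias)
    habitat <- ifelse(stats::runif(nrow(lineage_of)) < p_hab1,
                      habitat_labels[1], habitat_labels[2])
    slope <- ifelse(eco_index %% 2 == 1, depth_gradient, -depth_gradient)
    sec <- seq_len(n_sections)
    depth_section <- vapply(seq_len(nrow(lineage_of)), function(i) {
      w <- 1 + slope[i] * (sec - mean(sec)) / (n_sections / 2)
      w <- pmax(w, 0.01)
      sample(sec, 1, prob = w)
    }, integer(1))
    metadata <- tibble(
      record_id = lineage_of$record_id,
      habitat = habitat,
      depth_section = depth_section,
      replicate = sample.int(n_replicates, nrow(lineage_of), replace = TRUE),
      source = "BAC",
      lineage = lineage_of$lineage
    )

    structure(list(
      alignments = aln,
      metadata = metadata,
      truth = list(
        ecotype = lineage_of,
        events = if (length(events)) bind_rows(events) else tibble(),
        params = list(npop = npop, omega = omega, sigma = sigma,
                      theta_site = theta_site, n_records = n_records,
                      recomb_within_ratio = recomb_within_ratio,
                      recomb_between_ratio = recomb_between_ratio,
                      habitat_bias = habitat_bias,
                      depth_gradient = depth_gradient, seed = seed)
      )
    ), class = "mlsa_synthetic")
  })
}

#' Simulate depth-sectioned amplicon reads from a synthetic dataset
#'
#' Samples read copies of one locus from the dataset's records, per depth
#' section and replicate core, with each ecotype's linear depth gradient
#' governing its sampling weight — an emulation of depth-sectioned amplicon
#' sequencing of that locus.
#'
#' @param dataset An `mlsa_synthetic` object.
#' @param locus Locus to amplify.
#' @param reads_per_section Total copies sampled per (section, replicate).
#' @param n_sections,n_replicates Sampling design.
#' @param seed Seed.
#' @return Tibble (`read_id`, `seq`, `count`, `depth_section`, `replicate`,
#'   `source_record`, `true_ecotype`).
#' @export
simulate_amplicon_reads <- function(dataset, locus, reads_per_section = 200,
                                    n_sections = 8, n_replicates = 3,
                                    seed = 1) {
  stopifnot(inherits(dataset, "mlsa_synthetic"))
  aln <- dataset$alignments
  if (!locus %in% aln$locus) abort(paste0("locus not in dataset: ", locus))
  truth <- dataset$truth$ecotype
  eco_index <- as.integer(factor(truth$ecotype))
  slope <- ifelse(eco_index %% 2 == 1,
                  dataset$truth$params$depth_gradient,
                  -dataset$truth$params$depth_gradient)
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_sections)) {
      w_eco <- pmax(1 + slope * (s - (n_sections + 1) / 2) / (n_sections / 2), 0.01)
      for (r in seq_len(n_replicates)) {
        picks <- sample(truth$record_id, reads_per_section, replace = TRUE,
                        prob = w_eco)
        tab <- table(picks)
        rows[[length(rows) + 1L]] <- tibble(
          source_record = names(tab),
          count = as.integer(tab),
          depth_section = s, replicate = r
        )
      }
    }
    out <- bind_rows(rows) |>
      left_join(distinct(aln[aln$locus == locus, c("record_id", "seq")]),
                by = c(source_record = "record_id")) |>
      left_join(truth[, c("record_id", "ecotype")],
                by = c(source_record = "record_id")) |>
      rename(true_ecotype = "ecotype")
    out$read_id <- sprintf("read%05d", seq_len(nrow(out)))
    select(out, "read_id", "seq", "count", "depth_section", "replicate",
           "source_record", "true_ecotype")
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits the exact input formats the readers consume: one FASTA per locus,
#' a metadata TSV, a truth JSON, and optionally a newick of the UPGMA tree
#' over distinct concatenated sequences.
#'
#' @param dataset An `mlsa_synthetic` object.
#' @param dir Output directory (created if needed).
#' @param tree Also write `true_tree.nwk`.
#' @return `dir`, invisibly.
#' @export
write_mlsa_dataset <- function(dataset, dir, tree = FALSE) {
  stopifnot(inherits(dataset, "mlsa_synthetic"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lc in unique(dataset$alignments$locus)) {
    write_locus_fasta(dataset$alignments, file.path(dir, paste0(lc, ".fasta")),
                      locus_name = lc)
  }
  write_report_tsv(dataset$metadata, file.path(dir, "metadata.tsv"))
  truth <- dataset$truth
  truth$events <- if (nrow(truth$events) > 0) {
    mutate(truth$events, recipients = map_chr(.data$recipients, paste, collapse = ","))
  } else truth$events
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (tree) {
    conc <- concat_alignment(dataset$alignments)
    sv <- setNames(conc$seq, conc$record_id)
    sv <- sv[!duplicated(unname(sv))]
    hc <- stats::hclust(stats::as.dist(hamming_matrix(sv)), method = "average")
    ape::write.tree(ape::as.phylo(hc), file.path(dir, "true_tree.nwk"))
  }
  invisible(dir)
}
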