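two_locus_aln <- function(...) {
  recs <- list(...)
  dplyr::bind_rows(lapply(names(recs), function(id) {
    tibble::tibble(locus = names(recs[[id]]), record_id = id,
                   seq = unname(unlist(recs[[id]])))
  }))
}

test_that("SNP profiles report exact per-locus mismatch coordinates", {
  aln <- two_locus_aln(
    dom = c(lepB = "AAAA", aroA = "CCCC"),
    var = c(lepB = "ATAA", aroA = "CCGC")
  )
  p <- snp_profile(aln, "var", "dom")
  expect_equal(nrow(p), 2)
  expect_equal(p$locus, c("aroA", "lepB"))
  expect_equal(p$position, c(3L, 2L))
  expect_equal(p$variant_state, c("G", "T"))
  # positions strictly increasing within each locus
  expect_true(all(tapply(p$position, p$locus, function(x) all(diff(x) > 0))))

  identical_p <- snp_profile(aln, "dom", "dom")
  expect_equal(nrow(identical_p), 0)

  bad <- two_locus_aln(a = c(l1 = "AA"), b = c(l2 = "AA"))
  expect_error(snp_profile(bad, "a", "b"), "same loci")
})

test_that("more than one SNP in a single locus marks recombination", {
  aln <- two_locus_aln(
    dom = c(dnaG = strrep("A", 30), CHP = strrep("C", 30), rbsK = strrep("G", 30)),
    v1  = c(dnaG = paste0(strrep("T", 19), strrep("A", 11)),  # 19 SNPs in dnaG
            CHP = strrep("C", 30), rbsK = strrep("G", 30)),
    v2  = c(dnaG = strrep("A", 30),
            CHP = paste0("T", strrep("C", 29)),               # 1 SNP: mutation
            rbsK = strrep("G", 30)),
    v3  = c(dnaG = strrep("A", 30),
            CHP = paste0("TT", strrep("C", 28)),              # 2 SNPs
            rbsK = paste0("TTT", strrep("G", 27)))            # 3 SNPs
  )
  ev1 <- detect_snp_recombination(snp_profile(aln, "v1", "dom"))
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$locus, "dnaG")
  expect_equal(ev1$snp_count, 19)

  ev2 <- detect_snp_recombination(snp_profile(aln, "v2", "dom"))
  expect_equal(nrow(ev2), 0)  # single SNP is mutation by definition

  ev3 <- detect_snp_recombination(snp_profile(aln, "v3", "dom"))
  expect_equal(sort(ev3$locus), c("CHP", "rbsK"))
  expect_equal(ev3$snp_count[order(ev3$locus)], c(2L, 3L))

  # idempotent and order-independent
  prof <- snp_profile(aln, "v3", "dom")
  expect_equal(detect_snp_recombination(prof[sample(nrow(prof)), ]) |>
                 dplyr::arrange(locus),
               ev3 |> dplyr::arrange(locus))
})

test_that("shared SNP patterns are grouped and scoped to clades", {
  base <- strrep("A", 20)
  carrier <- paste0("A", "TT", strrep("A", 17))  # SNPs at 2,3 -> T
  other <- paste0("GG", strrep("A", 18))
  aln <- dplyr::bind_rows(
    tibble::tibble(locus = "CHP", record_id = "dom1", seq = base),
    tibble::tibble(locus = "CHP", record_id = "st7", seq = carrier),
    tibble::tibble(locus = "CHP", record_id = "st11", seq = carrier),
    tibble::tibble(locus = "CHP", record_id = "st5", seq = other)
  )
  profs <- dplyr::bind_rows(
    snp_profile(aln, "st7", "dom1"),
    snp_profile(aln, "st11", "dom1"),
    snp_profile(aln, "st5", "dom1")
  )
  pe_map <- tibble::tibble(record_id = c("st7", "st11", "st5"),
                           pe = c("A4", "A4", "A7"))
  ev <- shared_pattern_scan(profs, pe_map)
  expect_equal(nrow(ev), 1)          # only the identical pattern is shared
  expect_setequal(ev$st_ids[[1]], c("st7", "st11"))
  expect_equal(ev$clade_scope, "internal")  # both carriers in one PE
  expect_false(ev$cross_pe)

  # same carriers in different PEs -> cross-PE sharing flagged
  pe_map2 <- tibble::tibble(record_id = c("st7", "st11", "st5"),
                            pe = c("A4", "A7", "A2"))
  ev2 <- shared_pattern_scan(profs, pe_map2)
  expect_true(ev2$cross_pe)
  expect_equal(ev2$clade_scope, "tip")

  # patterns differing at one position are not shared
  aln2 <- dplyr::bind_rows(
    aln,
    tibble::tibble(locus = "CHP", record_id = "st9",
                   seq = paste0("A", "TG", strrep("A", 17)))
  )
  profs2 <- dplyr::bind_rows(profs, snp_profile(aln2, "st9", "dom1"))
  ev3 <- shared_pattern_scan(profs2, pe_map)
  expect_equal(nrow(ev3), 1)
})

test_that("an ancestral implant leaves a clade-wide identical pattern", {
  # a clade of five STs sharing one rbsK allele receives a conversion tract
  # from a diverged donor at its common ancestor; every descendant then
  # carries the identical SNP pattern against the dominant variant
  set.seed(19)
  dom_seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  donor_seq <- local({
    x <- strsplit(dom_seq, "")[[1]]
    flip <- sample(300, 30)
    x[flip] <- vapply(x[flip], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(x, collapse = "")
  })
  clade <- paste0("st", 1:5)
  implanted <- implant_conversion_tract(dom_seq, donor_seq, 50, 150)
  expect_gte(implanted$snp_count, 2)
  aln <- dplyr::bind_rows(
    tibble::tibble(locus = "rbsK", record_id = "dom", seq = dom_seq),
    tibble::tibble(locus = "rbsK", record_id = clade, seq = implanted$seq),
    tibble::tibble(locus = "rbsK", record_id = "other",
                   seq = paste0("T", substr(dom_seq, 2, 300)))
  )
  profs <- dplyr::bind_rows(lapply(c(clade, "other"),
                                   function(v) snp_profile(aln, v, "dom")))
  pe_map <- tibble::tibble(record_id = c(clade, "other", "dom"), pe = "PE1")
  ev <- shared_pattern_scan(profs, pe_map)
  expect_equal(nrow(ev), 1)
  expect_setequal(ev$st_ids[[1]], clade)
  expect_equal(ev$clade_scope, "internal")
  expect_equal(ev$snp_count, implanted$snp_count)
})

test_that("nearest-lineage assignment flags inter-lineage transfer candidates", {
  refs <- tibble::tibble(
    lineage = c("A", "B", "A", "B"),
    locus = c("rbsK", "rbsK", "aroA", "aroA"),
    seq = c("AAAAAAAA", "TTTTTTTT", "CCCCCCCC", "GGGGGGGG")
  )
  aln <- two_locus_aln(
    rec1 = c(rbsK = "TTTTTTTA", aroA = "CCCCCCCA"),  # rbsK from B, aroA from A
    rec2 = c(rbsK = "AAAATTTT", aroA = "CCCCCCCC")   # rbsK equidistant
  )
  lin <- tibble::tibble(record_id = c("rec1", "rec2"), lineage = c("A", "A"))
  out <- assign_nearest_lineage(aln, refs, lineage_of = lin)
  r1_rbsk <- out[out$record_id == "rec1" & out$locus == "rbsK", ]
  expect_equal(r1_rbsk$best_lineage, "B")
  expect_true(r1_rbsk$transfer_flag)
  r1_aroa <- out[out$record_id == "rec1" & out$locus == "aroA", ]
  expect_false(r1_aroa$transfer_flag)  # agrees with assigned lineage
  r2_rbsk <- out[out$record_id == "rec2" & out$locus == "rbsK", ]
  expect_true(r2_rbsk$ambiguous)
})

test_that("event reconciliation reproduces multi-method unique totals", {
  mk <- function(method, keys) {
    tibble::tibble(method = method, locus = "rbsK",
                   st_ids = lapply(keys, function(k) c(k, "dom")))
  }
  # 11 events from the primary method, 7 of them co-detected by the other
  # two methods, plus 24 events seen only in SNP patterns
  ev <- dplyr::bind_rows(
    mk("external:rdp4", paste0("k", 1:11)),
    mk("external:clonalframe", paste0("k", 1:7)),
    mk("SNP", c(paste0("k", 1:7), paste0("s", 1:24)))
  )
  rec <- reconcile_events(ev)
  expect_equal(rec$total_unique, 35)
  pm <- rec$per_method
  expect_equal(pm$n_unique[pm$method == "external:rdp4"], 11)
  expect_equal(pm$n_unique[pm$method == "external:clonalframe"], 0)
  expect_equal(pm$n_overlapping[pm$method == "external:clonalframe"], 7)
  expect_equal(pm$n_unique[pm$method == "SNP"], 24)
  expect_equal(pm$n_overlapping[pm$method == "SNP"], 7)

  # single method: every event unique
  expect_equal(reconcile_events(mk("SNP", paste0("x", 1:5)))$total_unique, 5)

  # permutation invariance given the fixed priority
  rec2 <- reconcile_events(ev[sample(nrow(ev)), ])
  expect_equal(rec2$total_unique, rec$total_unique)

  g <- glance(rec)
  expect_equal(g$total_unique, 35)
  expect_equal(nrow(tidy(rec)), 3)
})

test_that("events overlapping only among lower-priority methods count once", {
  mk <- function(method, keys) {
    tibble::tibble(method = method, locus = "pcrA",
                   st_ids = lapply(keys, function(k) c(k, "dom")))
  }
  # 4 primary-method events (all co-detected by the second method); the
  # second method adds 9 unique and shares 14 with the third; the third adds
  # 11 unique
  ev <- dplyr::bind_rows(
    mk("external:rdp4", paste0("r", 1:4)),
    mk("external:clonalframe", c(paste0("r", 1:4), paste0("c", 1:9), paste0("cs", 1:14))),
    mk("SNP", c(paste0("cs", 1:14), paste0("n", 1:11)))
  )
  rec <- reconcile_events(ev)
  expect_equal(rec$total_unique, 4 + 9 + 11)
})
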