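test_that("2x2 Fisher p-values equal full hypergeometric enumeration", {
  m <- matrix(c(10, 0, 0, 10), 2, 2)
  p <- fisher_exact_rxc(m)
  expect_equal(as.numeric(p), 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(attr(p, "method"), "exact")

  # proportional rows carry no signal
  prop <- matrix(c(6, 3, 4, 2), 2, 2)
  expect_equal(as.numeric(fisher_exact_rxc(prop)), 1)

  expect_error(fisher_exact_rxc(matrix(c(0, 0, 3, 4), 2, 2)), "degenerate")
})

test_that("2x2 Fisher agrees with the reference implementation everywhere", {
  set.seed(12)
  # exhaustive over small margins, sampled over larger ones
  check <- function(m) {
    ours <- as.numeric(fisher_exact_rxc(m))
    ref <- stats::fisher.test(m)$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
  for (i in 1:400) {
    r1 <- sample(1:15, 1); r2 <- sample(1:15, 1)
    a <- sample(0:r1, 1); c1 <- sample(0:r2, 1)
    m <- matrix(c(a, c1, r1 - a, r2 - c1), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    check(m)
  }
})

test_that("Monte-Carlo r x c p-values are seed-deterministic and consistent", {
  m <- matrix(c(12, 3, 5, 2, 9, 8), nrow = 3, byrow = TRUE)
  p1 <- fisher_exact_rxc(m, mc_reps = 2e4, seed = 1)
  p1b <- fisher_exact_rxc(m, mc_reps = 2e4, seed = 1)
  expect_identical(as.numeric(p1), as.numeric(p1b))
  expect_equal(attr(p1, "method"), "monte-carlo")

  p2 <- fisher_exact_rxc(m, mc_reps = 2e4, seed = 2)
  se <- sqrt(as.numeric(p1) * (1 - as.numeric(p1)) / 2e4)
  expect_lt(abs(as.numeric(p1) - as.numeric(p2)), 3 * se + 3 * se)

  # and close to the exact network-algorithm answer
  ref <- stats::fisher.test(m)$p.value
  expect_lt(abs(as.numeric(p1) - ref), 4 * se + 0.01)
})

test_that("G test matches the hand-computed statistic", {
  prop <- matrix(c(10, 5, 20, 10), 2, 2)  # proportional: G = 0, p = 1
  g0 <- g_test(prop)
  expect_equal(g0$statistic, 0, tolerance = 1e-12)
  expect_equal(g0$p.value, 1)

  m <- matrix(c(20, 5, 5, 20), 2, 2)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  g_hand <- 2 * sum(m * log(m / e))
  g <- g_test(m)
  expect_equal(g$statistic, g_hand)
  expect_equal(g$df, 1)

  expect_error(g_test(matrix(1:4, 1, 4)), "at least 2 rows")
})

test_that("Fisher and G orderings agree on clearly structured tables", {
  strong <- matrix(c(30, 2, 3, 28), 2, 2)
  weak <- matrix(c(17, 14, 15, 16), 2, 2)
  expect_lt(as.numeric(fisher_exact_rxc(strong)), as.numeric(fisher_exact_rxc(weak)))
  expect_lt(g_test(strong)$p.value, g_test(weak)$p.value)
})

test_that("high-frequency filtering sums copies across samples", {
  reads <- tibble::tibble(
    seq = c("AAA", "CCC", "TTT", "TTT"),
    count = c(60L, 49L, 25L, 25L),
    sample = c("s1", "s1", "s1", "s2")
  )
  kept <- filter_high_frequency(reads)
  expect_setequal(kept$seq, c("AAA", "TTT"))  # 25 + 25 reaches the threshold
  expect_equal(kept$total_count[kept$seq == "TTT"], 50L)

  expect_equal(nrow(filter_high_frequency(reads[0, ])), 0)
  expect_error(filter_high_frequency(tibble::tibble(seq = "A", count = 0L)),
               ">= 1")
})

test_that("reads match STs exactly, with ambiguity and novelty unassigned", {
  st_seqs <- tibble::tibble(st_id = 1:3, seq = c("AACC", "AATT", "GGCC"))
  pe_map <- tibble::tibble(st_id = 1:3, pe = c("A4", "A5", "A4"))
  reads <- tibble::tibble(seq = c("AACC", "AATT", "AAAA", "GGCC"))
  out <- match_reads_to_pes(reads, st_seqs, pe_map)
  expect_equal(out$match_status, c("assigned", "assigned", "novel", "assigned"))
  expect_equal(out$pe, c("A4", "A5", NA, "A4"))

  # a read matching STs of two PEs is ambiguous
  st2 <- tibble::tibble(st_id = 1:2, seq = c("AACC", "AACC"))
  pe2 <- tibble::tibble(st_id = 1:2, pe = c("A4", "A5"))
  amb <- match_reads_to_pes(tibble::tibble(seq = "AACC"), st2, pe2)
  expect_equal(amb$match_status, "ambiguous")
  expect_true(is.na(amb$pe))

  # trimming window applied to both sides
  win <- match_reads_to_pes(tibble::tibble(seq = "TAAT"), st_seqs, pe_map,
                            window = c(1, 3))
  expect_equal(win$match_status, "novel")
})

test_that("homopolymer correction restores the frame for single-base indels", {
  ref <- "AAACCCGGGTTT"
  ins <- "AAACCCCGGGTTT"   # one extra C
  del <- "AAACCGGGTTT"     # one C missing
  multi <- "AAACCCCCGGGTTT" # two extra: left alone, flagged
  out <- correct_homopolymers(c(ins, del, multi), ref)
  expect_equal(out$corrected[1], ref)
  expect_equal(out$corrected[2], ref)
  expect_true(out$multi_indel[3])
  expect_equal(out$corrected[3], multi)
})

test_that("depth profiles average replicate fractions with SE = sd/sqrt(n)", {
  # three replicates with fractions 0.2 / 0.3 / 0.4 for PE x at one section
  asg <- tibble::tibble(
    pe = c("x", "y", "x", "y", "x", "y"),
    match_status = "assigned",
    depth_section = 1L,
    replicate = c(1L, 1L, 2L, 2L, 3L, 3L),
    count = c(20L, 80L, 30L, 70L, 40L, 60L)
  )
  prof <- depth_profiles(asg)
  px <- prof[prof$pe == "x", ]
  expect_equal(px$mean_fraction, 0.3)
  expect_equal(px$se, stats::sd(c(0.2, 0.3, 0.4)) / sqrt(3), tolerance = 1e-12)

  # all reads one PE: flat profile at 1, SE 0
  one <- tibble::tibble(pe = "z", match_status = "assigned",
                        depth_section = rep(1:2, each = 2),
                        replicate = rep(1:2, 2), count = 10L)
  pone <- depth_profiles(one)
  expect_true(all(pone$mean_fraction == 1))
  expect_true(all(pone$se == 0))

  # per-section fractions over PEs sum to 1 (unassigned excluded)
  sums <- tapply(prof$mean_fraction, prof$depth_section, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("opposing synthetic depth gradients are recovered with power", {
  ds <- simulate_mlsa_dataset(n_records = 30, npop = 2, sigma = 5,
                              theta_site = 0.005, seed = 5,
                              recomb_within_ratio = 0, depth_gradient = 0.9,
                              locus_lengths = c(rbsK = 400))
  reads <- simulate_amplicon_reads(ds, "rbsK", reads_per_section = 150, seed = 6)
  asg <- dplyr::transmute(reads, pe = .data$true_ecotype,
                          match_status = "assigned",
                          depth_section = .data$depth_section,
                          replicate = .data$replicate, count = .data$count)
  prof <- depth_profiles(asg)
  tr <- depth_trends(prof)
  # ecotypes were generated with opposite-signed linear gradients
  expect_equal(sort(tr$trend), c("decreasing", "increasing"))
  a1 <- depth_anova(prof, tr$pe[1])
  expect_lt(a1$p.value, 0.05)
})

test_that("habitat contingency plus tests flag habitat-biased ecotypes", {
  ds <- simulate_mlsa_dataset(n_records = 80, npop = 2, sigma = 5,
                              habitat_bias = 0.95, seed = 8,
                              recomb_within_ratio = 0,
                              locus_lengths = c(rbsK = 400))
  pe_map <- ds$truth$ecotype |>
    dplyr::transmute(record_id = .data$record_id, pe = .data$ecotype)
  tab <- habitat_contingency(pe_map, ds$metadata, min_group = 5)
  expect_gte(nrow(tab), 2)
  p <- fisher_exact_rxc(tab, seed = 1)
  expect_lt(as.numeric(p), 0.05)
  expect_lt(g_test(tab)$p.value, 0.05)
})
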