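test_that("the simulator honours its degenerate and determinism contracts", {
  one <- simulate_ecotype_coalescent(1, 3, 0.1, 0.5, 0.01, 100, seed = 1)
  expect_equal(nrow(one$edges), 0)            # single lineage: no genealogy
  expect_equal(nrow(ecosim_sequences(one)), 1)
  expect_equal(one$tmrca, 0)

  a <- simulate_ecotype_coalescent(12, 3, 0.05, 0.5, 0.01, 500, seed = 42)
  b <- simulate_ecotype_coalescent(12, 3, 0.05, 0.5, 0.01, 500, seed = 42)
  expect_identical(ecosim_sequences(a), ecosim_sequences(b))
  expect_identical(a$ecotype, b$ecotype)

  # genealogy bookkeeping: every edge subtends a proper subset of tips and
  # ends no later than the root
  expect_true(all(lengths(a$edges$tips) < 12))
  expect_true(all(a$edges$end <= a$tmrca + 1e-12))
  expect_true(all(a$edges$end > a$edges$start))
})

test_that("expected segregating sites scale with theta in the neutral limit", {
  # npop = 1 runs as a plain Kingman coalescent: E[S] = theta * sum 1/i
  S <- vapply(1:400, function(i) {
    sim <- simulate_ecotype_coalescent(20, 1, 1, 1, 5 / 5000, 5000, seed = 5000 + i)
    ecomlsa:::ecosim_segregating(sim)
  }, integer(1))
  expected <- 5 * sum(1 / (1:19))
  se <- stats::sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se + 0.03 * expected)

  # doubling theta doubles E[S] (linearity)
  S2 <- vapply(1:200, function(i) {
    sim <- simulate_ecotype_coalescent(20, 1, 1, 1, 10 / 5000, 5000, seed = 9000 + i)
    ecomlsa:::ecosim_segregating(sim)
  }, integer(1))
  expect_lt(abs(mean(S2) / mean(S) - 2), 0.25)
})

test_that("strong periodic selection collapses ecotypes to tight clusters", {
  # sigma = 100 * omega: within-ecotype diversity is purged, so the cluster
  # count at a high identity cutoff concentrates on npop
  counts <- vapply(1:60, function(i) {
    sim <- simulate_ecotype_coalescent(40, 4, 0.05, 5, 0.005, 1000,
                                       seed = 300 + i)
    d <- ecomlsa:::ecosim_distances(sim$tip_states)
    ecomlsa:::n_clusters_at(d, 1000, 0.99)
  }, integer(1))
  modal <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
  expect_equal(modal, 4)
})

test_that("clade bins equal the union-find oracle and are monotone", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    sv <- setNames(vapply(seq_len(n), function(j) {
      paste(sample(c("A", "C", "G", "T"), 50, TRUE, prob = c(.7, .1, .1, .1)),
            collapse = "")
    }, character(1)), paste0("s", 1:n))
    cutoffs <- c(1, 0.98, 0.9, 0.8, 0.5)
    cb <- clade_bins(sv, cutoffs)
    expect_true(all(diff(cb$n_clusters) <= 0))
    expect_equal(cb$n_clusters[1], length(unique(unname(sv))))
    for (k in seq_along(cutoffs)) {
      expect_equal(cb$n_clusters[k], oracle_cluster_count(sv, cutoffs[k]))
    }
  }
  expect_equal(clade_bins(c(a = "AAAA", b = "AAAA"))$n_clusters, rep(1L, 6))
})

test_that("the compiled curve generator matches the reference simulator", {
  cut <- c(1, 0.99, 0.95, 0.9)
  r_counts <- vapply(1:120, function(i) {
    ecomlsa:::sim_curve(3, 0.1, 1, 0.005, 25, 800, cut, seed = i)
  }, integer(length(cut)))
  set.seed(55)
  cpp <- ecomlsa:::ecosim_curves_cpp(120L, 25L, 3L, 0.1, 1, 0.005, 800L,
                                     as.integer(floor((1 - cut) * 800 + 1e-9)))
  r_mean <- rowMeans(r_counts)
  c_mean <- colMeans(cpp$curves)
  # same model, independent implementations: means agree within MC error
  for (k in seq_along(cut)) {
    se <- sqrt(stats::var(r_counts[k, ]) / 120 + stats::var(cpp$curves[, k]) / 120)
    expect_lt(abs(r_mean[k] - c_mean[k]), 4 * se + 0.5)
  }
})

test_that("a single distinct sequence fits npop = 1", {
  obs <- tibble::tibble(record_id = c("a", "b"), seq = c("ACGTACGT", "ACGTACGT"))
  fit <- fit_ecotype_model(obs, nrep = 10, seed = 2)
  expect_equal(fit$estimates$npop, 1L)
  expect_true(all(fit$ci$low <= fit$ci$high))
})

test_that("fit output is coherent and tidies cleanly", {
  ds <- simulate_mlsa_dataset(n_records = 25, seed = 33, recomb_within_ratio = 0,
                              locus_lengths = c(l1 = 500, l2 = 500))
  conc <- concat_alignment(ds$alignments)
  fit <- fit_ecotype_model(conc, nrep = 20, npop_grid = 1:6,
                           omega_grid = 10^seq(-2, 1, length.out = 3),
                           sigma_grid = 10^seq(-2, 1, length.out = 3),
                           hillclimb = FALSE, seed = 7)
  # point estimates sit inside their confidence intervals
  est <- c(fit$estimates$npop, fit$estimates$omega, fit$estimates$sigma)
  expect_true(all(fit$ci$low <= est & est <= fit$ci$high))
  expect_true(fit$precision %in% c(1.25, 1.5, 1.75, 2))
  expect_gt(fit$score, 0)

  td <- tidy(fit)
  expect_equal(td$param, c("npop", "omega", "sigma"))
  expect_equal(td$estimate[1], fit$estimates$npop)
  gl <- glance(fit)
  expect_equal(gl$npop, fit$estimates$npop)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")

  # rerunning with the same seed reproduces the fit exactly
  fit2 <- fit_ecotype_model(conc, nrep = 20, npop_grid = 1:6,
                            omega_grid = 10^seq(-2, 1, length.out = 3),
                            sigma_grid = 10^seq(-2, 1, length.out = 3),
                            hillclimb = FALSE, seed = 7)
  expect_identical(tidy(fit), tidy(fit2))
})

test_that("demarcation splits well-separated ecotypes and lumps one clade", {
  # generator instance with two strongly purged, well-separated ecotypes
  # (within-ecotype spread ~0.4 differences, between ~6)
  ds <- simulate_mlsa_dataset(n_records = 16, npop = 2, sigma = 5,
                              recomb_within_ratio = 0, seed = 401,
                              locus_lengths = c(l1 = 500, l2 = 500))
  conc <- concat_alignment(ds$alignments)
  truth <- ds$truth$ecotype
  pes <- demarcate_pes(conc, nrep = 24, seed = 3)
  expect_equal(nrow(pes), 16)
  # partition matches the generator truth exactly
  tab <- table(pes$pe[match(truth$record_id, pes$record_id)], truth$ecotype)
  expect_equal(length(unique(pes$pe)), 2)
  expect_true(all(rowSums(tab > 0) == 1))

  # a clade of identical sequences is one PE
  same <- tibble::tibble(record_id = paste0("s", 1:5), seq = strrep("ACG", 30))
  expect_equal(unique(demarcate_pes(same, seed = 1)$pe), "PE1")
})
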