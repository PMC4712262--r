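#' Simulate a genealogy under the Stable Ecotype Model
#'
#' Backward-in-time simulation of `n_sample` lineages partitioned among
#' `npop` ecotypes.  Three event types compete:
#' \itemize{
#'   \item within-ecotype coalescence, at rate `k_e (k_e - 1) / 2` per
#'     ecotype holding `k_e` lineages;
#'   \item ecotype formation, at rate `omega` per lineage: backwards, the
#'     ecotype containing a uniformly chosen lineage merges its lineages
#'     into another (parent) ecotype, as the derived ecotype did not yet
#'     exist before its formation;
#'   \item periodic selection, at rate `sigma` per ecotype: backwards, all
#'     lineages of the swept ecotype coalesce at once into the sweep
#'     founder, purging the ecotype's diversity.
#' }
#' Once a single ancestral ecotype remains the process continues as a plain
#' neutral (Kingman) coalescent, so `npop = 1` is exactly the neutral
#' single-population limit.  Mutations are overlaid on branches as a Poisson
#' process at rate `theta_site * L / 2` per lineage per coalescent time
#' unit, each hitting a uniformly chosen site.
#'
#' @param n_sample Number of sampled lineages (>= 1).
#' @param npop Number of ecotypes.
#' @param omega Ecotype formation rate (per lineage per coalescent unit).
#' @param sigma Periodic selection rate (per ecotype per coalescent unit).
#' @param theta_site Per-site scaled mutation intensity (4Nu per site).
#' @param L Number of sites.
#' @param seed Optional integer seed; fixing it fixes all outputs.
#' @param max_events Guard against non-convergent genealogies.
#' @return Object of class `ecosim_genealogy`: list with `edges` (tibble
#'   `start`, `end`, `tips` list column), `mutations` (tibble `site`,
#'   `time`, `tips`), `tip_states` (character matrix, mutated sites x
#'   tips), `ancestral` (character vector length `L`), `ecotype` (initial
#'   ecotype index per tip), `tmrca`, and the parameters.
#' @export
simulate_ecotype_coalescent <- function(n_sample, npop, omega, sigma,
                                        theta_site, L, seed = NULL,
                                        max_events = 1e6) {
  core <- function() ecosim_core(n_sample, npop, omega, sigma, theta_site,
                                 L, max_events)
  res <- if (is.null(seed)) core() else withr::with_seed(seed, core())
  n_edges <- length(res$tips)
  edges_tbl <- tibble(start = res$starts, end = res$ends, tips = res$tips)
  mut_tbl <- tibble(site = res$mut$site, time = res$mut$time,
                    tips = if (length(res$mut$edge))
                      res$tips[res$mut$edge] else list(),
                    offset = res$mut$offset)
  bases <- c("A", "C", "G", "T")
  ts_chr <- matrix(bases[res$tip_states], nrow = nrow(res$tip_states),
                   dimnames = dimnames(res$tip_states))
  structure(list(
    edges = edges_tbl, mutations = mut_tbl, ancestral = bases[res$ancestral],
    tip_states = ts_chr, ecotype = res$ecotype,
    tmrca = res$tmrca, n_sample = n_sample, L = L,
    params = list(npop = npop, omega = omega, sigma = sigma,
                  theta_site = theta_site),
    seed = seed
  ), class = "ecosim_genealogy")
}

# Lean simulation core; assumes the caller controls the RNG state.
ecosim_core <- function(n_sample, npop, omega, sigma, theta_site, L,
                        max_events = 1e6) {
  stopifnot(n_sample >= 1, npop >= 1, omega > 0, sigma > 0,
            theta_site >= 0, L >= 1)
  comp0 <- sample.int(npop, n_sample, replace = TRUE)
  tips <- lapply(seq_len(n_sample), identity)
  comp <- comp0
  births <- rep(0, n_sample)
  e_start <- numeric(0); e_end <- numeric(0); e_tips <- list()
  add_edge <- function(i, t) {
    e_start[[length(e_start) + 1L]] <<- births[i]
    e_end[[length(e_end) + 1L]] <<- t
    e_tips[[length(e_tips) + 1L]] <<- tips[[i]]
  }
  t <- 0
  n_ev <- 0L
  while (length(tips) > 1) {
    n_ev <- n_ev + 1L
    if (n_ev > max_events) abort("simulation error: event cap exceeded")
    k <- length(tips)
    cnt <- tabulate(comp)
    active <- which(cnt > 0)
    ncomp <- length(active)
    pairs_e <- cnt[active] * (cnt[active] - 1) / 2
    rate_coal <- sum(pairs_e)
    rate_form <- if (ncomp > 1) omega * k else 0
    rate_ps <- if (ncomp > 1) sigma * ncomp else 0
    total <- rate_coal + rate_form + rate_ps
    t <- t + stats::rexp(1, total)
    u <- stats::runif(1) * total
    if (u < rate_coal) {
      ce <- active[sample.int(ncomp, 1, prob = pairs_e)]
      members <- which(comp == ce)
      ab <- members[sample.int(length(members), 2)]
      add_edge(ab[1], t); add_edge(ab[2], t)
      tips[[ab[1]]] <- c(tips[[ab[1]]], tips[[ab[2]]])
      births[ab[1]] <- t
      tips[[ab[2]]] <- NULL
      comp <- comp[-ab[2]]
      births <- births[-ab[2]]
    } else if (u < rate_coal + rate_form) {
      lin <- sample.int(k, 1)
      ce <- comp[lin]
      others <- setdiff(active, ce)
      target <- others[sample.int(length(others), 1)]
      comp[comp == ce] <- target
    } else {
      ce <- active[sample.int(ncomp, 1)]
      members <- which(comp == ce)
      if (length(members) >= 2) {
        for (i in members) add_edge(i, t)
        keep <- members[1]
        tips[[keep]] <- unlist(tips[members], use.names = FALSE)
        births[keep] <- t
        drop <- members[-1]
        tips[drop] <- NULL
        comp <- comp[-drop]
        births <- births[-drop]
      }
    }
  }
  mut <- overlay_mutations(e_start, e_end, theta_site, L)
  anc <- sample.int(4L, L, replace = TRUE)
  tip_states <- resolve_tip_states(mut, e_tips, anc, n_sample)
  list(starts = e_start, ends = e_end, tips = e_tips, mut = mut,
       ancestral = anc, tip_states = tip_states, ecotype = comp0, tmrca = t)
}

# Vectorised Poisson mutation overlay over all edges at once.
overlay_mutations <- function(e_start, e_end, theta_site, L) {
  empty <- list(site = integer(0), time = numeric(0), edge = integer(0),
                offset = integer(0))
  if (length(e_start) == 0 || theta_site == 0) return(empty)
  rate <- theta_site * L / 2
  lens <- e_end - e_start
  nm <- stats::rpois(length(lens), rate * lens)
  total <- sum(nm)
  if (total == 0) return(empty)
  edge <- rep.int(seq_along(lens), nm)
  list(
    site = sample.int(L, total, replace = TRUE),
    time = stats::runif(total, e_start[edge], e_end[edge]),
    edge = edge,
    offset = sample.int(3L, total, replace = TRUE)
  )
}

# Tip states (integer-coded bases 1..4) at mutated sites.  Mutations at one
# site are applied oldest first; every tip below an edge shares its state at
# the moment a mutation on that edge occurs, so sequential application is
# exact.  The offset picks one of the three non-current bases.
resolve_tip_states <- function(mut, e_tips, ancestral, n_sample) {
  alt <- matrix(c(2L, 3L, 4L, 1L, 3L, 4L, 1L, 2L, 4L, 1L, 2L, 3L),
                nrow = 4, byrow = TRUE)
  sites <- sort(unique(mut$site))
  if (length(sites) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = n_sample))
  }
  out <- matrix(NA_integer_, nrow = length(sites), ncol = n_sample,
                dimnames = list(as.character(sites), NULL))
  ord <- order(mut$site, -mut$time)
  site_o <- mut$site[ord]
  edge_o <- mut$edge[ord]
  off_o <- mut$offset[ord]
  idx <- split(seq_along(site_o), match(site_o, sites))
  for (r in seq_along(sites)) {
    state <- rep.int(ancestral[sites[r]], n_sample)
    for (i in idx[[r]]) {
      tt <- e_tips[[edge_o[i]]]
      state[tt] <- alt[state[tt[1]], off_o[i]]
    }
    out[r, ] <- state
  }
  out
}

#' Materialise simulated sequences
#'
#' @param sim An `ecosim_genealogy`.
#' @param prefix Record id prefix.
#' @return Tibble (`record_id`, `seq`) of `n_sample` aligned sequences.
#' @export
ecosim_sequences <- function(sim, prefix = "sim") {
  stopifnot(inherits(sim, "ecosim_genealogy"))
  anc <- sim$ancestral
  seqs <- vapply(seq_len(sim$n_sample), function(i) {
    x <- anc
    if (nrow(sim$tip_states) > 0) {
      x[as.integer(rownames(sim$tip_states))] <- sim$tip_states[, i]
    }
    paste(x, collapse = "")
  }, character(1))
  tibble(record_id = sprintf("%s%03d", prefix, seq_len(sim$n_sample)), seq = seqs)
}

# Number of segregating sites of a simulated sample, computed sparsely from
# the mutated-site states.
ecosim_segregating <- function(sim) {
  ts <- if (inherits(sim, "ecosim_genealogy")) sim$tip_states else sim
  if (nrow(ts) == 0) return(0L)
  sum(apply(ts, 1, function(x) length(unique(x)) > 1))
}

# Pairwise difference matrix of a simulated sample over mutated sites only.
ecosim_distances <- function(sim) {
  ts <- if (inherits(sim, "ecosim_genealogy")) sim$tip_states else sim
  n <- ncol(ts)
  d <- matrix(0, n, n)
  if (nrow(ts) == 0) return(d)
  for (b in unique(as.vector(ts))) {
    ind <- (ts == b) * 1
    d <- d + crossprod(ind)
  }
  d <- nrow(ts) - d
  diag(d) <- 0
  d
}

#' Cluster counts along a ladder of sequence-identity cutoffs
#'
#' Single-linkage clustering of aligned sequences at each identity cutoff:
#' two sequences link when their identity (1 - differences / length) is at
#' least the cutoff.  Counts are non-increasing as the cutoff decreases; at
#' cutoff 1.0 the count equals the number of distinct sequences.
#'
#' @param seqs Tibble (`record_id`, `seq`) or named character vector of
#'   equal-length sequences.
#' @param identity_cutoffs Decreasing identity thresholds.
#' @return Tibble (`cutoff`, `n_clusters`).
#' @export
clade_bins <- function(seqs, identity_cutoffs = c(1, 0.995, 0.99, 0.98, 0.95, 0.90)) {
  sv <- as_seq_vector(seqs)
  L <- nchar(sv[[1]])
  d <- hamming_matrix(sv)
  tibble(cutoff = identity_cutoffs,
         n_clusters = n_clusters_at(d, L, identity_cutoffs))
}

# Cluster counts from a difference matrix (single linkage).
n_clusters_at <- function(d, L, cutoffs) {
  n <- nrow(d)
  if (n == 1) return(rep(1L, length(cutoffs)))
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  heights <- hc$height
  vapply(cutoffs, function(cc) {
    thr <- (1 - cc) * L + 1e-9
    as.integer(n - sum(heights <= thr))
  }, integer(1))
}

# Simulate one replicate (under the current RNG stream position when seed is
# NULL) and return its clade-bin cluster counts.
sim_curve <- function(npop, omega, sigma, theta_site, n_sample, L, cutoffs,
                      seed = NULL) {
  res <- if (is.null(seed)) {
    ecosim_core(n_sample, npop, omega, sigma, theta_site, L)
  } else {
    withr::with_seed(seed, ecosim_core(n_sample, npop, omega, sigma, theta_site, L))
  }
  n_clusters_at(ecosim_distances(res$tip_states), L, cutoffs)
}
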