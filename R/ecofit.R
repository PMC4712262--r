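#' Fit Stable Ecotype Model parameters to an observed clade-bin curve
#'
#' Likelihood-free fit of (`npop`, `omega`, `sigma`).  For each candidate
#' parameter combination, replicate genealogies are simulated and the score
#' is the fraction of replicates whose clade-bin curve matches the observed
#' curve within a precision factor `f`: every cutoff bin must satisfy
#' `sim in [obs / f, obs * f]`.  The smallest factor on the precision
#' ladder (1.25x to 2x) at which any candidate scores above zero is the
#' reported precision ("best precision match"); the point estimate
#' maximises the score at that precision, after a local hill-climb around
#' the best grid point.  The 95\% confidence interval of each parameter is
#' the range of evaluated values whose best score, profiling over the other
#' two parameters, reaches the acceptance threshold (5\% of replicates
#' matching).
#'
#' @param observed Either a tibble (`record_id`, `seq`) of aligned
#'   sequences, or a clade-bin curve tibble from [clade_bins()] (then
#'   `n_sample`, `L` and `theta_site` must be given).
#' @param identity_cutoffs Identity ladder used for the comparison summary.
#' @param n_sample,L,theta_site Simulation sample size, region length and
#'   per-site mutation intensity; derived from the sequences when
#'   `observed` holds sequences (theta from Watterson's estimate per site
#'   on the de-duplicated set).
#' @param dedupe Collapse duplicate sequences before comparison (the fit is
#'   run on distinct haplotypes, with the full-to-distinct bookkeeping kept
#'   in the output).
#' @param npop_grid,omega_grid,sigma_grid Candidate grids; defaults are
#'   `1..min(n_distinct, 12)` and six log-spaced values over `1e-3..1e2`.
#' @param nrep Simulation replicates per candidate.
#' @param precisions Precision-factor ladder.
#' @param ci_threshold Score needed for a value to enter the CI (default
#'   0.05).
#' @param precision_min_score Reliability level defining the "best
#'   precision match": the reported precision is the smallest factor at
#'   which the best candidate's score reaches this fraction of replicates
#'   (default 0.25).
#' @param hillclimb Refine around the best grid point.
#' @param max_hill Maximum hill-climb iterations.
#' @param calibrate_theta Per candidate, rescale `theta_site` so that pilot
#'   simulations reproduce the observed mean pairwise difference (mutation
#'   counts are linear in theta), letting the curve shape rather than the
#'   total diversity discriminate candidates.
#' @param n_pilot Pilot replicates used for the theta calibration.
#' @param seed Integer seed controlling all replicates.
#' @return Object of class `ecotype_fit` with elements `estimates`, `ci`,
#'   `precision`, `score`, `grid` (all evaluated candidates with scores),
#'   `observed`, `n_sample`, `L`, `theta_site`, `nrep`, `seed`.
#' @export
fit_ecotype_model <- function(observed,
                              identity_cutoffs = c(1, 0.995, 0.99, 0.98, 0.95, 0.90),
                              n_sample = NULL, L = NULL, theta_site = NULL,
                              dedupe = TRUE,
                              npop_grid = NULL,
                              omega_grid = 10^seq(-3, 2, length.out = 6),
                              sigma_grid = 10^seq(-3, 2, length.out = 6),
                              nrep = 100, precisions = c(1.25, 1.5, 1.75, 2),
                              ci_threshold = 0.05, precision_min_score = 0.25,
                              hillclimb = TRUE,
                              max_hill = 3, calibrate_theta = TRUE,
                              n_pilot = 6, seed = 1) {
  n_total <- NA_integer_
  if (is.data.frame(observed) && all(c("record_id", "seq") %in% names(observed))) {
    sv <- as_seq_vector(observed)
    n_total <- length(sv)
    if (dedupe) sv <- sv[!duplicated(unname(sv))]
    n_sample <- length(sv)
    L <- nchar(sv[[1]])
    if (is.null(theta_site)) {
      theta_site <- if (n_sample >= 2) {
        watterson_theta(segregating_sites(sv), n_sample) / L
      } else 1e-3
    }
    obs_curve <- clade_bins(sv, identity_cutoffs)
  } else if (is.data.frame(observed) && all(c("cutoff", "n_clusters") %in% names(observed))) {
    if (is.null(n_sample) || is.null(L) || is.null(theta_site)) {
      abort("when observed is a curve, n_sample, L and theta_site are required")
    }
    obs_curve <- observed
    identity_cutoffs <- observed$cutoff
  } else {
    abort("observed must be sequences (record_id, seq) or a clade-bin curve")
  }
  obs <- obs_curve$n_clusters
  obs_pwd <- if (exists("sv", inherits = FALSE) && length(sv) >= 2) {
    d <- hamming_matrix(sv)
    mean(d[upper.tri(d)])
  } else NA_real_
  if (is.null(npop_grid)) npop_grid <- seq_len(max(1L, min(n_sample, 12L)))

  cand <- tidyr::expand_grid(npop = npop_grid, omega = omega_grid, sigma = sigma_grid)
  max_diff <- as.integer(floor((1 - identity_cutoffs) * L + 1e-9))
  evaluated <- new.env(parent = emptyenv())
  eval_candidate <- function(npop, omega, sigma) {
    key <- paste(npop, signif(omega, 8), signif(sigma, 8), sep = "_")
    hit <- evaluated[[key]]
    if (!is.null(hit)) return(hit)
    seed_c <- seed + length(ls(evaluated)) + 1L
    theta_c <- theta_site
    if (calibrate_theta && !is.na(obs_pwd)) {
      if (obs_pwd == 0) {
        theta_c <- 0
      } else {
        # mutation-free pilot: expected pairwise differences are
        # theta_site * L * T for mean pair coalescence time T, so theta is
        # set from the observed mean pairwise difference directly
        pilot <- withr::with_seed(
          seed_c,
          ecosim_curves_cpp(n_pilot, n_sample, as.integer(npop), omega, sigma,
                            0, as.integer(L), max_diff)
        )
        tbar <- mean(pilot$mean_tpair)
        if (tbar > 0) {
          theta_c <- min(max(obs_pwd / (L * tbar), 1e-7), 10)
        }
      }
    }
    curves <- withr::with_seed(
      seed_c + 1L,
      ecosim_curves_cpp(nrep, n_sample, as.integer(npop), omega, sigma,
                        theta_c, as.integer(L), max_diff)
    )$curves
    scores <- vapply(precisions, function(f) {
      lo <- matrix(obs / f, nrow = nrep, ncol = length(obs), byrow = TRUE)
      hi <- matrix(obs * f, nrow = nrep, ncol = length(obs), byrow = TRUE)
      mean(rowSums(curves >= lo & curves <= hi) == length(obs))
    }, numeric(1))
    res <- list(npop = npop, omega = omega, sigma = sigma,
                theta_used = theta_c, scores = scores)
    evaluated[[key]] <- res
    res
  }

  purrr::pwalk(cand, function(npop, omega, sigma) {
    eval_candidate(npop, omega, sigma)
  })

  collect <- function() {
    vals <- mget(ls(evaluated), envir = evaluated)
    tibble(
      npop = map_dbl(vals, "npop"), omega = map_dbl(vals, "omega"),
      sigma = map_dbl(vals, "sigma"),
      scores = map(vals, "scores")
    )
  }
  # "best precision match": the smallest factor at which the best candidate
  # reproduces the observation reliably (>= precision_min_score of
  # replicates).  Requiring a marginal match only (a single replicate)
  # would collapse the confidence intervals to the lucky candidate.  Fall
  # back to the smallest factor clearing the CI threshold, then to any
  # match at all.
  pick_precision <- function(tab) {
    sc <- do.call(rbind, tab$scores)
    for (i in seq_along(precisions)) {
      if (max(sc[, i]) >= precision_min_score) return(i)
    }
    for (i in seq_along(precisions)) {
      if (max(sc[, i]) >= ci_threshold) return(i)
    }
    for (i in seq_along(precisions)) {
      if (max(sc[, i]) > 0) return(i)
    }
    NA_integer_
  }

  tab <- collect()
  pi <- pick_precision(tab)
  if (is.na(pi)) {
    abort(paste0(
      "fit failure: no candidate matched the observed clade-bin curve at ",
      "precision 2x (observed bins ", paste(obs, collapse = "/"),
      ", n_sample ", n_sample, ", theta_site ", signif(theta_site, 3), ")"
    ))
  }
  score_at <- function(tab, i) vapply(tab$scores, `[[`, numeric(1), i)

  best_row <- function(tab, i) {
    sc <- score_at(tab, i)
    tab[order(-sc, tab$npop, tab$omega, tab$sigma)[1], ]
  }
  best <- best_row(tab, pi)

  if (hillclimb) {
    step <- sqrt(10)
    for (iter in seq_len(max_hill)) {
      cur_score <- score_at(best, pi)
      nb <- tidyr::expand_grid(
        npop = unique(pmax(1L, c(best$npop - 1L, best$npop, best$npop + 1L))),
        omega = c(best$omega / step, best$omega, best$omega * step),
        sigma = c(best$sigma / step, best$sigma, best$sigma * step)
      )
      purrr::pwalk(nb, function(npop, omega, sigma) eval_candidate(npop, omega, sigma))
      tab <- collect()
      pi <- pick_precision(tab)
      new_best <- best_row(tab, pi)
      if (score_at(new_best, pi) <= cur_score &&
          identical(unlist(new_best[1:3]), unlist(best[1:3]))) break
      if (score_at(new_best, pi) <= cur_score) break
      best <- new_best
    }
  }

  tab <- collect()
  pi <- pick_precision(tab)
  best <- best_row(tab, pi)
  sc <- score_at(tab, pi)
  ci_of <- function(param) {
    ok <- tab[[param]][sc >= ci_threshold]
    ok <- unique(c(ok, best[[param]]))
    c(min(ok), max(ok))
  }
  ci <- tibble(
    param = c("npop", "omega", "sigma"),
    low = as.numeric(c(ci_of("npop")[1], ci_of("omega")[1], ci_of("sigma")[1])),
    high = as.numeric(c(ci_of("npop")[2], ci_of("omega")[2], ci_of("sigma")[2]))
  )
  grid_out <- mutate(tab, score = sc) |>
    select("npop", "omega", "sigma", "score") |>
    arrange(desc(.data$score))
  structure(list(
    estimates = list(npop = as.integer(best$npop), omega = best$omega,
                     sigma = best$sigma),
    ci = ci, precision = precisions[pi], score = score_at(best, pi),
    grid = grid_out, observed = obs_curve,
    n_sample = n_sample, n_total = n_total, L = L, theta_site = theta_site,
    nrep = nrep, seed = seed
  ), class = "ecotype_fit")
}

#' @export
print.ecotype_fit <- function(x, ...) {
  cat("Stable Ecotype Model fit\n")
  cat(sprintf("  npop  %d (95%% CI %g-%g)\n", x$estimates$npop,
              x$ci$low[1], x$ci$high[1]))
  cat(sprintf("  omega %.4g (95%% CI %.4g-%.4g)\n", x$estimates$omega,
              x$ci$low[2], x$ci$high[2]))
  cat(sprintf("  sigma %.4g (95%% CI %.4g-%.4g)\n", x$estimates$sigma,
              x$ci$low[3], x$ci$high[3]))
  cat(sprintf("  precision %gx, score %.2f (%d reps/candidate, n=%d, L=%d)\n",
              x$precision, x$score, x$nrep, x$n_sample, x$L))
  invisible(x)
}

#' Tidy an ecotype model fit
#'
#' @param x An `ecotype_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `param`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.ecotype_fit <- function(x, ...) {
  tibble(param = c("npop", "omega", "sigma"),
         estimate = unname(c(x$estimates$npop, x$estimates$omega,
                             x$estimates$sigma)),
         conf.low = unname(x$ci$low), conf.high = unname(x$ci$high))
}

#' One-row summary of an ecotype model fit
#'
#' @inheritParams tidy.ecotype_fit
#' @return One-row tibble (`npop`, `omega`, `sigma`, `precision`, `score`,
#'   `nrep`, `n_sample`).
#' @export
glance.ecotype_fit <- function(x, ...) {
  tibble(npop = x$estimates$npop, omega = x$estimates$omega,
         sigma = x$estimates$sigma, precision = x$precision,
         score = x$score, nrep = x$nrep, n_sample = x$n_sample)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot profile scores of an ecotype model fit
#'
#' One panel per parameter showing the profiled match score across the
#' evaluated candidate values, with the point estimate marked.
#'
#' @param object An `ecotype_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecotype_fit <- function(object, ...) {
  prof <- bind_rows(lapply(c("npop", "omega", "sigma"), function(p) {
    object$grid |>
      group_by(value = .data[[p]]) |>
      summarise(score = max(.data$score), .groups = "drop") |>
      mutate(param = p)
  }))
  est <- tibble(param = c("npop", "omega", "sigma"),
                value = c(object$estimates$npop, object$estimates$omega,
                          object$estimates$sigma))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$value, y = .data$score)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(data = est, ggplot2::aes(xintercept = .data$value),
                        linetype = 2, colour = "firebrick") +
    ggplot2::facet_wrap(~param, scales = "free_x") +
    ggplot2::labs(x = "candidate value", y = "match score") +
    ggplot2::theme_minimal()
}

#' Demarcate putative ecotypes on a tree
#'
#' Conservative top-down demarcation: starting at the root, a clade is
#' declared a single putative ecotype (PE) when it is a single distinct
#' sequence, or when re-fitting the Stable Ecotype Model to that clade
#' alone yields an `npop` point estimate of 1; otherwise the procedure
#' recurses into the clade's children.  Every record ends in exactly one
#' PE; long-branch singletons naturally become singleton PEs.
#'
#' @param seqs Tibble (`record_id`, `seq`); duplicates are collapsed and
#'   mapped back in the result.
#' @param tree Optional rooted `phylo` over the distinct sequences' record
#'   ids.  When absent, a UPGMA tree built from pairwise differences is
#'   used as a distance-based fallback.
#' @param theta_site Mutation intensity passed to the clade fits; estimated
#'   from the full set when `NULL`.
#' @param npop_max Largest `npop` candidate per clade fit.
#' @param nrep Replicates per candidate in clade fits.
#' @param omega_grid,sigma_grid Candidate grids for clade fits.
#' @param identity_cutoffs Identity ladder for the clade fits.  Finer than
#'   the whole-sample default because demarcation operates at the sub-1\%
#'   divergence scale; the exact-identity bin (cutoff 1.0) is omitted: after
#'   de-duplication it always equals the clade size, carrying no information
#'   about structure while penalising strong-purging candidates.
#' @param seed Integer seed.
#' @return Tibble (`record_id`, `pe`).
#' @export
demarcate_pes <- function(seqs, tree = NULL, theta_site = NULL,
                          npop_max = 6L, nrep = 24,
                          omega_grid = 10^seq(-2, 1, length.out = 4),
                          sigma_grid = 10^seq(-2, 1.5, length.out = 4),
                          identity_cutoffs = c(0.999, 0.998, 0.995, 0.99,
                                               0.98, 0.95, 0.90),
                          seed = 1) {
  sv <- as_seq_vector(seqs)
  rep_of <- vapply(unname(sv), function(s) names(sv)[match(s, sv)][1], "")
  uniq <- sv[!duplicated(unname(sv))]
  n <- length(uniq)
  L <- nchar(uniq[[1]])
  if (is.null(theta_site)) {
    theta_site <- if (n >= 2) watterson_theta(segregating_sites(uniq), n) / L else 1e-3
  }
  if (is.null(tree)) {
    if (n >= 2) {
      d <- hamming_matrix(uniq)
      hc <- stats::hclust(stats::as.dist(d), method = "average")
      tree <- ape::as.phylo(hc)
    }
  } else {
    if (!ape::is.rooted(tree)) abort("supplied tree must be rooted")
    missing <- setdiff(names(uniq), tree$tip.label)
    if (length(missing) > 0) {
      abort(paste0("tree is missing distinct-sequence tips: ",
                   paste(missing, collapse = ", ")))
    }
    tree <- ape::keep.tip(tree, names(uniq))
  }
  labels <- character(0)
  assign_pe <- function(ids) {
    labels[length(labels) + 1] <<- paste0("PE", length(labels) + 1)
    setNames(rep(labels[length(labels)], length(ids)), ids)
  }
  clade_seed <- 0L
  rec <- function(ids) {
    clade_seed <<- clade_seed + 1L
    if (length(ids) == 1) return(assign_pe(ids))
    sub <- uniq[ids]
    if (length(unique(unname(sub))) == 1) return(assign_pe(ids))
    # no structure at any cutoff of the ladder: nothing to subdivide
    cb <- clade_bins(tibble(record_id = ids, seq = unname(sub)), identity_cutoffs)
    if (all(cb$n_clusters == 1)) return(assign_pe(ids))
    fit <- tryCatch(
      fit_ecotype_model(tibble(record_id = ids, seq = unname(sub)),
                        identity_cutoffs = identity_cutoffs,
                        theta_site = theta_site,
                        npop_grid = seq_len(min(npop_max, length(ids))),
                        omega_grid = omega_grid, sigma_grid = sigma_grid,
                        nrep = nrep, hillclimb = FALSE,
                        seed = seed + clade_seed),
      error = function(e) NULL)
    if (!is.null(fit) && fit$estimates$npop == 1) return(assign_pe(ids))
    kids <- clade_children(tree, ids)
    out <- character(0)
    for (k in kids) out <- c(out, rec(k))
    out
  }
  pe_uniq <- if (n == 1) assign_pe(names(uniq)) else rec(tree$tip.label)
  tibble(record_id = names(sv), pe = unname(pe_uniq[rep_of]))
}

# Children tip sets of the smallest clade containing `ids` in a rooted tree.
clade_children <- function(tree, ids) {
  if (length(ids) == 2) return(list(ids[1], ids[2]))
  node <- ape::getMRCA(tree, ids)
  kids <- phangorn_children(tree, node)
  out <- lapply(kids, function(k) {
    if (k <= length(tree$tip.label)) {
      tree$tip.label[k]
    } else {
      ape::extract.clade(tree, k)$tip.label
    }
  })
  out <- lapply(out, function(x) intersect(x, ids))
  out[lengths(out) > 0]
}

# Direct children of a node from the edge table (no phangorn dependency).
phangorn_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}
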