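# Synthetic data generation and the benchmark experiments: the
# TIMMA-vs-PKIM threshold sweep on uniform random data, planted-pathway
# recovery fixtures, and the optimality comparison of the selection
# algorithms against exhaustive search.

#' Simulation configuration
#'
#' The default configuration is the benchmark condition used throughout:
#' 100 drugs, 10 targets, binding affinities and treatment efficacies both
#' uniform on [0, 1] (the maximally uncertain case), binarization threshold
#' grid 0 to 1 in steps of 0.01.
#'
#' @param n_drugs,n_targets Panel dimensions.
#' @param thresholds Binarization threshold grid in [0, 1].
#' @param n_replicates Number of simulated datasets.
#' @param seed Base seed; each replicate perturbs the stream
#'   deterministically.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(n_drugs = 100L, n_targets = 10L,
                              thresholds = seq(0, 1, by = 0.01),
                              n_replicates = 100L, seed = 1L) {
  stopifnot(n_drugs >= 2L, n_targets >= 1L, n_replicates >= 1L,
            all(thresholds >= 0 & thresholds <= 1))
  structure(list(n_drugs = as.integer(n_drugs),
                 n_targets = as.integer(n_targets),
                 thresholds = thresholds,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.replicate_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + replicate)
}

#' Simulate a uniform random drug-target dataset
#'
#' @param cfg A \code{simulation_config}.
#' @param replicate Replicate index (>= 1); the same (seed, replicate) pair
#'   always yields the same dataset.
#' @return A list with \code{affinity} (scaled affinity matrix) and
#'   \code{panel} (a scaled \code{drug_panel}).
#' @export
simulate_dataset <- function(cfg, replicate = 1L) {
  set.seed(.replicate_seed(cfg$seed, replicate))
  a <- matrix(stats::runif(cfg$n_drugs * cfg$n_targets),
              cfg$n_drugs, cfg$n_targets,
              dimnames = list(sprintf("d%03d", seq_len(cfg$n_drugs)),
                              sprintf("T%02d", seq_len(cfg$n_targets))))
  y <- stats::runif(cfg$n_drugs)
  panel <- drug_panel(rownames(a), y, scaled_efficacy = y)
  list(affinity = affinity_matrix(a, "scaled"), panel = panel)
}

#' Generate planted-pathway data
#'
#' Draws random binary drug-target profiles and assigns each drug an
#' efficacy of 1 when its profile hits every planted parallel pathway
#' (the survival-pathway semantics of the inhibition network) and a
#' baseline near 0 otherwise, plus optional Gaussian noise clipped to
#' [0, 1].  Used for recovery tests: with zero noise, model selection
#' should attain zero leave-one-out error on a set covering the pathways,
#' and the fitted network should reproduce the planted family.
#'
#' @param n_drugs Number of drugs.
#' @param pathways List of character vectors of target names (the planted
#'   parallel pathways); their union defines the informative targets.
#' @param n_targets Total number of targets (>= the pathway union;
#'   extra targets are uninformative decoys).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param baseline Efficacy of drugs that fail to block every pathway.
#' @param p_inhibit Per-entry inhibition probability of the random
#'   profiles.
#' @param replicate_profiles Each sampled profile is repeated this many
#'   times (default 1, fully random).  With 2 or more, every inhibition
#'   state realized in the data appears at least twice, so noise-free data
#'   fully determine the planted function under leave-one-out evaluation --
#'   the setting recovery tests rely on.
#' @param seed Seed.
#' @return A list with \code{X} (\code{binary_target_matrix}),
#'   \code{panel}, and \code{pathways}.
#' @export
planted_network_dataset <- function(n_drugs, pathways, n_targets = NULL,
                                    noise_sd = 0, baseline = 0,
                                    p_inhibit = 0.5,
                                    replicate_profiles = 1L, seed = 1L) {
  stopifnot(length(pathways) >= 1L,
            n_drugs %% replicate_profiles == 0L)
  used <- unique(unlist(pathways))
  if (is.null(n_targets)) n_targets <- length(used)
  stopifnot(n_targets >= length(used))
  targets <- c(used, setdiff(sprintf("N%02d", seq_len(n_targets)), used))
  targets <- targets[seq_len(n_targets)]
  set.seed(seed)
  n_unique <- n_drugs %/% replicate_profiles
  x <- matrix(stats::rbinom(n_unique * n_targets, 1L, p_inhibit),
              n_unique, n_targets)
  x <- x[rep(seq_len(n_unique), each = replicate_profiles), , drop = FALSE]
  dimnames(x) <- list(sprintf("d%03d", seq_len(n_drugs)), targets)
  blocked <- apply(x, 1L, function(row) {
    all(vapply(pathways, function(p) any(row[p] == 1L), TRUE))
  })
  y <- ifelse(blocked, 1, baseline)
  if (noise_sd > 0) y <- pmin(1, pmax(0, y + stats::rnorm(n_drugs, 0, noise_sd)))
  list(X = affinity_matrix(x, "binary"),
       panel = drug_panel(rownames(x), y, scaled_efficacy = y),
       pathways = pathways)
}

#' Threshold sweep comparing TIMMA and PKIM
#'
#' For each replicate and each binarization threshold, binarizes the
#' simulated affinities, computes the mean leave-one-out error of both
#' predictors on the full target set, and converts the errors to
#' accuracies (1 - error).  The relative accuracy improvement of TIMMA
#' over PKIM, \code{100 * (acc_T - acc_P) / acc_P}, is aggregated per
#' threshold and as a grand mean over thresholds below
#' \code{grand_max_threshold}, with empirical 95% intervals over
#' replicates.
#'
#' @param cfg A \code{simulation_config}.
#' @param na_policy Non-identifiable/non-determinable policy for both
#'   models alike (see \code{\link{loo_error}}).
#' @param grand_max_threshold Upper bound (exclusive) of the thresholds
#'   entering the grand mean (default 0.8, the promiscuous regime with on
#'   average more than two targets per drug).
#' @return A \code{benchmark_report} list: \code{per_threshold} data frame
#'   (mean errors, mean improvement with 95% interval, mean targets per
#'   drug), \code{grand} (grand mean improvement, its replicate-level 95%
#'   interval, paired t-test of the per-replicate accuracies), and
#'   \code{replicate_grand} (one grand mean per replicate).
#' @export
threshold_sweep_compare <- function(cfg, na_policy = "half",
                                    grand_max_threshold = 0.8) {
  ths <- cfg$thresholds
  nt <- length(ths)
  imp <- err_t <- err_p <- matrix(NA_real_, cfg$n_replicates, nt)
  tpd <- matrix(NA_real_, cfg$n_replicates, nt)
  for (r in seq_len(cfg$n_replicates)) {
    sim <- simulate_dataset(cfg, r)
    a <- unclass(sim$affinity)
    y <- sim$panel$scaled_efficacy
    bits <- 2L^(seq_len(cfg$n_targets) - 1L)
    for (j in seq_len(nt)) {
      x <- (a >= ths[j]) + 0L
      masks <- as.integer(x %*% bits)
      et <- .loo_masks(masks, y, .timma_predictor, na_policy)
      ep <- .loo_masks(masks, y, .pkim_predictor, na_policy)
      err_t[r, j] <- et
      err_p[r, j] <- ep
      imp[r, j] <- 100 * ((1 - et) - (1 - ep)) / (1 - ep)
      tpd[r, j] <- mean(rowSums(x))
    }
  }
  q <- function(v, p) unname(stats::quantile(v, p, na.rm = TRUE))
  per_threshold <- data.frame(
    threshold = ths,
    err_timma = colMeans(err_t), err_pkim = colMeans(err_p),
    improvement = colMeans(imp),
    improvement_lo = apply(imp, 2L, q, 0.025),
    improvement_hi = apply(imp, 2L, q, 0.975),
    targets_per_drug = colMeans(tpd))
  sel <- ths < grand_max_threshold
  rep_grand <- rowMeans(imp[, sel, drop = FALSE])
  ttest <- stats::t.test(rowMeans((1 - err_t)[, sel, drop = FALSE]),
                         rowMeans((1 - err_p)[, sel, drop = FALSE]),
                         paired = TRUE)
  structure(list(
    per_threshold = per_threshold,
    grand = list(mean_improvement = mean(rep_grand),
                 ci = c(q(rep_grand, 0.025), q(rep_grand, 0.975)),
                 max_threshold = grand_max_threshold,
                 paired_p = ttest$p.value),
    replicate_grand = rep_grand,
    config = cfg,
    definitions = paste("accuracy = 1 - mean LOO error;",
                        "improvement = 100 * (acc_TIMMA - acc_PKIM) / acc_PKIM;",
                        "full target set (no model selection);",
                        "na_policy =", na_policy)),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("TIMMA vs PKIM threshold sweep (", x$config$n_replicates,
      " replicates, ", x$config$n_drugs, " drugs x ", x$config$n_targets,
      " targets)\n", sep = "")
  cat("  ", x$definitions, "\n", sep = "")
  cat("  grand mean improvement over thresholds < ", x$grand$max_threshold,
      ": ", round(x$grand$mean_improvement, 2), "% (95% interval ",
      round(x$grand$ci[1L], 2), " to ", round(x$grand$ci[2L], 2), ")\n",
      sep = "")
  invisible(x)
}

#' Optimality of the selection heuristics against exhaustive search
#'
#' For each subset size k, repeatedly samples k candidate targets, runs
#' exhaustive search (the global optimum over those candidates), SFFS and
#' greedy forward selection restricted to the same candidates under the
#' TIMMA objective, and reports the relative distance of each heuristic's
#' error to the optimum, \code{(err - opt) / opt} (absolute difference when
#' the optimum is 0).
#'
#' @param X A \code{binary_target_matrix}.
#' @param y Scaled efficacies (or scaled \code{drug_panel}).
#' @param ks Candidate-set sizes (each at most 12).
#' @param n_samples Random candidate draws per size.
#' @param seed Seed.
#' @param na_policy Passed to the selection routines.
#' @return A list with \code{samples} (one row per draw and algorithm) and
#'   \code{summary} (mean relative distance and empirical 95% interval per
#'   size and algorithm).
#' @export
optimality_experiment <- function(X, y, ks = 2:6, n_samples = 20L, seed = 1L,
                                  na_policy = "half") {
  if (inherits(y, "drug_panel")) y <- y$scaled_efficacy
  stopifnot(max(ks) <= 12L, ncol(X) >= max(ks))
  set.seed(seed)
  rows <- list()
  for (k in ks) {
    for (s in seq_len(n_samples)) {
      cand <- sample(colnames(X), k)
      Xc <- X[, cand, drop = FALSE]
      Xc <- .as_binary(Xc + 0L, Xc)
      opt <- exhaustive_select(Xc, y, na_policy = na_policy)$loo_error
      e_sffs <- sffs_select(Xc, y, na_policy = na_policy)$loo_error
      e_greedy <- greedy_select(Xc, y, method = "timma",
                                na_policy = na_policy)$loo_error
      rel <- function(e) if (opt > 0) (e - opt) / opt else e - opt
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, sample = s, optimum = opt,
        algorithm = c("sffs", "greedy"),
        error = c(e_sffs, e_greedy),
        rel_distance = c(rel(e_sffs), rel(e_greedy)))
    }
  }
  samples <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(samples, samples[c("k", "algorithm")]),
    function(d) data.frame(k = d$k[1L], algorithm = d$algorithm[1L],
                           mean_rel_distance = mean(d$rel_distance),
                           lo = unname(stats::quantile(d$rel_distance, 0.025)),
                           hi = unname(stats::quantile(d$rel_distance, 0.975)))))
  rownames(agg) <- NULL
  list(samples = samples, summary = agg[order(agg$k, agg$algorithm), ])
}
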