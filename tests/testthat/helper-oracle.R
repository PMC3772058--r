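# Independent reference implementations used as oracles.  These work on
# plain lists of target-name sets (no bitmasks) and literally re-scan all
# training drugs for every relation, so they share no code path with the
# package internals.

set_subset <- function(a, b) all(a %in% b)          # a contained in b
set_equal <- function(a, b) setequal(a, b)

# Literal transcription of the three TIMMA rules on set lists.
# profiles: list of character vectors; returns list(lower, upper, prediction)
naive_timma <- function(profiles, y, query) {
  eq <- vapply(profiles, set_equal, TRUE, b = query)
  if (any(eq)) {
    est <- mean(y[eq])
    return(list(lower = NA_real_, upper = NA_real_, prediction = est,
                identical = est))
  }
  is_sub <- vapply(profiles, set_subset, TRUE, b = query)
  is_sup <- vapply(profiles, function(p) set_subset(query, p), TRUE)
  lower <- upper <- NA_real_
  if (any(is_sub)) {
    idx <- which(is_sub)
    kmax <- idx[which.max(y[idx])]
    pool <- y[kmax]
    for (j in idx) {
      if (j != kmax && set_subset(profiles[[kmax]], profiles[[j]]) &&
          y[j] < y[kmax]) {
        pool <- c(pool, y[j])
      }
    }
    lower <- mean(pool)
  }
  if (any(is_sup)) {
    idx <- which(is_sup)
    kmin <- idx[which.min(y[idx])]
    pool <- y[kmin]
    for (j in idx) {
      if (j != kmin && set_subset(profiles[[j]], profiles[[kmin]]) &&
          y[j] > y[kmin]) {
        pool <- c(pool, y[j])
      }
    }
    upper <- mean(pool)
  }
  pred <- if (is.na(lower) && is.na(upper)) NA_real_ else
    mean(c(lower, upper), na.rm = TRUE)
  list(lower = lower, upper = upper, prediction = pred, identical = NA_real_)
}

# Independent transcription of the PKIM estimate (sets, not bitmasks).
naive_pkim <- function(profiles, y, query, clip = TRUE) {
  is_sub <- vapply(profiles, set_subset, TRUE, b = query)
  is_sup <- vapply(profiles, function(p) set_subset(query, p), TRUE)
  if (!any(is_sub) || !any(is_sup)) return(NA_real_)
  est <- mean(y[is_sub]) - mean(1 - y[is_sup])
  if (clip) est <- min(1, max(0, est))
  est
}

naive_loo <- function(profiles, y, predictor, na_policy = "half") {
  n <- length(y)
  errs <- vapply(seq_len(n), function(i) {
    p <- predictor(profiles[-i], y[-i], profiles[[i]])
    if (is.list(p)) p <- p$prediction
    if (is.na(p)) {
      switch(na_policy, half = abs(y[i] - 0.5), worst = 1, skip = NA_real_)
    } else abs(p - y[i])
  }, 0)
  mean(errs, na.rm = TRUE)
}

# AUC by exhaustive pair counting (ties count one half).
naive_auc <- function(pred, labels) {
  pos <- pred[labels == 1]
  neg <- pred[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Kendall tau (no ties expected in the toy inputs that use it).
naive_kendall <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
  }
  s / (n * (n - 1) / 2)
}

# Random small instance: binary matrix with named drugs/targets plus
# efficacies; profile list view for the oracles.
random_instance <- function(n_drugs, n_targets, p = 0.5) {
  x <- matrix(rbinom(n_drugs * n_targets, 1L, p), n_drugs, n_targets,
              dimnames = list(paste0("d", seq_len(n_drugs)),
                              LETTERS[seq_len(n_targets)]))
  list(X = affinity_matrix(x, "binary"),
       y = round(runif(n_drugs), 3),
       profiles = apply(x, 1L, function(r) colnames(x)[r == 1L],
                        simplify = FALSE))
}

mask_of <- function(targets, S) sum(2L^(match(targets, S) - 1L))

unmask <- function(mask, S) S[bitwAnd(mask, 2L^(seq_along(S) - 1L)) > 0L]

toy_binary <- function(rows, targets) {
  x <- do.call(rbind, rows)
  dimnames(x) <- list(paste0("d", seq_len(nrow(x))), targets)
  affinity_matrix(x + 0L, "binary")
}
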