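# Cancer-specific target-set selection by sequential forward floating search
# (SFFS), with exhaustive enumeration as a small-instance reference and
# random-restart confidence intervals.
#
# Candidate sets are evaluated by the mean leave-one-out error.  During
# Inclusion the bitmask states of a candidate set S + {t} are derived
# incrementally from the cached states of S (one added bit column) rather
# than rebuilt from the matrix; tests assert this equals from-scratch
# recomputation.

.SFFS_TOL <- 1e-12   # "decreases the error" means strictly, beyond this

#' Select targets by sequential forward floating search
#'
#' Minimizes the leave-one-out prediction error over target sets using the
#' four-step floating search: \emph{Initialization} at the best single
#' target; \emph{Inclusion} of the error-minimizing additional target,
#' exiting when no addition strictly decreases the error;
#' \emph{Conditional exclusion} of the least harmful target, kept only when
#' the reduced set beats the best error previously achieved at that
#' cardinality; and \emph{Continuation of conditional exclusion}, shrinking
#' further while strictly improving on the historical best of each size.
#' The floating (backward) steps let the search leave local optima that trap
#' a strictly forward search.
#'
#' @param X A \code{binary_target_matrix}.
#' @param y Scaled efficacies (or a scaled \code{drug_panel}).
#' @param start Optional starting target set (default: best single target).
#' @param max_k Maximal set size, at most 30 (bitmask width).
#' @param method Predictor used in the objective (\code{"timma"} default).
#' @param na_policy Passed to \code{\link{loo_error}}.
#' @param max_moves Safety cap on accepted moves; exceeding it is an error
#'   (it would indicate a cycling objective, which the strict-improvement
#'   comparisons are designed to exclude).
#' @return A \code{selection_result} list: \code{selected} (target set),
#'   \code{loo_error} (objective at the optimum over the whole run),
#'   \code{trace} (data frame of init/include/exclude moves with the error
#'   after each), and \code{best_by_cardinality}.
#' @export
sffs_select <- function(X, y, start = NULL, max_k = NULL, method = "timma",
                        na_policy = "half", max_moves = 10000L) {
  if (inherits(y, "drug_panel")) y <- y$scaled_efficacy
  stopifnot(length(y) == nrow(X))
  targets <- colnames(X)
  if (is.null(max_k)) max_k <- min(length(targets), .MAX_BITS)
  max_k <- min(max_k, .MAX_BITS)
  pred <- if (method == "timma") .timma_predictor else .pkim_predictor
  Xm <- unclass(X)
  obj_masks <- function(masks) .loo_masks(masks, y, pred, na_policy)
  masks_of <- function(S) .state_masks(X, S)

  # --- Initialization ------------------------------------------------------
  single <- vapply(targets, function(t) obj_masks(as.integer(Xm[, t])), 0)
  if (is.null(start)) {
    S <- targets[which.min(single)]
    err <- min(single)
  } else {
    S <- as.character(start)
    stopifnot(all(S %in% targets))
    err <- obj_masks(masks_of(S))
  }
  best_k <- rep(Inf, max_k)
  best_k[1L] <- min(single)
  k <- length(S)
  if (k <= max_k) best_k[k] <- min(best_k[k], err)
  best_S <- S
  best_err <- err
  trace <- data.frame(action = "init", target = paste(S, collapse = "/"),
                      error = err, k = k, stringsAsFactors = FALSE)
  masks <- masks_of(S)
  moves <- 0L
  note <- function(action, t, e, k) {
    trace <<- rbind(trace, data.frame(action = action, target = t, error = e,
                                      k = k, stringsAsFactors = FALSE))
  }

  repeat {
    # --- Inclusion ---------------------------------------------------------
    rest <- setdiff(targets, S)
    if (!length(rest) || length(S) >= max_k) break
    bit <- 2L^length(S)
    cand_err <- vapply(rest, function(t)
      obj_masks(masks + bit * as.integer(Xm[, t])), 0)
    if (min(cand_err) >= err - .SFFS_TOL) break   # no strict decrease: exit
    t_new <- rest[which.min(cand_err)]            # ties: lowest column index
    S <- c(S, t_new)
    masks <- masks + bit * as.integer(Xm[, t_new])
    err <- min(cand_err)
    k <- length(S)
    best_k[k] <- min(best_k[k], err)
    note("include", t_new, err, k)
    if (err < best_err) { best_err <- err; best_S <- S }
    moves <- moves + 1L
    if (moves > max_moves) stop("sffs_select exceeded max_moves = ", max_moves)

    # --- Conditional exclusion (and its continuation) ----------------------
    first_pass <- TRUE
    while (length(S) > 2L) {
      excl_err <- vapply(seq_along(S), function(j)
        obj_masks(masks_of(S[-j])), 0)
      j <- which.min(excl_err)
      if (first_pass && S[j] == t_new) break   # just-added target: keep it
      if (excl_err[j] >= best_k[length(S) - 1L] - .SFFS_TOL) break
      t_out <- S[j]
      S <- S[-j]
      masks <- masks_of(S)
      err <- excl_err[j]
      k <- length(S)
      best_k[k] <- err
      note("exclude", t_out, err, k)
      if (err < best_err) { best_err <- err; best_S <- S }
      first_pass <- FALSE
      moves <- moves + 1L
      if (moves > max_moves) stop("sffs_select exceeded max_moves = ",
                                  max_moves)
    }
  }

  structure(list(selected = best_S, loo_error = best_err, trace = trace,
                 best_by_cardinality = best_k[is.finite(best_k)],
                 method = method, algorithm = "sffs"),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(toupper(x$algorithm), " selection (", x$method, " objective):\n",
      "  selected (", length(x$selected), "): ",
      paste(x$selected, collapse = ", "), "\n",
      "  LOO error: ", format(x$loo_error), "\n", sep = "")
  invisible(x)
}

#' Exhaustive target-set selection
#'
#' Enumerates every non-empty subset of the candidate targets up to
#' \code{max_k} and returns the global optimum of the leave-one-out error.
#' Guarded to at most 20 candidates; use \code{\link{sffs_select}} beyond
#' that.
#'
#' @inheritParams sffs_select
#' @param candidates Candidate targets (default: all columns of \code{X}).
#' @return A \code{selection_result} whose \code{loo_error} is the global
#'   optimum over the enumerated subsets.
#' @export
exhaustive_select <- function(X, y, candidates = colnames(X),
                              max_k = length(candidates), method = "timma",
                              na_policy = "half") {
  if (inherits(y, "drug_panel")) y <- y$scaled_efficacy
  m <- length(candidates)
  if (m > 20L) {
    stop("exhaustive enumeration is limited to 20 candidates (got ", m,
         "); use sffs_select()")
  }
  pred <- if (method == "timma") .timma_predictor else .pkim_predictor
  base_masks <- .state_masks(X, candidates)
  best_err <- Inf
  best_S <- NULL
  best_sz <- rep(Inf, min(m, max_k))
  for (s in seq_len(2L^m - 1L)) {
    sz <- sum(bitwAnd(s, 2L^(0:(m - 1L))) > 0L)
    if (sz > max_k) next
    e <- .loo_masks(bitwAnd(base_masks, s), y, pred, na_policy)
    if (e < best_sz[sz]) best_sz[sz] <- e
    if (e < best_err) {
      best_err <- e
      best_S <- candidates[bitwAnd(s, 2L^(0:(m - 1L))) > 0L]
    }
  }
  structure(list(selected = best_S, loo_error = best_err,
                 trace = data.frame(action = "exhaustive",
                                    target = paste(best_S, collapse = "/"),
                                    error = best_err, k = length(best_S),
                                    stringsAsFactors = FALSE),
                 best_by_cardinality = best_sz, method = method,
                 algorithm = "exhaustive"),
            class = "selection_result")
}

#' Random-restart distribution of SFFS selections
#'
#' Reruns the floating search from randomly chosen single-target starting
#' points and summarizes the spread of the attained objective, giving an
#' empirical confidence interval for the selection error.
#'
#' @inheritParams sffs_select
#' @param n_starts Number of random restarts (default 50).
#' @param seed Integer seed making the restarts reproducible.
#' @return A list with \code{results} (one \code{selection_result} per
#'   start), \code{errors}, \code{mean} and the empirical 95% interval
#'   \code{ci}.
#' @export
selection_ci <- function(X, y, n_starts = 50L, seed = 1L, max_k = NULL,
                         method = "timma", na_policy = "half") {
  set.seed(seed)
  starts <- sample(colnames(X), n_starts, replace = TRUE)
  results <- lapply(starts, function(s)
    sffs_select(X, y, start = s, max_k = max_k, method = method,
                na_policy = na_policy))
  errors <- vapply(results, `[[`, 0, "loo_error")
  list(results = results, errors = errors, mean = mean(errors),
       ci = unname(stats::quantile(errors, c(0.025, 0.975))))
}
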