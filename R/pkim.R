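# Baseline probabilistic kinase-inhibition-map (PKIM) predictor of
# Pal & Berlow (2010) and its greedy forward model selection.  The original
# closed form of the prediction rule is not reproduced here; the rule is
# re-implemented from its published verbal description -- the efficacy
# accumulated from the subset profiles of the query, penalized by the loss of
# efficacy in its superset profiles -- and validated for internal consistency
# against an independently coded transcription in the test suite.

# Subset/superset families are non-strict: a training profile equal to the
# query belongs to both.  Estimate = mean(y over subsets) - mean(1 - y over
# supersets), clipped to [0, 1] (an efficacy must live on the efficacy
# scale); NA when either family is empty (non-determinable).
.pkim_predictor <- function(masks, y, q, clip = TRUE) {
  sub <- bitwAnd(masks, q) == masks
  if (!any(sub)) return(NA_real_)
  sup <- bitwAnd(masks, q) == q
  if (!any(sup)) return(NA_real_)
  est <- mean(y[sub]) - mean(1 - y[sup])
  if (clip) est <- min(1, max(0, est))
  est
}

#' PKIM efficacy prediction
#'
#' The baseline predictor: the mean efficacy of the training drugs whose
#' target profiles are subsets of the query state, penalized by the mean
#' efficacy loss (1 - y) of the drugs whose profiles are supersets.  Both
#' families must be non-empty; otherwise the state is non-determinable and
#' \code{NA} is returned.  Unlike TIMMA there is no identical-set rule and no
#' one-sided fallback, which is exactly what the subset/superset averaging of
#' TIMMA was designed to fix.
#'
#' @param model A \code{timma_model} (the same container serves both
#'   predictors).
#' @param query Target set (character) or integer bitmask over the model's S.
#' @param exclude Optional training drug to leave out (index or id).
#' @param clip Clip the estimate into [0, 1] (default TRUE).
#' @return Predicted efficacy, or \code{NA} when non-determinable.
#' @export
pkim_predict <- function(model, query, exclude = NULL, clip = TRUE) {
  stopifnot(inherits(model, "timma_model"))
  q <- if (is.numeric(query)) as.integer(query) else
    .set_to_mask(as.character(query), model$S)
  masks <- model$masks
  y <- model$y
  if (!is.null(exclude)) {
    if (is.character(exclude)) exclude <- match(exclude, model$drugs)
    masks <- masks[-exclude]
    y <- y[-exclude]
  }
  .pkim_predictor(masks, y, q, clip = clip)
}

#' Greedy forward target selection
#'
#' The strictly forward selection used by the PKIM baseline: start from the
#' single target with the lowest leave-one-out error, repeatedly add the
#' target whose inclusion lowers the error most, and stop as soon as no
#' addition improves.  Unlike the floating search it can never drop a target
#' once added, so it is prone to local optima.
#'
#' @param X A \code{binary_target_matrix}.
#' @param y Scaled efficacies (or scaled \code{drug_panel}).
#' @param max_k Maximal set size (default \code{min(ncol(X), 30)}).
#' @param method Predictor scoring candidate sets, \code{"pkim"} (default,
#'   the historical pairing) or \code{"timma"}.
#' @param na_policy Passed to \code{\link{loo_error}}.
#' @return A \code{selection_result}; see \code{\link{sffs_select}}.
#' @export
greedy_select <- function(X, y, max_k = NULL, method = "pkim",
                          na_policy = "half") {
  if (inherits(y, "drug_panel")) y <- y$scaled_efficacy
  targets <- colnames(X)
  if (is.null(max_k)) max_k <- min(length(targets), .MAX_BITS)
  obj <- function(S) loo_error(X, y, S, method = method,
                               na_policy = na_policy)
  single <- vapply(targets, function(t) obj(t), 0)
  S <- targets[which.min(single)]       # ties: lowest column index
  err <- min(single)
  trace <- data.frame(action = "init", target = S, error = err, k = 1L,
                      stringsAsFactors = FALSE)
  repeat {
    if (length(S) >= max_k) break
    rest <- setdiff(targets, S)
    if (!length(rest)) break
    errs <- vapply(rest, function(t) obj(c(S, t)), 0)
    if (min(errs) >= err - 1e-12) break
    t_new <- rest[which.min(errs)]
    S <- c(S, t_new)
    err <- min(errs)
    trace <- rbind(trace, data.frame(action = "include", target = t_new,
                                     error = err, k = length(S),
                                     stringsAsFactors = FALSE))
  }
  best_k <- tapply(trace$error, trace$k, min)
  structure(list(selected = S, loo_error = err, trace = trace,
                 best_by_cardinality = best_k, method = method,
                 algorithm = "greedy"),
            class = "selection_result")
}
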