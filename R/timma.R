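# Core set-theoretic prediction engine.  Target-inhibition states are held
# as integer bitmasks over the selected target set S (bit b set = target b of
# S inhibited), so subset/superset tests are single bitwAnd comparisons.

.MAX_BITS <- 30L   # R's bitwAnd operates on 32-bit signed integers

.state_masks <- function(X, S) {
  miss <- setdiff(S, colnames(X))
  if (length(miss)) stop("unknown target(s): ", paste(miss, collapse = ", "))
  if (length(S) > .MAX_BITS) {
    stop("target sets are limited to ", .MAX_BITS, " targets (got ",
         length(S), ")")
  }
  bits <- 2L^(seq_along(S) - 1L)
  as.integer(unclass(X)[, S, drop = FALSE] %*% bits)
}

.set_to_mask <- function(targets, S) {
  miss <- setdiff(targets, S)
  if (length(miss)) {
    stop("query contains target(s) outside the model set: ",
         paste(miss, collapse = ", "))
  }
  sum(2L^(match(unique(targets), S) - 1L))
}

.mask_to_set <- function(mask, S) S[bitwAnd(mask, 2L^(seq_along(S) - 1L)) > 0L]

#' Build a TIMMA model
#'
#' Restricts the binary drug-target matrix to a selected target set S,
#' pairs it with the scaled efficacies, and caches the pairwise
#' subset/superset/equality relations between the training drugs under S.
#' Drugs whose restricted profiles are empty are retained: they inhibit
#' nothing in S and act as "no inhibition" evidence.
#'
#' @param X A \code{binary_target_matrix}.
#' @param y Scaled efficacies in [0, 1], one per drug, in the row order of
#'   \code{X} (or a scaled \code{drug_panel} whose \code{drug_id}s match).
#' @param S Character vector of selected targets (default: all columns).
#' @return A \code{timma_model} with elements \code{S}, \code{masks},
#'   \code{y}, \code{drugs} and the relation cache \code{relations}
#'   (\code{equal}, \code{subset}, \code{superset} logical matrices;
#'   \code{subset[i, j]} is TRUE when drug i's profile is contained in
#'   drug j's).
#' @export
timma_model <- function(X, y, S = colnames(X)) {
  stopifnot(inherits(X, "binary_target_matrix"), length(S) >= 1L)
  if (inherits(y, "drug_panel")) {
    if (!identical(y$drug_id, rownames(X))) {
      stop("drug order of the panel and matrix differ")
    }
    y <- y$scaled_efficacy
  }
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(y)) stop("efficacies contain NA; scale the panel first")
  masks <- .state_masks(X, S)
  sub <- outer(masks, masks, function(a, b) bitwAnd(a, b) == a)
  eq <- outer(masks, masks, "==")
  structure(list(S = S, masks = masks, y = as.numeric(y),
                 drugs = rownames(X),
                 relations = list(equal = eq, subset = sub,
                                  superset = t(sub))),
            class = "timma_model")
}

#' @export
print.timma_model <- function(x, ...) {
  cat("TIMMA model:", length(x$y), "drugs,", length(x$S), "targets (",
      paste(utils::head(x$S, 6L), collapse = ", "),
      if (length(x$S) > 6L) "..." else "", ")\n")
  invisible(x)
}

# Fast path shared by prediction, LOO and enumeration.  Returns
# c(identical, lower, upper, prediction), NA where unavailable; prediction
# NA = non-identifiable.  Equality has precedence; the subset/superset rules
# then see strict relations only.
.timma_rules <- function(masks, y, q) {
  eq <- masks == q
  if (any(eq)) {
    est <- mean(y[eq])
    return(c(est, NA_real_, NA_real_, est))
  }
  lo <- NA_real_
  up <- NA_real_
  sub <- bitwAnd(masks, q) == masks
  if (any(sub)) {
    ys <- y[sub]
    ms <- masks[sub]
    k <- which.max(ys)            # ties: lowest index
    tk <- ms[k]
    yk <- ys[k]
    qual <- bitwAnd(ms, tk) == tk & ys < yk
    lo <- mean(c(yk, ys[qual]))
  }
  sup <- bitwAnd(masks, q) == q
  if (any(sup)) {
    ys <- y[sup]
    ms <- masks[sup]
    k <- which.min(ys)
    tk <- ms[k]
    yk <- ys[k]
    qual <- bitwAnd(ms, tk) == ms & ys > yk
    up <- mean(c(yk, ys[qual]))
  }
  pred <- if (is.na(lo) && is.na(up)) NA_real_ else mean(c(lo, up), na.rm = TRUE)
  c(NA_real_, lo, up, pred)
}

#' Predict the efficacy of a target-inhibition state
#'
#' Applies the three TIMMA rules in order of precedence.  (1) Identical-set:
#' if any training profile equals the query state, the prediction is the mean
#' efficacy of those drugs.  (2) Maximization (lower bound): among training
#' profiles strictly contained in the query, take the drug with highest
#' efficacy; average its efficacy with those of other contained profiles that
#' are supersets of its profile with lower efficacy.  (3) Minimization (upper
#' bound): symmetrically over profiles strictly containing the query, via the
#' minimum-efficacy drug and containing profiles contained in its profile
#' with higher efficacy.  The prediction is the mean of the available bounds;
#' with a single bound the prediction equals that bound; with neither the
#' state is non-identifiable.
#'
#' @param model A \code{timma_model}.
#' @param query Character vector of targets (subset of the model's S), or a
#'   single integer bitmask over S.
#' @param exclude Optional index (or drug id) of one training drug to leave
#'   out, as used in leave-one-out validation.
#' @return A \code{prediction_detail} list: \code{query},
#'   \code{identical_estimate}, \code{lower_bound}, \code{upper_bound},
#'   \code{prediction} (NA when non-identifiable) and \code{identifiable}.
#' @export
predict_efficacy <- function(model, query, exclude = NULL) {
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
  r <- .timma_rules(masks, y, q)
  structure(list(query = .mask_to_set(q, model$S),
                 identical_estimate = r[1L], lower_bound = r[2L],
                 upper_bound = r[3L], prediction = r[4L],
                 identifiable = !is.na(r[4L])),
            class = "prediction_detail")
}

#' @export
print.prediction_detail <- function(x, ...) {
  cat("query: {", paste(x$query, collapse = ", "), "}\n")
  cat("prediction:",
      if (x$identifiable) format(x$prediction) else "NON_IDENTIFIABLE", "\n")
  if (!is.na(x$identical_estimate))
    cat("  identical-set estimate:", format(x$identical_estimate), "\n")
  if (!is.na(x$lower_bound))
    cat("  lower bound (maximization rule):", format(x$lower_bound), "\n")
  if (!is.na(x$upper_bound))
    cat("  upper bound (minimization rule):", format(x$upper_bound), "\n")
  invisible(x)
}

# Mask-level LOO mean absolute error; predictor(masks, y, q) -> scalar or NA.
.loo_masks <- function(masks, y, predictor,
                       na_policy = c("half", "skip", "worst")) {
  na_policy <- match.arg(na_policy)
  n <- length(y)
  err <- numeric(n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    p <- predictor(masks[-i], y[-i], masks[i])
    if (is.na(p)) {
      err[i] <- switch(na_policy, half = abs(y[i] - 0.5), worst = 1,
                       skip = {keep[i] <- FALSE; 0})
    } else {
      err[i] <- abs(p - y[i])
    }
  }
  if (!any(keep)) return(NA_real_)
  mean(err[keep])
}

.timma_predictor <- function(masks, y, q) .timma_rules(masks, y, q)[4L]

#' Leave-one-out prediction error
#'
#' For each drug, predicts its efficacy from a model trained on the remaining
#' drugs (restricted to S) and returns the mean absolute prediction error --
#' the model-selection objective.
#'
#' @param X A \code{binary_target_matrix}.
#' @param y Scaled efficacies (or scaled \code{drug_panel}).
#' @param S Target set to restrict to (default: all columns).
#' @param method \code{"timma"} (default) or \code{"pkim"}.
#' @param na_policy How a non-identifiable (TIMMA) or non-determinable
#'   (PKIM) leave-one-out prediction contributes to the error:
#'   \code{"half"} (default) charges \code{|y - 0.5|}, the error of a
#'   maximally uninformative guess; \code{"skip"} drops the drug;
#'   \code{"worst"} charges 1.
#' @return Mean absolute LOO error.
#' @export
loo_error <- function(X, y, S = colnames(X), method = c("timma", "pkim"),
                      na_policy = "half") {
  method <- match.arg(method)
  if (inherits(y, "drug_panel")) y <- y$scaled_efficacy
  stopifnot(length(y) == nrow(X), length(y) >= 2L)
  masks <- .state_masks(X, S)
  pred <- if (method == "timma") .timma_predictor else .pkim_predictor
  .loo_masks(masks, y, pred, na_policy)
}
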