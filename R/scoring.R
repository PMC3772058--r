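# Synergy and synthetic-lethality scoring on the predicted efficacy matrix.

#' Enumerate the predicted efficacy matrix
#'
#' Runs the TIMMA prediction rules over every target-inhibition state of the
#' selected set (full mode) or over the states inhibiting at most two
#' targets (pairwise mode), with no training drug excluded.  The empty state
#' ("no inhibition") is predicted by the same rules; when non-identifiable
#' it defaults to a baseline efficacy of 0.
#'
#' @param model A \code{timma_model}.
#' @param mode \code{"full"} (all \code{2^|S|} states; |S| limited to 20) or
#'   \code{"pairwise"}.
#' @return An \code{efficacy_matrix}: a data frame with one row per state
#'   (\code{state} bitmask, \code{targets} label, \code{n_targets},
#'   \code{efficacy}, \code{identifiable}), carrying the target order and
#'   the training efficacy range as attributes.
#' @export
enumerate_efficacy_matrix <- function(model, mode = c("full", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "timma_model"))
  m <- length(model$S)
  if (mode == "full" && m > 20L) {
    stop("full enumeration is limited to 20 targets (got ", m,
         "); use mode = \"pairwise\"")
  }
  states <- if (mode == "full") 0:(2L^m - 1L) else {
    singles <- 2L^(seq_len(m) - 1L)
    pairs <- if (m >= 2L) {
      ij <- utils::combn(m, 2L)
      2L^(ij[1L, ] - 1L) + 2L^(ij[2L, ] - 1L)
    } else integer(0)
    c(0L, singles, pairs)
  }
  eff <- vapply(states, function(s)
    .timma_rules(model$masks, model$y, s)[4L], 0)
  identifiable <- !is.na(eff)
  eff[!identifiable & states == 0L] <- 0   # no-inhibition baseline
  out <- data.frame(
    state = states,
    targets = vapply(states, function(s)
      paste(.mask_to_set(s, model$S), collapse = " + "), ""),
    n_targets = vapply(states, function(s)
      sum(bitwAnd(s, 2L^(seq_len(m) - 1L)) > 0L), 0L),
    efficacy = eff,
    identifiable = identifiable,
    stringsAsFactors = FALSE)
  structure(out, target_order = model$S, y_range = range(model$y),
            class = c("efficacy_matrix", "data.frame"))
}

.matrix_lookup <- function(M, targets) {
  S <- attr(M, "target_order")
  s <- .set_to_mask(targets, S)
  i <- match(s, M$state)
  if (is.na(i)) stop("state {", paste(targets, collapse = ", "),
                     "} not enumerated; rebuild the matrix in full mode")
  if (!M$identifiable[i]) return(NA_real_)
  M$efficacy[i]
}

.synergy_null <- function(ya, yb, null) {
  switch(null, bliss = ya + yb - ya * yb, product = ya * yb)
}

#' Synergy score of a target pair
#'
#' Deviation of the predicted pair efficacy from the expectation under
#' independent single-target action.  The default null is Bliss
#' independence on the [0, 1] efficacy scale, \code{yA + yB - yA*yB}
#' (equivalently, multiplicative on cell survival); \code{null = "product"}
#' gives the pure product expectation \code{yA*yB}.  Positive scores
#' indicate synergy, negative antagonism.
#'
#' @param M An \code{efficacy_matrix}.
#' @param A,B Target names in the matrix's target order.
#' @param null \code{"bliss"} (default) or \code{"product"}.
#' @return The synergy score, or \code{NA} when any of the three required
#'   efficacies is non-identifiable.
#' @export
synergy_target_pair <- function(M, A, B, null = c("bliss", "product")) {
  null <- match.arg(null)
  if (identical(A, B)) stop("A and B must be distinct targets")
  yab <- .matrix_lookup(M, c(A, B))
  ya <- .matrix_lookup(M, A)
  yb <- .matrix_lookup(M, B)
  if (anyNA(c(yab, ya, yb))) return(NA_real_)
  yab - .synergy_null(ya, yb, null)
}

#' Synergy score of a drug pair
#'
#' A drug pair inhibits the union of the two drugs' target sets; its synergy
#' is the mean of the synergy scores over all cross pairs of targets drawn
#' one from each drug (within the selected set).  Pairs sharing the same
#' node (a = b) are skipped -- a node cannot be combined with itself -- and
#' non-identifiable pairs are skipped, averaging over the valid ones.
#'
#' @param M An \code{efficacy_matrix}.
#' @param T1,T2 The two drugs' target sets intersected with the selected
#'   set; character vectors, non-empty.
#' @param null Passed to \code{\link{synergy_target_pair}}.
#' @return Mean synergy over valid cross pairs, or \code{NA} when none.
#' @export
synergy_drug_pair <- function(M, T1, T2, null = "bliss") {
  stopifnot(length(T1) >= 1L, length(T2) >= 1L)
  scores <- c()
  for (a in T1) for (b in T2) {
    if (a == b) next
    scores <- c(scores, synergy_target_pair(M, a, b, null))
  }
  if (!length(scores) || all(is.na(scores))) return(NA_real_)
  mean(scores, na.rm = TRUE)
}

#' All pairwise target synergies
#'
#' @param M An \code{efficacy_matrix}.
#' @param null Passed to \code{\link{synergy_target_pair}}.
#' @return A symmetric-in-(A,B) \code{SynergyTable} data frame with the pair
#'   efficacy, the single-target efficacies and the synergy score.
#' @export
synergy_table <- function(M, null = "bliss") {
  S <- attr(M, "target_order")
  if (length(S) < 2L) stop("need at least two targets")
  ij <- utils::combn(length(S), 2L)
  rows <- lapply(seq_len(ncol(ij)), function(k) {
    A <- S[ij[1L, k]]; B <- S[ij[2L, k]]
    data.frame(entity_a = A, entity_b = B,
               efficacy_ab = .matrix_lookup(M, c(A, B)),
               single_a = .matrix_lookup(M, A),
               single_b = .matrix_lookup(M, B),
               synergy = synergy_target_pair(M, A, B, null),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "null") <- null
  out
}

#' All pairwise drug synergies
#'
#' @param M An \code{efficacy_matrix} built on a selected target set S.
#' @param X The \code{binary_target_matrix} the model was trained on (used
#'   to intersect each drug's profile with S).
#' @param null Passed to \code{\link{synergy_target_pair}}.
#' @return A \code{SynergyTable} data frame over drug pairs; drugs with an
#'   empty profile within S are omitted.
#' @export
drug_synergy_table <- function(M, X, null = "bliss") {
  S <- attr(M, "target_order")
  profs <- lapply(rownames(X), function(d) S[unclass(X)[d, S] == 1L])
  names(profs) <- rownames(X)
  profs <- profs[vapply(profs, length, 0L) > 0L]
  drugs <- names(profs)
  if (length(drugs) < 2L) stop("need at least two drugs hitting the set")
  ij <- utils::combn(length(drugs), 2L)
  rows <- lapply(seq_len(ncol(ij)), function(k) {
    d1 <- drugs[ij[1L, k]]; d2 <- drugs[ij[2L, k]]
    T12 <- union(profs[[d1]], profs[[d2]])
    eff <- tryCatch(.matrix_lookup(M, T12), error = function(e) NA_real_)
    data.frame(entity_a = d1, entity_b = d2,
               efficacy_ab = eff,
               synergy = synergy_drug_pair(M, profs[[d1]], profs[[d2]], null),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "null") <- null
  out[order(-out$synergy, out$entity_a, out$entity_b,
            na.last = TRUE), , drop = FALSE]
}

# Pooled within-group sum of squares for a list of index groups (empty
# groups are the caller's responsibility).
.pooled_tss <- function(y, groups) {
  sum(vapply(groups, function(g) sum((y[g] - mean(y[g]))^2), 0))
}

#' Synthetic lethality score of a target pair
#'
#' Drugs are grouped by their joint (A, B) inhibition state and three
#' two-node network structures are fit by pooled group means: the
#' \emph{parallel} model (only joint inhibition blocks survival: state 11
#' vs the rest), the \emph{series} model (either inhibition suffices:
#' states 01/10/11 vs 00) and the \emph{singleton} model (the better of the
#' two single-target splits).  Each fit is scored by its total within-group
#' sum of squares (TSS) of the efficacies, and the synthetic lethality
#' score is \code{min(TSS_series, TSS_singleton) / TSS_parallel}: the
#' higher, the stronger the evidence that A and B act as redundant parallel
#' pathways -- individually dispensable, jointly lethal.  A perfect AND
#' pattern has \code{TSS_parallel = 0} and scores \code{Inf}; a perfect OR
#' pattern scores 0.
#'
#' @param X A \code{binary_target_matrix}.
#' @param y Scaled efficacies (or scaled \code{drug_panel}).
#' @param A,B Target names (\code{A == B} is allowed and is the natural
#'   baseline; all three models then coincide and the score is 1).
#' @return A \code{sl_score} list: \code{tss_parallel}, \code{tss_series},
#'   \code{tss_singleton}, \code{score} and a \code{reason} when undefined.
#' @export
synthetic_lethality_score <- function(X, y, A, B) {
  if (inherits(y, "drug_panel")) y <- y$scaled_efficacy
  a <- unclass(X)[, A]
  b <- unclass(X)[, B]
  state <- a + 2L * b   # 0 = neither, 1 = A only, 2 = B only, 3 = both
  grp <- function(states) which(state %in% states)
  models <- list(
    parallel = list(grp(3L), grp(0:2)),
    series = list(grp(1:3), grp(0L)),
    singleton_a = list(which(a == 1L), which(a == 0L)),
    singleton_b = list(which(b == 1L), which(b == 0L)))
  tss <- vapply(models, function(m)
    if (all(lengths(m) > 0L)) .pooled_tss(y, m) else NA_real_, 0)
  singleton <- suppressWarnings(min(tss[c("singleton_a", "singleton_b")],
                                    na.rm = TRUE))
  if (!is.finite(singleton)) singleton <- NA_real_
  out <- list(pair = c(A, B), tss_parallel = unname(tss["parallel"]),
              tss_series = unname(tss["series"]),
              tss_singleton = singleton, score = NA_real_, reason = NA_character_)
  if (anyNA(c(out$tss_parallel, out$tss_series, out$tss_singleton))) {
    out$reason <- "empty inhibition-state group"
    class(out) <- "sl_score"
    return(out)
  }
  num <- min(out$tss_series, out$tss_singleton)
  out$score <- if (out$tss_parallel == 0) {
    if (num == 0) 1 else Inf    # all models perfect: no preference
  } else num / out$tss_parallel
  class(out) <- "sl_score"
  out
}

#' @export
print.sl_score <- function(x, ...) {
  cat("synthetic lethality {", paste(x$pair, collapse = ", "), "}: score ",
      format(x$score), "\n  TSS parallel/series/singleton: ",
      format(x$tss_parallel), " / ", format(x$tss_series), " / ",
      format(x$tss_singleton), "\n", sep = "")
  if (!is.na(x$reason)) cat("  undefined:", x$reason, "\n")
  invisible(x)
}

#' Rank synthetic-lethal partners of an anchor target
#'
#' Scores every (anchor, t) pair, takes the (anchor, anchor) pair as the
#' baseline, and returns the targets scoring strictly above it, ranked in
#' decreasing score with ties sharing a rank (targets inhibited by the same
#' drug set score identically).
#'
#' @inheritParams synthetic_lethality_score
#' @param anchor The anchor target name.
#' @return A list with \code{baseline} (the anchor-anchor score) and
#'   \code{partners}, a data frame (target, score, rank) of above-baseline
#'   targets.
#' @export
rank_synthetic_lethal_partners <- function(X, y, anchor) {
  stopifnot(anchor %in% colnames(X))
  others <- setdiff(colnames(X), anchor)
  baseline <- synthetic_lethality_score(X, y, anchor, anchor)$score
  scores <- vapply(others, function(t)
    synthetic_lethality_score(X, y, anchor, t)$score, 0)
  keep <- !is.na(scores) & scores > baseline
  partners <- data.frame(target = others[keep], score = scores[keep],
                         stringsAsFactors = FALSE)
  partners <- partners[order(-partners$score, partners$target), , drop = FALSE]
  partners$rank <- rank(-partners$score, ties.method = "min")
  rownames(partners) <- NULL
  list(anchor = anchor, baseline = baseline, partners = partners)
}

#' ROC analysis for classifying sensitive drugs
#'
#' Pools model predictions (typically across binarization thresholds) and
#' evaluates how well they separate sensitive from insensitive drugs.  The
#' area under the curve uses the rank (Mann-Whitney) statistic with midrank
#' tie handling, so identical predictions for all drugs give 0.5.
#'
#' @param predictions Numeric vector of pooled predicted efficacies.
#' @param labels Binary sensitivity labels (1/TRUE = sensitive), same
#'   length.
#' @return A list with \code{auc} and \code{points}, a data frame of
#'   (fpr, tpr) pairs tracing the curve.
#' @export
roc_sensitive_drugs <- function(predictions, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(predictions) == length(labels), !anyNA(predictions))
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; ROC undefined")
  }
  r <- pROC::roc(response = labels, predictor = predictions,
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  list(auc = as.numeric(r$auc), points = pts)
}
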