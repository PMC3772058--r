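# Processing of single and pairwise siRNA viability screens and comparison
# of measured knockdown synergies with model-predicted ones.  Inhibition
# values are percentages (0-100); all fraction conversions funnel through
# .pct_to_frac/.frac_to_pct so the two scales are never mixed.

.pct_to_frac <- function(x) x / 100
.frac_to_pct <- function(x) x * 100

.pair_key <- function(a, b) {
  ifelse(is.na(b), a, paste(pmin(a, b), pmax(a, b), sep = "\r"))
}

#' Replicate quality control and averaging
#'
#' Averages replicate inhibition percentages per knockdown.  When exactly
#' two replicates disagree by more than \code{max_discordance} percentage
#' points and exactly one of them sits on a plate edge, the edge replicate
#' is dropped (edge wells are prone to evaporation artifacts).  Discordant
#' pairs with no, or two, edge replicates are kept whole with a warning:
#' data are never silently discarded.
#'
#' @param records Data frame with columns \code{gene_a}, \code{gene_b}
#'   (\code{NA} for single knockdowns), \code{inhibition} (percent) and
#'   \code{edge} (logical plate-edge flag); one row per replicate well.
#' @param max_discordance Absolute discordance threshold in percentage
#'   points (default 15).
#' @return Data frame with one row per knockdown: \code{gene_a},
#'   \code{gene_b}, averaged \code{inhibition}, \code{n_replicates},
#'   \code{n_used} and a \code{flag} (\code{"ok"}, \code{"edge_dropped"} or
#'   \code{"discordant_kept"}).
#' @export
qc_and_average <- function(records, max_discordance = 15) {
  stopifnot(all(c("gene_a", "inhibition") %in% names(records)))
  if (is.null(records$gene_b)) records$gene_b <- NA_character_
  if (is.null(records$edge)) records$edge <- FALSE
  stopifnot(all(is.finite(records$inhibition)))
  key <- .pair_key(records$gene_a, records$gene_b)
  out <- lapply(split(records, factor(key, levels = unique(key))), function(d) {
    v <- d$inhibition
    flag <- "ok"
    used <- seq_along(v)
    if (length(v) == 2L && abs(v[1L] - v[2L]) > max_discordance) {
      if (sum(d$edge) == 1L) {
        used <- which(!d$edge)
        flag <- "edge_dropped"
      } else {
        flag <- "discordant_kept"
        warning("discordant replicates for ", d$gene_a[1L],
                if (!is.na(d$gene_b[1L])) paste0("+", d$gene_b[1L]),
                " with ", sum(d$edge), " edge flag(s); keeping both",
                call. = FALSE)
      }
    }
    data.frame(gene_a = d$gene_a[1L], gene_b = d$gene_b[1L],
               inhibition = mean(v[used]), n_replicates = length(v),
               n_used = length(used), flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag plate-edge wells
#'
#' @param row,col Well coordinates (1-based).
#' @param n_rows,n_cols Plate dimensions (default 16 x 24, a 384-well
#'   plate).
#' @return Logical: TRUE for wells in the first/last row or column.
#' @export
edge_well <- function(row, col, n_rows = 16L, n_cols = 24L) {
  row == 1L | row == n_rows | col == 1L | col == n_cols
}

#' Normalize single-knockdown inhibition values
#'
#' A single knockdown of gene g is expected to inhibit at most as much as
#' any double knockdown involving g.  Each single value s is therefore
#' replaced by the mean of s and all double-knockdown values involving g
#' that lie below s, pulling inflated singles down; a single value is never
#' increased.
#'
#' @param singles Data frame with columns \code{gene}, \code{inhibition}.
#' @param doubles Data frame with columns \code{gene_a}, \code{gene_b},
#'   \code{inhibition} (averaged, e.g. from \code{\link{qc_and_average}}).
#' @return \code{singles} with a \code{normalized} column added.
#' @export
normalize_single_knockdown <- function(singles, doubles) {
  singles$normalized <- vapply(seq_len(nrow(singles)), function(i) {
    g <- singles$gene[i]
    s <- singles$inhibition[i]
    dv <- doubles$inhibition[doubles$gene_a == g | doubles$gene_b == g]
    mean(c(s, dv[dv < s]))
  }, 0)
  singles
}

#' Synergy scores from siRNA knockdown measurements
#'
#' Applies the same independence null as the model-side synergy scoring
#' (\code{\link{synergy_target_pair}}) to measured inhibition percentages:
#' values are converted to fractions, the null expectation of the two
#' normalized singles is subtracted from the double-knockdown value, and
#' the score is reported back on the percentage scale.
#'
#' @param singles Normalized singles (from
#'   \code{\link{normalize_single_knockdown}}); the \code{normalized}
#'   column is used.
#' @param doubles Averaged doubles with \code{gene_a}, \code{gene_b},
#'   \code{inhibition}.
#' @param null \code{"bliss"} (default) or \code{"product"}.
#' @return A \code{SynergyTable} data frame over gene pairs with the
#'   measured pair inhibition, both single values and the synergy score,
#'   all in percent; pairs with a missing single get \code{NA}.
#' @export
sirna_synergy <- function(singles, doubles, null = c("bliss", "product")) {
  null <- match.arg(null)
  sv <- stats::setNames(singles$normalized, singles$gene)
  rows <- lapply(seq_len(nrow(doubles)), function(i) {
    a <- doubles$gene_a[i]
    b <- doubles$gene_b[i]
    ya <- .pct_to_frac(sv[a])
    yb <- .pct_to_frac(sv[b])
    yab <- .pct_to_frac(doubles$inhibition[i])
    syn <- if (anyNA(c(ya, yb))) NA_real_ else
      .frac_to_pct(yab - .synergy_null(ya, yb, null))
    data.frame(entity_a = a, entity_b = b,
               inhibition_ab = doubles$inhibition[i],
               single_a = unname(sv[a]) , single_b = unname(sv[b]),
               synergy = unname(syn), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "null") <- null
  out
}

#' Compare predicted and measured pair synergies
#'
#' Maps gene pairs to model node (meta-target) pairs, averages the measured
#' synergies within each node pair, and correlates them with the predicted
#' synergies by Kendall's tau-b.  Node pairs are additionally split into
#' High/Low groups at the mean predicted pair efficacy and the measured
#' inhibition of the groups compared by rank-sum tests with Bonferroni
#' adjustment.
#'
#' @param predicted Data frame over node pairs with columns \code{node_a},
#'   \code{node_b}, \code{synergy} and (optionally, for the grouping)
#'   \code{efficacy}.
#' @param measured Measured gene-pair synergies (\code{entity_a},
#'   \code{entity_b}, \code{synergy}, optionally \code{inhibition_ab}),
#'   e.g. from \code{\link{sirna_synergy}}.
#' @param mapping Data frame mapping \code{gene} to \code{node}.
#' @return A list with \code{pairs} (node-pair table of predicted and mean
#'   measured synergy), \code{kendall} (estimate and p-value; \code{NA}
#'   with fewer than 3 mapped pairs) and, when efficacies are supplied,
#'   \code{groups} with the High/Low comparison.
#' @export
compare_predicted_measured <- function(predicted, measured, mapping) {
  node_of <- stats::setNames(mapping$node, mapping$gene)
  na <- node_of[measured$entity_a]
  nb <- node_of[measured$entity_b]
  ok <- !is.na(na) & !is.na(nb)
  mkey <- .pair_key(na[ok], nb[ok])
  meas <- tapply(measured$synergy[ok], mkey, mean, na.rm = TRUE)
  pkey <- .pair_key(predicted$node_a, predicted$node_b)
  pairs <- data.frame(node_a = predicted$node_a, node_b = predicted$node_b,
                      predicted = predicted$synergy,
                      measured = as.numeric(meas[pkey]),
                      stringsAsFactors = FALSE)
  cc <- stats::complete.cases(pairs[c("predicted", "measured")])
  kendall <- if (sum(cc) < 3L) {
    list(tau = NA_real_, p = NA_real_)
  } else {
    ct <- suppressWarnings(stats::cor.test(pairs$predicted[cc],
                                           pairs$measured[cc],
                                           method = "kendall"))
    list(tau = unname(ct$estimate), p = ct$p.value)
  }
  out <- list(pairs = pairs, kendall = kendall)
  if (!is.null(predicted$efficacy)) {
    cut <- mean(predicted$efficacy, na.rm = TRUE)
    grp <- ifelse(predicted$efficacy >= cut, "high", "low")
    hi <- pairs$measured[cc & grp == "high"]
    lo <- pairs$measured[cc & grp == "low"]
    p <- if (length(hi) && length(lo))
      suppressWarnings(stats::wilcox.test(hi, lo,
                                          alternative = "greater"))$p.value
    else NA_real_
    out$groups <- list(cutoff = cut, group = grp,
                       mean_high = mean(hi), mean_low = mean(lo),
                       p_high_vs_low = stats::p.adjust(p, "bonferroni", n = 1L))
  }
  out
}
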