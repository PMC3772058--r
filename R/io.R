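#' Read a drug efficacy table
#'
#' Reads a delimited text file with one row per drug and returns a drug panel
#' holding the raw efficacy scores (IC50-derived, activity area or drug
#' sensitivity score).  Scaling to the unit interval is a separate, explicit
#' step (\code{\link{scale_efficacy}}).
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param drug_col Name or index of the drug identifier column.
#' @param efficacy_col Name or index of the numeric efficacy column.
#' @param sep Field separator, \code{","} by default.
#' @return A \code{drug_panel}: a data frame with columns \code{drug_id},
#'   \code{raw_efficacy} and \code{scaled_efficacy} (\code{NA} until scaled).
#' @seealso \code{\link{scale_efficacy}}
#' @export
read_efficacy_table <- function(path, drug_col = 1L, efficacy_col = 2L,
                                sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in list(drug_col, efficacy_col)) {
    if (is.character(col) && !col %in% names(tab)) {
      stop("column '", col, "' not found in ", path)
    }
  }
  ids <- as.character(tab[[drug_col]])
  eff <- tab[[efficacy_col]]
  if (!is.numeric(eff)) {
    bad <- which(is.na(suppressWarnings(as.numeric(eff))))
    stop("non-numeric efficacy value(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (anyNA(eff)) {
    stop("missing efficacy value(s) at row(s) ",
         paste(utils::head(which(is.na(eff)), 5L), collapse = ", "))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate drug id(s): ", paste(unique(dup), collapse = ", "))
  }
  drug_panel(ids, eff)
}

#' Construct a drug panel in code
#'
#' @param drug_id Character vector of unique drug identifiers.
#' @param raw_efficacy Numeric efficacy scores, arbitrary units.
#' @param scaled_efficacy Optional pre-scaled efficacies in [0, 1].
#' @return A \code{drug_panel} data frame.
#' @export
drug_panel <- function(drug_id, raw_efficacy, scaled_efficacy = NA_real_) {
  stopifnot(length(drug_id) == length(raw_efficacy),
            !anyDuplicated(drug_id), is.numeric(raw_efficacy))
  out <- data.frame(drug_id = as.character(drug_id),
                    raw_efficacy = as.numeric(raw_efficacy),
                    scaled_efficacy = as.numeric(scaled_efficacy),
                    stringsAsFactors = FALSE)
  class(out) <- c("drug_panel", "data.frame")
  out
}

#' Scale drug efficacies to the unit interval
#'
#' Linearly rescales the raw efficacy scores so that the least effective drug
#' on the panel maps to 0 and the most effective to 1.  All model rules
#' operate on this scale.
#'
#' @param panel A \code{drug_panel}.
#' @return The panel with \code{scaled_efficacy} filled in.  Idempotent:
#'   rescaling an already scaled panel leaves it unchanged.
#' @export
scale_efficacy <- function(panel) {
  stopifnot(inherits(panel, "drug_panel"))
  r <- panel$raw_efficacy
  rng <- range(r)
  if (diff(rng) == 0) {
    stop("degenerate panel: all raw efficacies are identical (", rng[1L], ")")
  }
  panel$scaled_efficacy <- (r - rng[1L]) / diff(rng)
  panel
}

#' Inverse-logarithmic scaling of dissociation constants
#'
#' Maps a binding affinity Kd (nM) to a scaled affinity in [0, 1] such that a
#' high value implies tight binding: \code{s = 1 - log10(kd) / log10(max_conc)},
#' clipped to [0, 1].  With the default maximal assay concentration of
#' 10000 nM, \code{kd = 1} gives 1 and \code{kd = 10000} gives 0.
#'
#' @param kd Numeric vector of Kd values in nM, all > 0.  \code{NA} (target
#'   not measured, i.e. not binding) maps to scaled affinity 0.
#' @param max_conc Maximal assay concentration in nM (default 10000).
#' @return Scaled affinities in [0, 1].
#' @export
inverse_scale_kd <- function(kd, max_conc = 10000) {
  if (any(kd <= 0, na.rm = TRUE)) stop("Kd values must be positive")
  s <- 1 - log10(kd) / log10(max_conc)
  s[is.na(kd)] <- 0
  pmin(1, pmax(0, s))
}

#' Read a drug-by-target matrix
#'
#' Reads a delimited file whose first column holds drug identifiers and whose
#' remaining columns hold per-target values (Kd in nM, scaled affinities, or
#' 0/1 indicators).  Rows are drugs, columns are targets, throughout the
#' package.
#'
#' @param path CSV/TSV path with a header row.
#' @param value_kind One of \code{"kd_nM"}, \code{"scaled"} or
#'   \code{"binary"}.  Empty cells are missing measurements and are treated
#'   as non-binding (Kd infinite / scaled 0 / binary 0).
#' @param sep Field separator.
#' @return A numeric matrix (drugs x targets) with the \code{value_kind}
#'   attribute set; binary matrices carry class \code{binary_target_matrix}.
#' @export
read_target_matrix <- function(path, value_kind = c("kd_nM", "scaled", "binary"),
                               sep = ",") {
  value_kind <- match.arg(value_kind)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate drug id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  affinity_matrix(m, value_kind)
}

#' Construct an affinity (or binary) drug-target matrix
#'
#' @param m Numeric matrix, rows = drugs, columns = targets, with dimnames.
#' @param value_kind \code{"kd_nM"}, \code{"scaled"} or \code{"binary"}.
#' @return The matrix with value-kind metadata; validated per kind.
#' @export
affinity_matrix <- function(m, value_kind = c("kd_nM", "scaled", "binary")) {
  value_kind <- match.arg(value_kind)
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (value_kind == "kd_nM" && any(m <= 0, na.rm = TRUE)) {
    stop("all Kd values must be > 0 nM")
  }
  if (value_kind == "scaled" && any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("scaled affinities must lie in [0, 1]")
  }
  if (value_kind == "binary") {
    if (any(is.na(m)) || !all(m %in% c(0, 1))) {
      stop("binary matrix values must all be 0 or 1")
    }
    storage.mode(m) <- "integer"
    attr(m, "value_kind") <- "binary"
    attr(m, "meta_map") <- stats::setNames(as.list(colnames(m)), colnames(m))
    class(m) <- c("binary_target_matrix", class(m))
    return(m)
  }
  attr(m, "value_kind") <- value_kind
  m
}

.as_binary <- function(x, template) {
  # carries dimnames from template, installs the trivial meta map
  storage.mode(x) <- "integer"
  dimnames(x) <- dimnames(template)
  affinity_matrix(x, "binary")
}

#' Binarize scaled affinities at a global threshold
#'
#' @param aff A scaled affinity matrix (\code{value_kind = "scaled"}).
#' @param threshold Cut-off in [0, 1]; affinities at or above the threshold
#'   count as inhibited (ties are inhibited, for reproducibility).
#' @return A \code{binary_target_matrix}.
#' @export
binarize_global <- function(aff, threshold) {
  if (identical(attr(aff, "value_kind"), "kd_nM")) {
    stop("binarize_global needs scaled affinities; see inverse_scale_kd()")
  }
  if (length(threshold) != 1L || threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]")
  }
  a <- unclass(aff)
  a[is.na(a)] <- 0          # missing measurement = not binding
  .as_binary((a >= threshold) + 0L, aff)
}

#' Binarize Kd values with a drug-specific fold threshold
#'
#' For each drug, targets with \code{Kd <= fold * min(Kd)} over that drug's
#' measured targets are called inhibited (ties inhibited).  This is the
#' drug-specific 50-fold rule used for kinome binding panels.
#'
#' @param aff A Kd matrix in nM (\code{value_kind = "kd_nM"}); \code{NA}
#'   means not measured (never inhibited).
#' @param fold Fold-change over the drug's minimal Kd (default 50).
#' @return A \code{binary_target_matrix}.
#' @export
binarize_drug_specific <- function(aff, fold = 50) {
  stopifnot(identical(attr(aff, "value_kind"), "kd_nM"), fold > 0)
  a <- unclass(aff)
  mins <- suppressWarnings(apply(a, 1L, min, na.rm = TRUE))  # all-NA -> -Inf guard below
  if (any(!is.finite(mins))) {
    stop("drug(s) with no measured Kd: ",
         paste(rownames(a)[!is.finite(mins)], collapse = ", "))
  }
  x <- (a <= outer(fold * mins, rep(1, ncol(a)))) + 0L
  x[is.na(x)] <- 0L
  .as_binary(x, aff)
}

#' Drop sparsely inhibited targets
#'
#' Removes target columns inhibited by fewer than \code{min_drugs} drugs;
#' such targets carry too little efficacy information for the set rules.
#' The dropped target names are kept in the \code{filter_report} attribute.
#'
#' @param X A \code{binary_target_matrix}.
#' @param min_drugs Minimal number of inhibiting drugs (default 2).
#' @return Filtered \code{binary_target_matrix}.
#' @export
filter_targets <- function(X, min_drugs = 2L) {
  stopifnot(inherits(X, "binary_target_matrix"))
  keep <- colSums(X) >= min_drugs
  if (!any(keep)) stop("no targets left after filtering at min_drugs = ",
                       min_drugs)
  out <- X[, keep, drop = FALSE]
  out <- .as_binary(out + 0L, out)
  attr(out, "meta_map") <- attr(X, "meta_map")[colnames(out)]
  attr(out, "filter_report") <- list(min_drugs = min_drugs,
                                     dropped = colnames(X)[!keep])
  out
}

#' Collapse targets with identical inhibition profiles into meta-targets
#'
#' Targets inhibited by exactly the same set of drugs are indistinguishable
#' to the model; they are merged into a single meta-target named by joining
#' the member names with \code{"/"} in original column order.  The
#' \code{meta_map} attribute records the membership so columns can be
#' expanded back.
#'
#' @param X A \code{binary_target_matrix}.
#' @return A \code{binary_target_matrix} with distinct columns.
#' @export
collapse_identical_targets <- function(X) {
  stopifnot(inherits(X, "binary_target_matrix"))
  old_map <- attr(X, "meta_map")
  key <- apply(X, 2L, paste, collapse = "")
  first <- !duplicated(key)
  groups <- split(colnames(X), factor(key, levels = unique(key)))
  nm <- unname(vapply(groups, paste, "", collapse = "/"))
  out <- X[, first, drop = FALSE]
  colnames(out) <- nm
  out <- .as_binary(out + 0L, out)
  # meta map expands through any previous collapse
  attr(out, "meta_map") <- stats::setNames(
    lapply(groups, function(g) unlist(old_map[g], use.names = FALSE)), nm)
  out
}

#' Expand a collapsed matrix back to original target columns
#'
#' Inverse of \code{\link{collapse_identical_targets}} up to column order:
#' reproduces one column per original target using the meta map.
#'
#' @param X A collapsed \code{binary_target_matrix}.
#' @return A \code{binary_target_matrix} with one column per original target.
#' @export
expand_meta_targets <- function(X) {
  stopifnot(inherits(X, "binary_target_matrix"))
  map <- attr(X, "meta_map")
  cols <- lapply(names(map), function(nm) {
    members <- map[[nm]]
    matrix(rep(X[, nm], length(members)), ncol = length(members),
           dimnames = list(rownames(X), members))
  })
  out <- do.call(cbind, cols)
  affinity_matrix(out + 0L, "binary")
}

#' Write a binary target matrix as CSV
#'
#' @param X A \code{binary_target_matrix}.
#' @param path Output path; first column is \code{drug_id}.
#' @export
write_binary_matrix <- function(X, path) {
  df <- data.frame(drug_id = rownames(X), unclass(X)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the filtering / collapsing report as JSON
#'
#' @param X A \code{binary_target_matrix} (after filtering/collapsing).
#' @param path Output JSON path.
#' @export
write_matrix_report <- function(X, path) {
  rep <- list(n_drugs = nrow(X), n_targets = ncol(X),
              meta_map = attr(X, "meta_map"),
              filter = attr(X, "filter_report"))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
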