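# Target inhibition network: the parallel-pathways representation of the
# binarized predicted efficacy function.  A target set is effective iff it
# inhibits at least one node in every parallel pathway, so the pathway
# family is the prime-implicate (minimal transversal) dual of the minimal
# effective sets (prime implicants) of the monotone binarized function.

.popcount <- function(x, m) {
  n <- integer(length(x))
  for (b in 0:(m - 1L)) n <- n + (bitwAnd(x, 2L^b) > 0L)
  n
}

#' Build the target inhibition network
#'
#' Binarizes the predicted efficacy matrix at threshold \code{threshold}
#' (states with efficacy >= threshold are effective; non-identifiable states
#' count as not effective), repairs any monotonicity violations by monotone
#' closure (a state is effective if any of its sub-states is), extracts the
#' minimal effective target sets, and converts them into the dual family of
#' parallel survival pathways.  The round trip is verified exactly: a state
#' is closure-effective iff it intersects every pathway.
#'
#' @param M An \code{efficacy_matrix} in full mode.
#' @param threshold Binarization level on the efficacy scale.
#' @return An \code{inhibition_network}: \code{pathways} (list of character
#'   vectors, each a series chain of meta-target nodes),
#'   \code{minimal_effective_sets}, \code{threshold} and
#'   \code{monotonicity_violations} (count of repaired state pairs).
#' @export
build_inhibition_network <- function(M, threshold) {
  stopifnot(inherits(M, "efficacy_matrix"))
  S <- attr(M, "target_order")
  m <- length(S)
  if (nrow(M) != 2L^m) stop("matrix must be enumerated in full mode")
  eff <- logical(2L^m)
  eff[M$state + 1L] <- M$identifiable & M$efficacy >= threshold
  if (!any(eff)) stop("no effective state at threshold ", threshold)

  # monotone closure by bitwise dynamic programming
  closed <- eff
  for (b in 0:(m - 1L)) {
    has <- bitwAnd(0:(2L^m - 1L), 2L^b) > 0L
    closed[has] <- closed[has] | closed[which(has) - 2L^b]
  }
  violations <- sum(closed & !eff)
  if (violations > 0L) {
    warning(violations, " state(s) made effective by monotone closure ",
            "(non-monotone binarized efficacies)")
  }

  states <- 0:(2L^m - 1L)
  # prime implicants: effective states whose immediate sub-states are not
  minimal <- states[closed[states + 1L] & vapply(states, function(s) {
    bits <- 2L^(0:(m - 1L))
    below <- s - bits[bitwAnd(s, bits) > 0L]
    !any(closed[below + 1L])
  }, TRUE)]
  if (length(minimal) == 0L || any(minimal == 0L)) {
    # the empty set effective => constant function, no pathway constraints
    pathways <- list()
    transversals <- integer(0)
  } else {
    hits_all <- rep(TRUE, length(states))
    for (p in minimal) hits_all <- hits_all & bitwAnd(states, p) > 0L
    # minimal transversals: hitting sets whose immediate subsets do not hit
    transversals <- states[hits_all & vapply(states, function(s) {
      if (!hits_all[s + 1L]) return(FALSE)
      bits <- 2L^(0:(m - 1L))
      below <- s - bits[bitwAnd(s, bits) > 0L]
      !any(hits_all[below + 1L])
    }, TRUE)]
    pathways <- lapply(transversals, .mask_to_set, S = S)
    # round trip: hitting-set semantics must equal the closed function
    hit_eval <- rep(TRUE, length(states))
    for (tv in transversals) hit_eval <- hit_eval & bitwAnd(states, tv) > 0L
    if (!identical(unname(hit_eval), unname(closed))) {
      stop("internal error: pathway family does not reproduce the binarized",
           " efficacy function")   # duality guarantees this never triggers
    }
  }
  structure(list(pathways = pathways,
                 minimal_effective_sets = lapply(minimal, .mask_to_set, S = S),
                 threshold = threshold, targets = S,
                 monotonicity_violations = violations),
            class = "inhibition_network")
}

#' @export
print.inhibition_network <- function(x, ...) {
  cat("target inhibition network (threshold ", x$threshold, "):\n", sep = "")
  if (!length(x$pathways)) {
    cat("  no pathway constraints (every state effective)\n")
  } else {
    for (i in seq_along(x$pathways)) {
      cat("  pathway ", i, ": ", paste(x$pathways[[i]], collapse = " - "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Evaluate a target set against the network
#'
#' @param net An \code{inhibition_network}.
#' @param targets Character vector of inhibited targets.
#' @return TRUE when the set intersects every parallel pathway.
#' @export
network_effective <- function(net, targets) {
  all(vapply(net$pathways, function(p) any(p %in% targets), TRUE))
}

#' Export the inhibition network as GraphML and/or DOT
#'
#' Builds an annotated graph: one circle node per meta-target (attributes:
#' pathway index, position in the chain, and the collapsed kinase members
#' with the tightest-binding member first when a Kd matrix is supplied) and
#' one square node per drug inhibiting any node, linked to the nodes it
#' inhibits.  Consecutive nodes of a pathway are chained by "series" edges.
#' Node ordering is deterministic.
#'
#' @param net An \code{inhibition_network}.
#' @param drugs Optional \code{binary_target_matrix} used to annotate each
#'   node with the drugs inhibiting it.
#' @param kd Optional Kd matrix (nM) over the original kinases, used to
#'   order meta-target members by minimal Kd.
#' @param meta_map Optional meta-target membership map (defaults to the one
#'   on \code{drugs}).
#' @param graphml,dot Optional output paths.
#' @return The \code{igraph} graph, invisibly.
#' @export
export_network <- function(net, drugs = NULL, kd = NULL, meta_map = NULL,
                           graphml = NULL, dot = NULL) {
  nodes <- unique(unlist(net$pathways))
  if (!length(nodes)) nodes <- character(0)
  if (is.null(meta_map) && !is.null(drugs)) meta_map <- attr(drugs, "meta_map")
  node_df <- data.frame(name = nodes, type = rep("target", length(nodes)),
                        stringsAsFactors = FALSE)
  if (length(nodes)) {
    node_df$pathway <- vapply(nodes, function(n)
      which(vapply(net$pathways, function(p) n %in% p, TRUE))[1L], 0L)
    node_df$members <- vapply(nodes, function(n) {
      members <- if (!is.null(meta_map) && n %in% names(meta_map))
        meta_map[[n]] else strsplit(n, "/", fixed = TRUE)[[1L]]
      if (!is.null(kd)) {
        found <- intersect(members, colnames(kd))
        if (length(found)) {
          minkd <- apply(unclass(kd)[, found, drop = FALSE], 2L, min,
                         na.rm = TRUE)
          members <- c(found[order(minkd)], setdiff(members, found))
        }
      }
      paste(members, collapse = "/")
    }, "")
  }
  edges <- data.frame(from = character(0), to = character(0),
                      kind = character(0), stringsAsFactors = FALSE)
  for (p in net$pathways) {
    if (length(p) > 1L) {
      edges <- rbind(edges, data.frame(from = p[-length(p)], to = p[-1L],
                                       kind = "series",
                                       stringsAsFactors = FALSE))
    }
  }
  if (!is.null(drugs)) {
    for (n in nodes) {
      if (!n %in% colnames(drugs)) next
      inhib <- rownames(drugs)[unclass(drugs)[, n] == 1L]
      for (d in sort(inhib)) {
        if (!d %in% node_df$name) {
          node_df <- rbind(node_df,
                           data.frame(name = d, type = "drug",
                                      pathway = NA_integer_, members = d,
                                      stringsAsFactors = FALSE))
        }
        edges <- rbind(edges, data.frame(from = d, to = n, kind = "inhibits",
                                         stringsAsFactors = FALSE))
      }
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = node_df)
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(dot)) igraph::write_graph(g, dot, format = "dot")
  invisible(g)
}
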