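#' Run the full target-inhibition analysis pipeline
#'
#' Wires the whole workflow end to end: read efficacies and the drug-target
#' matrix, scale, binarize, filter and collapse targets, select the
#' cancer-specific target set, enumerate the predicted efficacy matrix,
#' score target- and drug-pair synergies, and construct and export the
#' target inhibition network.  Every intermediate is written to the output
#' directory together with a manifest echoing the fully resolved
#' configuration, so a run is reproducible from the manifest alone.
#'
#' @param config A named list (or path to a JSON file holding one) with
#'   entries: \code{efficacy_csv}, \code{matrix_csv}, \code{value_kind}
#'   (\code{"kd_nM"}, \code{"scaled"} or \code{"binary"}),
#'   \code{binarize} (\code{"global"} with \code{threshold}, or
#'   \code{"drug_specific"} with \code{fold}), \code{min_drugs},
#'   \code{selection} (\code{"sffs"}, \code{"greedy"} or
#'   \code{"exhaustive"}), \code{max_k}, \code{synergy_null},
#'   \code{network_threshold}, \code{matrix_mode} (\code{"full"} or
#'   \code{"pairwise"}), \code{seed} and \code{out_dir}.
#' @return Invisibly, a list with the selection result, efficacy matrix,
#'   synergy tables and network.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(value_kind = "kd_nM", binarize = "drug_specific",
                   threshold = 0.9, fold = 50, min_drugs = 2L,
                   selection = "sffs", max_k = NULL, synergy_null = "bliss",
                   network_threshold = NULL, matrix_mode = "full",
                   seed = 1L, out_dir = "timnet_out")
  cfg <- utils::modifyList(defaults, config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  panel <- stage("efficacy", {
    scale_efficacy(read_efficacy_table(cfg$efficacy_csv))
  })
  X <- stage("binarize", {
    m <- read_target_matrix(cfg$matrix_csv, cfg$value_kind)
    if (cfg$value_kind == "binary") m
    else if (cfg$binarize == "global") {
      if (cfg$value_kind == "kd_nM") m <- affinity_matrix(inverse_scale_kd(unclass(m)) * 1, "scaled")
      binarize_global(m, cfg$threshold)
    } else binarize_drug_specific(m, cfg$fold)
  })
  X <- stage("filter", {
    if (!identical(rownames(X), panel$drug_id)) {
      stop("drug ids of the efficacy table and matrix differ")
    }
    collapse_identical_targets(filter_targets(X, cfg$min_drugs))
  })
  write_binary_matrix(X, file.path(cfg$out_dir, "binary_matrix.csv"))
  write_matrix_report(X, file.path(cfg$out_dir, "matrix_report.json"))

  sel <- stage("select", switch(cfg$selection,
    sffs = sffs_select(X, panel, max_k = cfg$max_k),
    greedy = greedy_select(X, panel, max_k = cfg$max_k, method = "timma"),
    exhaustive = exhaustive_select(X, panel),
    stop("unknown selection method: ", cfg$selection)))
  utils::write.csv(sel$trace, file.path(cfg$out_dir, "selection_trace.csv"),
                   row.names = FALSE)

  model <- timma_model(X, panel, sel$selected)
  M <- stage("matrix", enumerate_efficacy_matrix(model, cfg$matrix_mode))
  utils::write.csv(as.data.frame(M),
                   file.path(cfg$out_dir, "efficacy_matrix.csv"),
                   row.names = FALSE)
  syn <- stage("synergy", synergy_table(M, cfg$synergy_null))
  utils::write.csv(syn, file.path(cfg$out_dir, "target_synergy.csv"),
                   row.names = FALSE, na = "NA")
  dsyn <- stage("synergy", drug_synergy_table(M, X, cfg$synergy_null))
  utils::write.csv(dsyn, file.path(cfg$out_dir, "drug_synergy.csv"),
                   row.names = FALSE, na = "NA")

  net <- NULL
  if (cfg$matrix_mode == "full") {
    thr <- cfg$network_threshold
    if (is.null(thr)) thr <- mean(range(model$y))
    net <- stage("network", build_inhibition_network(M, thr))
    export_network(net, drugs = X,
                   graphml = file.path(cfg$out_dir, "network.graphml"),
                   dot = file.path(cfg$out_dir, "network.dot"))
    jsonlite::write_json(list(threshold = thr, pathways = net$pathways),
                         file.path(cfg$out_dir, "network.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  manifest <- c(cfg, list(
    package_version = as.character(utils::packageVersion("timnet")),
    selected = sel$selected, loo_error = sel$loo_error,
    synergy_null = cfg$synergy_null))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(list(panel = panel, X = X, selection = sel, matrix = M,
                 target_synergy = syn, drug_synergy = dsyn, network = net))
}
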