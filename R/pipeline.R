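#' Run the full synthetic-screen analysis pipeline
#'
#' Orchestrates the stages -- simulate, preprocess, doseresponse,
#' interactions, equivalence, fit, toy -- from a single configuration,
#' writing each stage's CSV artifacts and a run manifest to `out_dir`.
#' Every stage is a pure function of (inputs, config, seed), so rerunning
#' with an identical configuration reproduces identical artifacts.
#'
#' @param config list with elements `panel` ([ligand_panel()]), `contexts`
#'   (named list of [receptor_context()]), `truth` ([model_params()]),
#'   `noise` ([noise_model()]), and optionally `n_replicates`, `n_ratios`,
#'   `min_cells`, `ic_split`, `cluster_threshold`, `global_threshold`,
#'   `overrides` (data.frame), `fit` (list: `ligands`, `receptor_expr`,
#'   `criteria`, `n_starts`, `seed`), `sequences` (for the seqcompare
#'   stage).
#' @param stages character subset of
#'   `c("simulate", "preprocess", "doseresponse", "interactions",
#'   "equivalence", "seqcompare", "fit", "toy")`; stages are always
#'   executed in that order and later stages require the earlier ones.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @return (invisibly) a list with each executed stage's in-memory result
#'   and the manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "doseresponse",
                                    "interactions", "equivalence", "fit",
                                    "toy"),
                         out_dir = NULL) {
  all_stages <- c("simulate", "preprocess", "doseresponse", "interactions",
                  "equivalence", "seqcompare", "fit", "toy")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) .stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  .validate_config(config, stages)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, df) {
    if (!is.null(out_dir))
      write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                row.names = FALSE)
  }
  res <- list()
  manifest <- list(seed = config$noise$seed, stages = stages)
  n_ratios <- config$n_ratios %||% 9L
  split <- config$ic_split %||% 0.5

  if ("simulate" %in% stages) {
    res$simulate <- generate_dataset(
      config$panel, config$contexts, config$truth, config$noise,
      n_replicates = config$n_replicates %||% 4L, n_ratios = n_ratios)
    emit("wells", res$simulate$wells)
    emit("ground_truth", res$simulate$truth)
    emit("factors", res$simulate$factors)
  }
  if ("preprocess" %in% stages) {
    res$preprocess <- preprocess_dataset(res$simulate$wells,
                                         min_cells = config$min_cells %||% 500L)
    emit("processed", res$preprocess)
    if (!is.null(attr(res$preprocess, "replicate_factors")))
      emit("replicate_factors", attr(res$preprocess, "replicate_factors"))
  }
  if ("doseresponse" %in% stages) {
    res$doseresponse <- dose_response_table(res$preprocess, config$panel)
    emit("dose_response", res$doseresponse)
  }
  if ("interactions" %in% stages) {
    res$interactions <- interaction_table(res$preprocess,
                                          n_ratios = n_ratios, split = split,
                                          overrides = config$overrides)
    emit("interaction_ratios", res$interactions$ratios)
    emit("interaction_pairs", res$interactions$pairs)
  }
  if ("equivalence" %in% stages) {
    ligs <- config$panel$ligand
    contexts <- names(config$contexts)
    feats <- build_feature_vectors(res$doseresponse, res$interactions$pairs,
                                   ligs, contexts)
    per_ctx <- lapply(contexts, function(cx) {
      cols <- grep(paste0("^", cx, ":"), colnames(feats))
      pc <- res$interactions$pairs
      pc <- pc[pc$context_id == cx & pc$row_kind == "pair", ]
      rls <- setNames(res$doseresponse$rls[res$doseresponse$context_id == cx],
                      res$doseresponse$ligand[res$doseresponse$context_id == cx])
      cluster_equivalence(feats[, cols, drop = FALSE],
                          threshold = config$cluster_threshold %||% 1,
                          categories = data.frame(ligand_a = pc$ligand_a,
                                                  ligand_b = pc$ligand_b,
                                                  category = pc$category),
                          strengths = rls)
    })
    names(per_ctx) <- contexts
    glob <- global_equivalence(feats,
                               threshold = config$global_threshold %||% 7)
    res$equivalence <- list(features = feats, per_context = per_ctx,
                            global = glob)
    memb <- do.call(rbind, lapply(contexts, function(cx)
      data.frame(context_id = cx, ligand = names(per_ctx[[cx]]$membership),
                 group = per_ctx[[cx]]$membership, stringsAsFactors = FALSE)))
    memb <- rbind(memb, data.frame(context_id = "global",
                                   ligand = names(glob$membership),
                                   group = glob$membership,
                                   stringsAsFactors = FALSE))
    emit("equivalence_groups", memb)
    if (!is.null(out_dir) && !is.null(glob$tree))
      equivalence_newick(glob, file.path(out_dir, "global_tree.nwk"))
  }
  if ("seqcompare" %in% stages) {
    sq <- sequence_distance_matrix(config$sequences)
    res$seqcompare <- sq
    emit("sequence_distance", as.data.frame(sq$distance))
  }
  if ("fit" %in% stages) {
    fcfg <- config$fit
    fo <- assemble_observations(res$preprocess, fcfg$ligands,
                                fcfg$receptor_expr)
    fits <- fit_multistart(fo, n_starts = fcfg$n_starts %||% 50L,
                           seed = fcfg$seed %||% config$noise$seed)
    flt <- filter_solutions(fits, fo, criteria = fcfg$criteria)
    res$fit <- list(observations = fo, fits = fits, filtered = flt)
    fdf <- do.call(rbind, lapply(seq_along(fits), function(i)
      data.frame(rank = i, start = fits[[i]]$start,
                 residual = fits[[i]]$residual,
                 converged = fits[[i]]$converged)))
    emit("fit_results", fdf)
    if (length(flt$accepted))
      emit("best_fit_params", as.data.frame(flt$accepted[[1L]]$params))
  }
  if ("toy" %in% stages) {
    toy <- toy_model_factory()
    states <- lapply(names(toy$contexts), function(cx)
      do.call(rbind, lapply(names(toy$environments), function(ev)
        data.frame(context = cx, environment = ev,
                   S = solve_equilibrium(toy$params, toy$environments[[ev]],
                                         toy$contexts[[cx]])$S,
                   stringsAsFactors = FALSE))))
    res$toy <- list(model = toy, outputs = do.call(rbind, states))
    emit("toy_outputs", res$toy$outputs)
  }
  manifest$artifacts <- if (!is.null(out_dir)) list.files(out_dir) else character(0)
  res$manifest <- manifest
  if (!is.null(out_dir)) {
    writeLines(c(sprintf("seed: %s", manifest$seed),
                 sprintf("stages: %s", paste(stages, collapse = ", ")),
                 sprintf("artifacts: %s",
                         paste(manifest$artifacts, collapse = ", "))),
               file.path(out_dir, "manifest.txt"))
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_config <- function(config, stages) {
  if ("simulate" %in% stages) {
    if (!inherits(config$panel, "ligand_panel")) .stopf("config$panel must be a ligand_panel")
    if (!inherits(config$truth, "bmp_params")) .stopf("config$truth must be a model_params object")
    if (!inherits(config$noise, "noise_model")) .stopf("config$noise must be a noise_model")
    if (is.null(names(config$contexts))) .stopf("config$contexts must be a named list")
    for (cx in names(config$contexts))
      if (!inherits(config$contexts[[cx]], "receptor_context"))
        .stopf("context %s is not a receptor_context", cx)
  }
  if ("fit" %in% stages) {
    fcfg <- config$fit
    if (is.null(fcfg$ligands) || is.null(fcfg$receptor_expr))
      .stopf("config$fit needs ligands and receptor_expr")
    for (cx in names(config$contexts))
      if (!cx %in% names(fcfg$receptor_expr))
        .stopf("config$fit$receptor_expr is missing context %s", cx)
  }
  if ("seqcompare" %in% stages && is.null(config$sequences))
    .stopf("seqcompare stage requires config$sequences")
  invisible(TRUE)
}
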