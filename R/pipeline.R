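#' Run the full scoring pipeline on a synthetic universe
#'
#' Chains the whole method end to end: simulate (or accept) a universe,
#' curate training labels from homozygous non-coding deletions and conserved
#' elements, build the integrated network, compute / prune / impute the
#' feature matrix, train the balanced-resampling forest, score all
#' non-training enhancers and run the downstream validation statistics.
#'
#' @param universe a `synthetic_universe`, or NULL to generate one from
#'   `spec`.
#' @param spec a `fixture_spec` used when `universe` is NULL.
#' @param repeats,pos_per_repeat,folds training-protocol sizes (see
#'   [balanced_repeat_train()]).
#' @param seed master seed for the training stage.
#' @param prune_threshold Spearman pruning cutoff.
#' @param impute_policy imputation policy for missing GIS/conservation.
#' @param out_dir optional directory: tabular results are written there as
#'   TSVs with `#` provenance headers.
#' @return list with `universe`, `labels`, `net`, `features` (pruned,
#'   imputed), `training`, `scores`, `tissue_enrichment`, `importance`.
#' @export
run_pipeline <- function(universe = NULL, spec = fixture_spec(),
                         repeats = 50, pos_per_repeat = 50, folds = 10,
                         seed = 1, prune_threshold = 0.9,
                         impute_policy = "median", out_dir = NULL) {
  if (is.null(universe)) universe <- generate_universe(spec)

  dels <- homozygous_noncoding_deletions(universe$deletions, universe$exons)
  labels <- label_set(
    call_lof_tolerant(universe$enhancers, dels),
    call_low_tolerance(universe$enhancers, universe$conserved),
    known_ids = universe$enhancers$id
  )

  reg <- universe$network |>
    dplyr::group_by(.data$enhancer, .data$gene) |>
    dplyr::summarise(tissues = list(sort(unique(.data$tissue))),
                     .groups = "drop")
  net <- build_meganet(reg, universe$interactions)

  feats <- compute_enhancer_features(net, gis = universe$gis,
                                     conservation = universe$conservation)
  feats <- prune_correlated_features(feats, threshold = prune_threshold)
  feats <- impute_missing(feats, policy = impute_policy, labels = labels)

  n_pos <- length(intersect(labels$lof_tolerant, feats$enhancer))
  training <- balanced_repeat_train(
    feats, labels, repeats = repeats,
    pos_per_repeat = min(pos_per_repeat, n_pos), folds = folds, seed = seed)

  scores <- predict_scores(training$model, feats)

  enh_tissues <- stats::setNames(universe$enhancers$tissues,
                                 universe$enhancers$id)
  enrich <- tissue_enrichment(labels, enh_tissues, label_class = "tolerant")
  importance <- feature_importance_report(training$model)

  result <- list(universe = universe, labels = labels, net = net,
                 features = feats, training = training, scores = scores,
                 tissue_enrichment = enrich, importance = importance)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir, seed = seed)
  result
}

# provenance header lines prepended to every pipeline output table
provenance_header <- function(seed, extra = character()) {
  c(sprintf("# enhtol %s", as.character(utils::packageVersion("enhtol"))),
    sprintf("# seed=%d", seed), extra)
}

#' Write pipeline result tables
#'
#' @param result list from [run_pipeline()].
#' @param dir output directory.
#' @param seed seed echoed in the provenance headers.
#' @return written paths, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir, seed = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- provenance_header(seed)
  emit <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(c(hdr, paste(names(df), collapse = "\t")), path)
    readr::write_tsv(df, path, append = TRUE, progress = FALSE)
    path
  }
  labels_df <- tibble::tibble(
    enhancer = c(result$labels$lof_tolerant, result$labels$low_tolerance),
    label = c(rep("tolerant", length(result$labels$lof_tolerant)),
              rep("low", length(result$labels$low_tolerance))))
  runs_df <- result$training$runs |>
    dplyr::select(-dplyr::any_of(c("fold_aurocs", "pos_ids")))
  paths <- c(
    emit(labels_df, "labels.tsv"),
    emit(runs_df, "training_runs.tsv"),
    emit(result$scores, "scores.tsv"),
    emit(result$tissue_enrichment, "tissue_enrichment.tsv"),
    emit(result$importance$features, "feature_importance.tsv"),
    emit(result$importance$groups, "feature_importance_groups.tsv"))
  invisible(paths)
}
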