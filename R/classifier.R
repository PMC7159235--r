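#' Stratified k-fold assignment
#'
#' Assigns each observation to one of `k` folds so that the class ratio is
#' preserved within +/- 1 observation per fold. Randomness comes from the
#' caller's RNG state, keeping the whole training protocol reproducible from
#' one master seed.
#'
#' @param y class vector (coerced to factor).
#' @param k number of folds.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k = 10) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# AUROC via pROC, oriented so that higher scores favor the positive class.
auroc <- function(y, p, positive = "tolerant") {
  lev <- c(setdiff(levels(as.factor(y)), positive), positive)
  as.numeric(pROC::auc(pROC::roc(response = factor(y, levels = lev),
                                 predictor = p, levels = lev,
                                 direction = "<", quiet = TRUE)))
}

# Area under the precision-recall curve by step-wise average precision:
# AP = sum_k (R_k - R_{k-1}) * P_k over decreasing score thresholds.
auprc <- function(y, p, positive = "tolerant") {
  ord <- order(p, decreasing = TRUE)
  pos <- y[ord] == positive
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  rec <- tp / sum(pos)
  sum(diff(c(0, rec)) * prec)
}

# Hyperparameter candidates: a random draw over the forest's knobs followed
# by a local grid refinement around the best mtry (search-then-refine).
rf_candidates <- function(p, n_random = 4) {
  base_mtry <- max(1, round(sqrt(p)))
  cand <- list()
  for (i in seq_len(n_random)) {
    cand[[i]] <- list(
      num.trees = sample(c(250L, 500L), 1),
      mtry = min(p, max(1L, round(base_mtry * 2^stats::runif(1, -1, 1.5)))),
      min.node.size = sample(c(1L, 2L, 5L), 1)
    )
  }
  cand
}

rf_refine <- function(best, p) {
  mtrys <- unique(pmin(p, pmax(1L, round(best$mtry * c(0.5, 2)))))
  mtrys <- setdiff(mtrys, best$mtry)
  lapply(mtrys, function(m) {
    list(num.trees = best$num.trees, mtry = m,
         min.node.size = best$min.node.size)
  })
}

# Stratified k-fold CV of one forest configuration. Returns per-fold AUROC
# and AUPRC. A degenerate single-class fold (only possible for tiny inputs)
# is re-drawn with a perturbed assignment.
cv_forest <- function(X, y, config, folds = 10, seed = 1) {
  k <- min(folds, min(table(y)))
  fold <- stratified_folds(y, k)
  for (attempt in 1:10) {
    degenerate <- any(vapply(seq_len(k), function(f)
      length(unique(y[fold == f])) < 2 || length(unique(y[fold != f])) < 2,
      logical(1)))
    if (!degenerate) break
    fold <- stratified_folds(y, k)
  }
  aurocs <- auprcs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- ranger::ranger(
      x = X[tr, , drop = FALSE], y = factor(y[tr]),
      probability = TRUE, num.trees = config$num.trees, mtry = config$mtry,
      min.node.size = config$min.node.size, seed = seed + f,
      num.threads = 1, verbose = FALSE)
    pr <- stats::predict(fit, data = X[!tr, , drop = FALSE],
                         num.threads = 1)$predictions[, "tolerant"]
    aurocs[f] <- auroc(y[!tr], pr)
    auprcs[f] <- auprc(y[!tr], pr)
  }
  list(fold_aurocs = aurocs, fold_auprcs = auprcs)
}

#' Balanced-resampling random-forest training
#'
#' Implements the balanced training protocol for a large positive class and a
#' small negative class: each repeat draws `pos_per_repeat` LoF-tolerant
#' enhancers (cycling through a shuffled positive pool without replacement, so
#' every positive is used at least once when `repeats * pos_per_repeat >=`
#' the pool size) and pairs them with all low-LoF-tolerance enhancers; a
#' hyperparameter search (random draw plus local grid refinement) is scored
#' by stratified k-fold cross-validated mean AUROC; the final model is the
#' forest refit on the full sample of the winning repeat (highest mean AUROC;
#' ties broken by mean AUPRC, then lower repeat index).
#'
#' Predicted probabilities of the resulting model are the mean predicted
#' class probabilities of the trees in the forest.
#'
#' @param m feature tibble (`enhancer` id column + numeric features),
#'   typically pruned and imputed.
#' @param labels a `label_set`.
#' @param repeats number of balanced repeats.
#' @param pos_per_repeat positives drawn per repeat.
#' @param folds cross-validation folds.
#' @param search_budget list with `n_random` (random candidates per repeat)
#'   and `refine` (logical, add the local mtry refinement).
#' @param seed master seed; all per-repeat seeds are derived from it and
#'   recorded.
#' @param with_conservation if FALSE the `conservation` column is excluded
#'   from the schema before training.
#' @return list of class `balanced_training`:
#'   \describe{
#'     \item{runs}{tibble, one row per repeat: seed, hyperparameters,
#'       `mean_auroc`, `sd_auroc`, `mean_auprc`, list columns `fold_aurocs`,
#'       `pos_ids`}
#'     \item{model}{`lof_model` refit on the winning repeat's full sample}
#'     \item{auroc_mean, auroc_sd}{across-repeat average and sd of the
#'       per-repeat mean AUROCs}
#'   }
#' @export
balanced_repeat_train <- function(m, labels, repeats = 50,
                                  pos_per_repeat = 50, folds = 10,
                                  search_budget = list(n_random = 4,
                                                       refine = TRUE),
                                  seed = 1, with_conservation = TRUE) {
  stopifnot(inherits(labels, "label_set"))
  schema <- setdiff(names(m), "enhancer")
  if (!with_conservation) schema <- setdiff(schema, "conservation")
  X <- as.matrix(m[schema])
  rownames(X) <- m$enhancer
  if (anyNA(X)) stop("feature matrix contains missing values; impute first",
                     call. = FALSE)
  pos_pool <- intersect(labels$lof_tolerant, m$enhancer)
  neg_ids <- intersect(labels$low_tolerance, m$enhancer)
  if (length(pos_pool) < pos_per_repeat) {
    stop("fewer positives (", length(pos_pool), ") than pos_per_repeat (",
         pos_per_repeat, ")", call. = FALSE)
  }
  if (length(neg_ids) < 2) stop("need at least 2 negatives", call. = FALSE)

  set.seed(seed)
  repeat_seeds <- sample.int(2^31 - 2, repeats)
  # cycle through the shuffled positive pool so coverage is guaranteed
  pool <- sample(pos_pool)
  ptr <- 0L
  draw_pos <- function() {
    out <- character()
    need <- pos_per_repeat
    while (need > 0) {
      if (ptr >= length(pool)) { pool <<- sample(pos_pool); ptr <<- 0L }
      take <- min(need, length(pool) - ptr)
      out <- c(out, pool[(ptr + 1):(ptr + take)])
      ptr <<- ptr + take
      need <- need - take
    }
    unique(out)[seq_len(min(pos_per_repeat, length(unique(out))))]
  }
  pos_draws <- lapply(seq_len(repeats), function(i) draw_pos())

  runs <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(repeat_seeds[r])
    ids <- c(pos_draws[[r]], neg_ids)
    y <- c(rep("tolerant", length(pos_draws[[r]])),
           rep("low", length(neg_ids)))
    Xr <- X[ids, , drop = FALSE]
    cands <- rf_candidates(ncol(X), n_random = search_budget$n_random)
    scored <- lapply(cands, function(cf)
      c(cf, cv_forest(Xr, y, cf, folds = folds, seed = repeat_seeds[r])))
    best <- scored[[which.max(vapply(scored, function(s)
      mean(s$fold_aurocs), numeric(1)))]]
    if (isTRUE(search_budget$refine)) {
      ref <- rf_refine(best, ncol(X))
      if (length(ref) > 0) {
        scored2 <- lapply(ref, function(cf)
          c(cf, cv_forest(Xr, y, cf, folds = folds,
                          seed = repeat_seeds[r])))
        allc <- c(list(best), scored2)
        best <- allc[[which.max(vapply(allc, function(s)
          mean(s$fold_aurocs), numeric(1)))]]
      }
    }
    runs[[r]] <- tibble::tibble(
      repeat_index = r, seed = repeat_seeds[r],
      num_trees = best$num.trees, mtry = best$mtry,
      min_node_size = best$min.node.size,
      mean_auroc = mean(best$fold_aurocs),
      sd_auroc = stats::sd(best$fold_aurocs),
      mean_auprc = mean(best$fold_auprcs),
      fold_aurocs = list(best$fold_aurocs),
      pos_ids = list(pos_draws[[r]])
    )
  }
  runs <- dplyr::bind_rows(runs)
  win <- runs |>
    dplyr::arrange(dplyr::desc(.data$mean_auroc),
                   dplyr::desc(.data$mean_auprc), .data$repeat_index) |>
    dplyr::slice(1)
  win_ids <- c(win$pos_ids[[1]], neg_ids)
  win_y <- factor(c(rep("tolerant", length(win$pos_ids[[1]])),
                    rep("low", length(neg_ids))))
  fit <- ranger::ranger(
    x = X[win_ids, , drop = FALSE], y = win_y, probability = TRUE,
    num.trees = win$num_trees, mtry = win$mtry,
    min.node.size = win$min_node_size, importance = "impurity",
    seed = win$seed, num.threads = 1, verbose = FALSE)
  model <- structure(list(fit = fit, schema = schema,
                          winning_repeat = win,
                          training_ids = win_ids,
                          with_conservation = with_conservation,
                          seed = seed),
                     class = "lof_model")
  structure(list(runs = runs, model = model,
                 auroc_mean = mean(runs$mean_auroc),
                 auroc_sd = stats::sd(runs$mean_auroc)),
            class = "balanced_training")
}

#' @export
print.balanced_training <- function(x, ...) {
  cat("<balanced_training> ", nrow(x$runs), " repeats; mean AUROC ",
      sprintf("%.4f +/- %.4f", x$auroc_mean, x$auroc_sd),
      "; selected repeat ", x$model$winning_repeat$repeat_index,
      sprintf(" (AUROC %.4f)", x$model$winning_repeat$mean_auroc), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.lof_model <- function(x, ...) {
  cat("<lof_model> ", length(x$schema), " features",
      if (!x$with_conservation) " (conservation excluded)",
      "; trained on ", length(x$training_ids), " enhancers\n", sep = "")
  invisible(x)
}

#' Null-model overfitting check with pseudo-negatives
#'
#' Repeats balanced training with the true positives but with negatives drawn
#' at random from enhancers labeled neither tolerant nor low-tolerance. A
#' resulting mean-of-mean-AUROCs near 0.5 certifies that the small negative
#' class does not by itself let the forest overfit.
#'
#' @inheritParams balanced_repeat_train
#' @param n_pseudo pseudo-negatives per repeat (defaults to
#'   `pos_per_repeat`).
#' @return list: `mean_aurocs` (one per repeat), `mean`, `sd`.
#' @export
null_model_check <- function(m, labels, repeats = 50, pos_per_repeat = 50,
                             folds = 10, n_pseudo = NULL,
                             search_budget = list(n_random = 4,
                                                  refine = FALSE),
                             seed = 1) {
  stopifnot(inherits(labels, "label_set"))
  if (is.null(n_pseudo)) n_pseudo <- pos_per_repeat
  schema <- setdiff(names(m), "enhancer")
  X <- as.matrix(m[schema])
  rownames(X) <- m$enhancer
  pos_pool <- intersect(labels$lof_tolerant, m$enhancer)
  unlabeled <- setdiff(m$enhancer,
                       c(labels$lof_tolerant, labels$low_tolerance))
  if (length(unlabeled) < n_pseudo) {
    stop("unlabeled pool (", length(unlabeled),
         ") smaller than n_pseudo (", n_pseudo, ")", call. = FALSE)
  }
  set.seed(seed)
  repeat_seeds <- sample.int(2^31 - 2, repeats)
  vals <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(repeat_seeds[r])
    pos <- sample(pos_pool, min(pos_per_repeat, length(pos_pool)))
    pneg <- sample(unlabeled, n_pseudo)
    ids <- c(pos, pneg)
    y <- c(rep("tolerant", length(pos)), rep("low", length(pneg)))
    cands <- rf_candidates(ncol(X), n_random = search_budget$n_random)
    scores <- vapply(cands, function(cf)
      mean(cv_forest(X[ids, , drop = FALSE], y, cf, folds = folds,
                     seed = repeat_seeds[r])$fold_aurocs), numeric(1))
    vals[r] <- max(scores)
  }
  list(mean_aurocs = vals, mean = mean(vals), sd = stats::sd(vals))
}

#' Score enhancers with a trained model
#'
#' Applies the selected forest to every enhancer in the matrix except the
#' training ids. The probability is the mean of the per-tree class
#' probabilities; the binary call is `tolerant` at `p >= 0.5`; confident
#' calls require `p > 0.95` (tolerant) or `p < 0.05` (low tolerance).
#'
#' @param model a `lof_model`.
#' @param m feature tibble whose columns cover the model schema.
#' @param exclude_ids enhancer ids to omit (defaults to the model's training
#'   ids).
#' @param p_binary,p_confident_high,p_confident_low call thresholds.
#' @return tibble `enhancer_id`, `p_lof_tol`, `binary_call`,
#'   `confident_call`.
#' @export
predict_scores <- function(model, m, exclude_ids = model$training_ids,
                           p_binary = 0.5, p_confident_high = 0.95,
                           p_confident_low = 0.05) {
  stopifnot(inherits(model, "lof_model"))
  have <- setdiff(names(m), "enhancer")
  missing_cols <- setdiff(model$schema, have)
  if (length(missing_cols) > 0) {
    stop("feature matrix is missing model columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- !m$enhancer %in% exclude_ids
  mm <- m[keep, , drop = FALSE]
  X <- as.matrix(mm[model$schema])
  p <- stats::predict(model$fit, data = X,
                      num.threads = 1)$predictions[, "tolerant"]
  tibble::tibble(
    enhancer_id = mm$enhancer,
    p_lof_tol = as.numeric(p),
    binary_call = ifelse(p >= p_binary, "tolerant", "low"),
    confident_call = ifelse(p > p_confident_high, "tolerant",
                            ifelse(p < p_confident_low, "low", "none"))
  )
}

# feature-name -> importance group, following the grouped reporting scheme:
# gene-side aggregates, conservation, enhancer-topology, edge-ubiquity.
feature_group <- function(feature) {
  ifelse(feature == "conservation", "conservation",
  ifelse(grepl("^EGTU", feature), "edge",
  ifelse(feature %in% c("EOD", "ETU") | grepl("__EOD$", feature), "enhancer",
         "gene")))
}

#' Feature-importance report with group sums
#'
#' Mean-decrease-impurity importances of the selected forest, normalized to
#' sum 1, plus collective sums over the four feature groups (gene,
#' conservation, enhancer, edge).
#'
#' @param model a `lof_model` trained with impurity importance.
#' @return list: `features` (tibble `feature`, `group`, `importance`, sorted
#'   decreasing) and `groups` (tibble `group`, `importance`).
#' @export
feature_importance_report <- function(model) {
  stopifnot(inherits(model, "lof_model"))
  imp <- model$fit$variable.importance
  if (is.null(imp)) stop("model was trained without impurity importance",
                         call. = FALSE)
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  features <- tibble::tibble(feature = names(imp),
                             group = feature_group(names(imp)),
                             importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  groups <- features |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(importance = sum(.data$importance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$importance))
  list(features = features, groups = groups)
}
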