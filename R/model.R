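#' Train the multiscale structural mapping classifier
#'
#' The end-to-end trainable core: smoothed per-subject feature stacks are
#' reduced to one value per vertex by vertex-wise PLS (fitted on the training
#' split only), the reduced maps are vectorized per subject (optionally
#' capped to the top-k vertices by training-split effect size), and a
#' class-weighted top-3 ensemble is selected by 5-initialization x 4-fold
#' cross-validation over the train+validation pool. The decision threshold
#' minimizes FP + FN on the validation split. Test subjects are never seen by
#' any fitted object.
#'
#' @param x subjects x vertices x features array ([stack_features()]), all
#'   subjects.
#' @param labels binary diagnosis per subject (e.g. "AD"/"CN").
#' @param split train/val/test assignment per subject ([make_splits()]).
#' @param positive label of the disease class (default: first sorted label).
#' @param config an [mssm_config()].
#' @param feature one of `"mssm"` (PLS-reduced 9-feature maps, default) or
#'   `"thickness"` (thickness map alone, no PLS — the traditional-morphometry
#'   comparator).
#' @param top_k optional cap: keep only the `top_k` vertices with the largest
#'   absolute training-split effect size as classifier inputs (`Inf` = all).
#' @param params hyperparameters forwarded to [select_ensemble()].
#' @return object of class `mssm_model`.
#' @export
mssm_train <- function(x, labels, split, positive = NULL,
                       config = mssm_config(), feature = c("mssm", "thickness"),
                       top_k = Inf, params = list()) {
  feature <- match.arg(feature)
  y <- encode_labels(labels, positive = positive)
  stopifnot(length(y) == dim(x)[1], length(split) == dim(x)[1])
  tr <- split == "train"; va <- split == "val"; te <- split == "test"
  if (sum(tr) < 4L || sum(va) < 2L) stop("training/validation splits too small")

  pls <- NULL
  if (feature == "mssm") {
    pls <- fit_vertex_pls(x[tr, , , drop = FALSE], y[tr])
    reduced <- predict(pls, x)
  } else {
    reduced <- x[, , "thickness", drop = TRUE]
  }
  defined <- colSums(is.na(reduced)) == 0
  keep <- which(defined)
  if (is.finite(top_k) && top_k < length(keep)) {
    st <- vertex_ttest(reduced[tr & y == 1, keep, drop = FALSE],
                       reduced[tr & y == 0, keep, drop = FALSE])
    keep <- keep[order(-abs(st$d))[seq_len(top_k)]]
    keep <- sort(keep)
  }
  feat <- reduced[, keep, drop = FALSE]

  pool <- which(tr | va)
  ens <- select_ensemble(feat[pool, , drop = FALSE], y[pool],
                         refit_idx = if (config$refit_train_val) seq_along(pool)
                                     else which(tr[pool]),
                         families = config$models,
                         seed = derive_seed(config$seed, "ensemble"),
                         n_init = config$n_init, n_folds = config$n_folds,
                         params = params)
  pv <- predict(ens, feat[va, , drop = FALSE])
  thr <- as.numeric(choose_threshold(pv, y[va]))
  structure(list(pls = pls, ensemble = ens, threshold = thr,
                 feature = feature, vertices_used = keep,
                 positive = positive, config = config,
                 split = split, labels_train = y[tr],
                 val_auroc = auroc(pv, y[va]),
                 fitted_on = object_hash(list(which(tr), which(va)))),
            class = "mssm_model")
}

#' @export
print.mssm_model <- function(x, ...) {
  cat(sprintf("mssm_model (%s features): ensemble of %s\n", x$feature,
              paste(x$ensemble$member_families, collapse = " + ")))
  cat(sprintf("  %d vertex inputs, validation AUROC %.3f, threshold %.3f\n",
              length(x$vertices_used), x$val_auroc, x$threshold))
  invisible(x)
}

#' @export
summary.mssm_model <- function(object, ...) {
  cat("Multiscale structural mapping classifier\n")
  print(object)
  cat("\nFamily ranking (mean validation AUROC over 5 inits x 4 folds):\n")
  print(object$ensemble$ranking, row.names = FALSE)
  invisible(object)
}

#' Predict class-1 probabilities for new subjects
#'
#' Applies the fitted PLS reduction (training normalization bounds; no
#' refitting) and the fitted ensemble.
#'
#' @param object an `mssm_model`.
#' @param x subjects x vertices x features array on the same mesh and feature
#'   set the model was trained on.
#' @param ... unused.
#' @return numeric vector of disease-class probabilities.
#' @export
predict.mssm_model <- function(object, x, ...) {
  reduced <- if (object$feature == "mssm") predict(object$pls, x)
             else x[, , "thickness", drop = TRUE]
  feat <- reduced[, object$vertices_used, drop = FALSE]
  if (anyNA(feat)) stop("undefined vertex values in prediction input")
  predict(object$ensemble, feat)
}

#' Evaluate a fitted model on a subject set
#'
#' @param model an `mssm_model`.
#' @param x feature array for the subjects to evaluate.
#' @param labels their binary labels.
#' @param threshold decision threshold; default the model's validation-chosen
#'   threshold.
#' @return an `eval_report`.
#' @export
mssm_evaluate <- function(model, x, labels, threshold = model$threshold) {
  probs <- predict(model, x)
  eval_report(probs, encode_labels(labels, positive = model$positive),
              threshold = threshold)
}

#' Apply a trained model to a second cohort without retraining
#'
#' Transfer evaluation: the PLS normalization bounds, ensemble members and
#' decision threshold fitted on the first cohort are applied unchanged to a
#' second cohort (e.g. an AD/CN-trained model distinguishing MCI converters
#' from non-converters).
#'
#' @param model an `mssm_model` trained on cohort 1.
#' @param x feature array for cohort 2 (same mesh and features).
#' @param labels cohort-2 binary labels.
#' @param positive label of the cohort-2 class mapped to the disease class
#'   (default: first sorted label, e.g. "MCI-C").
#' @return an `eval_report`.
#' @export
transfer_predict <- function(model, x, labels, positive = NULL) {
  y <- encode_labels(labels, positive = positive)
  eval_report(predict(model, x), y, threshold = model$threshold)
}
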