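#' Stratified train/validation/test split
#'
#' Each subject receives a uniform draw derived deterministically from
#' `(seed, subject_id)`; within each label stratum subjects are ranked by
#' their draw and cut at the cumulative fractions (ceiling boundaries). The
#' test block is therefore assigned at the very beginning, before any
#' preprocessing sees the data, and a subject's draw never depends on who
#' else is in the cohort.
#'
#' @param cohort a cohort table (or any data frame with `subject_id`, `label`).
#' @param fractions train/val/test fractions summing to 1.
#' @param seed integer seed.
#' @return the cohort with a `split` column (train/val/test).
#' @export
make_splits <- function(cohort, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  u <- vapply(cohort$subject_id, function(id)
    with_seed(derive_seed(seed, "split", id), stats::runif(1)), numeric(1))
  split <- character(nrow(cohort))
  for (lab in unique(cohort$label)) {
    idx <- which(cohort$label == lab)
    n <- length(idx)
    b1 <- ceiling(fractions[1] * n)
    b2 <- ceiling((fractions[1] + fractions[2]) * n)
    r <- rank(u[idx], ties.method = "first")
    split[idx] <- c("train", "val", "test")[1L + (r > b1) + (r > b2)]
  }
  cohort$split <- split
  cohort
}

#' Inverse-prevalence class weights
#'
#' `w_c = n_total / (K * n_c)` for each of the `K` classes, so each class
#' contributes equally in total; balanced labels give all weights 1.
#'
#' @param labels class labels.
#' @return named numeric weights, one per class.
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L) stop("class weights need at least two classes")
  w <- as.numeric(sum(tab) / (length(tab) * tab))
  names(w) <- names(tab)
  w
}

# ---- metrics ---------------------------------------------------------------

#' ROC curve points
#'
#' @param scores classifier scores (higher = more positive).
#' @param labels binary labels (1 = positive).
#' @return data frame with `threshold`, `fpr`, `tpr`, starting at (0, 0) and
#'   ending at (1, 1).
#' @export
roc_points <- function(scores, labels) {
  y <- encode_labels(labels)
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) stop("need both classes for a ROC curve")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == 0)
  last <- !duplicated(rev(ss))            # keep the last row of each tie block
  keep <- rev(last)
  data.frame(threshold = c(Inf, ss[keep]),
             fpr = c(0, fp[keep] / nn),
             tpr = c(0, tp[keep] / np))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Equals the probability that a random positive outscores a random negative,
#' counting ties as one half.
#'
#' @inheritParams roc_points
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Precision-recall curve points
#'
#' @inheritParams roc_points
#' @return data frame with `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(scores, labels) {
  y <- encode_labels(labels)
  np <- sum(y == 1)
  if (np == 0) stop("need positives for a PR curve")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys == 1)
  pred_pos <- seq_along(ys)
  keep <- rev(!duplicated(rev(ss)))
  data.frame(threshold = ss[keep],
             recall = tp[keep] / np,
             precision = tp[keep] / pred_pos[keep])
}

#' Area under the precision-recall curve (step-wise)
#'
#' Non-interpolated step integration: the sum over descending thresholds of
#' the recall increment times the precision at that threshold (avoids the
#' optimistic trapezoid bias).
#'
#' @inheritParams roc_points
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  pts <- pr_points(scores, labels)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' Decision threshold minimizing total misclassification
#'
#' Exhaustive scan over midpoints of adjacent sorted unique scores (plus
#' sentinels below and above all scores); predicts positive when
#' `score >= threshold` and minimizes FP + FN. Ties pick the lowest
#' threshold, favouring sensitivity.
#'
#' @inheritParams roc_points
#' @return the chosen threshold; attribute `"errors"` is its FP + FN count.
#' @export
choose_threshold <- function(scores, labels) {
  y <- encode_labels(labels)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (utils::head(s, -1) + utils::tail(s, -1)) / 2,
            s[length(s)] + 1)
  errs <- vapply(cand, function(th) {
    pred <- as.integer(scores >= th)
    sum(pred == 1 & y == 0) + sum(pred == 0 & y == 1)
  }, numeric(1))
  best <- which.min(errs)   # which.min returns the first (lowest) minimizer
  structure(cand[best], errors = errs[best])
}

#' Classifier evaluation report
#'
#' All five headline metrics plus the ROC and PR curves at the chosen
#' threshold.
#'
#' @param probs class-1 probabilities (or calibrated scores).
#' @param labels binary labels (1 / positive-class label).
#' @param threshold decision threshold; defaults to the error-minimizing
#'   threshold on these data (normally the threshold is chosen on the
#'   validation set and passed in).
#' @return list of class `eval_report`: `auroc`, `auprc`, `accuracy`,
#'   `sensitivity`, `specificity`, `threshold`, `roc`, `pr`, `n`.
#' @export
eval_report <- function(probs, labels, threshold = NULL) {
  y <- encode_labels(labels)
  if (is.null(threshold)) threshold <- as.numeric(choose_threshold(probs, y))
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(list(auroc = auroc(probs, y),
                 auprc = auprc(probs, y),
                 accuracy = (tp + tn) / length(y),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 threshold = as.numeric(threshold),
                 roc = roc_points(probs, y),
                 pr = pr_points(probs, y),
                 n = length(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("eval_report (n=%d): AUROC %.3f | AUPRC %.3f | ",
                     "accuracy %.3f | sensitivity %.3f | specificity %.3f ",
                     "(threshold %.3g)\n"),
              x$n, x$auroc, x$auprc, x$accuracy, x$sensitivity,
              x$specificity, x$threshold))
  invisible(x)
}

#' Plot ROC and PR curves of an evaluation report
#'
#' @param x an `eval_report`.
#' @param ... passed to `plot`.
#' @export
plot.eval_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUROC %.3f)", x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  plot(x$pr$recall, x$pr$precision, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Recall", ylab = "Precision",
       main = sprintf("PR (AUPRC %.3f)", x$auprc), ...)
  invisible(x)
}

# ---- model zoo -------------------------------------------------------------

platt_calibrate <- function(dv, y, case_w) {
  df <- data.frame(dv = as.numeric(dv), y = y)
  fit <- suppressWarnings(stats::glm(y ~ dv, data = df,
                                     family = stats::quasibinomial(),
                                     weights = case_w))
  fit$coefficients
}

platt_prob <- function(coefs, dv) {
  eta <- coefs[1] + coefs[2] * as.numeric(dv)
  1 / (1 + exp(-pmin(500, pmax(-500, eta))))
}

svm_family <- function(kernel) {
  list(
    fit = function(x, y, class_w, case_w, seed, params) {
      fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = kernel,
                        cost = params$svm_cost %||% 1,
                        gamma = params$svm_gamma %||% (1 / ncol(x)),
                        degree = params$svm_degree %||% 3,
                        class.weights = stats::setNames(class_w, c("0", "1")),
                        scale = FALSE)
      dv <- attr(stats::predict(fit, x, decision.values = TRUE),
                 "decision.values")
      list(fit = fit, platt = platt_calibrate(dv, y, case_w))
    },
    predict = function(model, x) {
      dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
                 "decision.values")
      platt_prob(model$platt, dv)
    })
}

model_zoo_impl <- function() {
  list(
    "svm_linear" = svm_family("linear"),
    "svm_sigmoid" = svm_family("sigmoid"),
    "svm_polynomial" = svm_family("polynomial"),
    "svm_rbf" = svm_family("radial"),
    "neural_network" = list(
      fit = function(x, y, class_w, case_w, seed, params) {
        with_seed(seed,
          nnet::nnet(x, y, size = params$nn_size %||% 2,
                     decay = params$nn_decay %||% 0.01,
                     maxit = params$nn_maxit %||% 60,
                     weights = case_w, entropy = TRUE, trace = FALSE,
                     MaxNWts = 100000))
      },
      predict = function(model, x) as.numeric(stats::predict(model, x))),
    "random_forest" = list(
      fit = function(x, y, class_w, case_w, seed, params) {
        with_seed(seed,
          randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                     ntree = params$rf_ntree %||% 300,
                                     classwt = class_w))
      },
      predict = function(model, x)
        as.numeric(stats::predict(model, x, type = "prob")[, "1"])),
    "logistic_regression" = list(
      fit = function(x, y, class_w, case_w, seed, params) {
        if (ncol(x) >= 2L) {
          lam <- params$logit_lambda %||% 0.1
          fit <- glmnet::glmnet(x, factor(y, levels = c(0, 1)),
                                family = "binomial", alpha = 0,
                                lambda = c(10 * lam, lam), weights = case_w,
                                standardize = FALSE)
          list(kind = "glmnet", fit = fit, lambda = lam)
        } else {
          df <- data.frame(x1 = x[, 1], y = y)
          list(kind = "glm",
               fit = suppressWarnings(stats::glm(y ~ x1, data = df,
                                                 family = stats::quasibinomial(),
                                                 weights = case_w)))
        }
      },
      predict = function(model, x) {
        if (model$kind == "glmnet")
          as.numeric(stats::predict(model$fit, x, s = model$lambda,
                                    type = "response"))
        else
          as.numeric(stats::predict(model$fit,
                                    newdata = data.frame(x1 = x[, 1]),
                                    type = "response"))
      }),
    "knn" = list(
      fit = function(x, y, class_w, case_w, seed, params) {
        list(x = x, y = y, k = params$knn_k %||% 5, seed = seed)
      },
      predict = function(model, x) {
        pred <- with_seed(model$seed,
          class::knn(model$x, x, factor(model$y, levels = c(0, 1)),
                     k = model$k, prob = TRUE))
        pw <- attr(pred, "prob")
        ifelse(pred == "1", pw, 1 - pw)
      }),
    "gaussian_process" = list(
      fit = function(x, y, class_w, case_w, seed, params) {
        with_seed(seed,
          kernlab::gausspr(x, factor(y, levels = c(0, 1)),
                           kernel = "rbfdot",
                           kpar = list(sigma = params$gp_sigma %||% (1 / ncol(x))),
                           scaled = FALSE))
      },
      predict = function(model, x)
        as.numeric(kernlab::predict(model, x, type = "probabilities")[, "1"]))
  )
}

#' Classifier families considered by the ensemble
#'
#' Nine families: four SVM kernels (linear, sigmoid, polynomial, RBF), a
#' small feed-forward neural network, a random forest, ridge-penalized
#' logistic regression, k-nearest neighbours and a Gaussian-process
#' classifier. Every family outputs a class-1 probability (SVMs through a
#' weighted Platt calibration of their decision values). Class imbalance is
#' handled by inverse-prevalence weights: per-sample loss weights for
#' loss-based learners, split-criterion reweighting for the forest; kNN has
#' no weighting mechanism and is left unweighted.
#'
#' @return named list of family definitions (fit/predict function pairs).
#' @export
model_zoo <- function() model_zoo_impl()

`%||%` <- function(a, b) if (is.null(a)) b else a

stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2, std$mu, "-"), 2, std$sd, "/")
}

# ---- ensemble selection ----------------------------------------------------

#' Select and fit the top-3 ensemble
#'
#' For every candidate family, 5 random initializations x 4 stratified
#' cross-validation folds over the train+validation pool yield 20 validation
#' AUROCs; families are ranked by their mean, the top 3 are refit (on the
#' training split by default) and ensembled by averaging their class-1
#' probabilities. Deterministic families reuse the same fit across
#' initializations; their 5 "initializations" differ only through the fold
#' shuffling. Families that fail to produce probabilities are excluded with a
#' logged reason; fewer than 3 survivors is an error.
#'
#' @param x subjects x features numeric matrix (train+validation pool).
#' @param y binary labels for the pool (1 = positive class).
#' @param refit_idx row indices of `x` used for the final refit (default all).
#' @param families subset of [model_zoo()] names to consider (>= 3).
#' @param seed integer seed.
#' @param n_init random initializations per family.
#' @param n_folds cross-validation folds.
#' @param params named list of family hyperparameters (see [model_zoo()]).
#' @return object of class `mssm_ensemble`: fitted members, the per-family
#'   mean validation AUROC table, and the standardization fitted on the refit
#'   rows.
#' @export
select_ensemble <- function(x, y, refit_idx = seq_len(nrow(x)),
                            families = names(model_zoo()), seed = 1L,
                            n_init = 5L, n_folds = 4L, params = list()) {
  if (length(families) < 3L) stop("need at least 3 candidate families")
  zoo <- model_zoo()
  if (!all(families %in% names(zoo)))
    stop("unknown families: ",
         paste(setdiff(families, names(zoo)), collapse = ", "))
  y <- encode_labels(y)
  cw <- class_weights(y)                       # names "0", "1"
  cv_auc <- matrix(NA_real_, length(families), n_init * n_folds,
                   dimnames = list(families, NULL))
  failed <- character(0)
  for (init in seq_len(n_init)) {
    fold <- stratified_folds(y, n_folds, derive_seed(seed, "fold", init))
    for (k in seq_len(n_folds)) {
      tr <- fold != k; te <- fold == k
      std <- standardizer(x[tr, , drop = FALSE])
      xtr <- apply_standardizer(std, x[tr, , drop = FALSE])
      xte <- apply_standardizer(std, x[te, , drop = FALSE])
      ytr <- y[tr]
      case_w <- cw[as.character(ytr)]
      for (fam in setdiff(families, failed)) {
        res <- tryCatch({
          m <- zoo[[fam]]$fit(xtr, ytr, cw, case_w,
                              derive_seed(seed, "init", init, "fold", k, fam),
                              params)
          p <- zoo[[fam]]$predict(m, xte)
          if (any(!is.finite(p))) stop("non-finite probabilities")
          auroc(p, y[te])
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failed <- c(failed, fam)
          message(sprintf("family %s excluded: %s", fam, conditionMessage(res)))
        } else {
          cv_auc[fam, (init - 1L) * n_folds + k] <- res
        }
      }
    }
  }
  ok <- setdiff(families, failed)
  if (length(ok) < 3L)
    stop("fewer than 3 families produced probabilities in cross-validation")
  mean_auc <- rowMeans(cv_auc[ok, , drop = FALSE])
  ranking <- data.frame(family = ok, mean_val_auroc = mean_auc,
                        row.names = NULL)
  ranking <- ranking[order(-ranking$mean_val_auroc, ranking$family), ]
  top <- ranking$family[1:3]
  std <- standardizer(x[refit_idx, , drop = FALSE])
  xr <- apply_standardizer(std, x[refit_idx, , drop = FALSE])
  yr <- y[refit_idx]
  cwr <- class_weights(yr)
  members <- lapply(top, function(fam)
    zoo[[fam]]$fit(xr, yr, cwr, cwr[as.character(yr)],
                   derive_seed(seed, "final", fam), params))
  names(members) <- top
  structure(list(members = members, member_families = top,
                 ranking = ranking, cv_auc = cv_auc, standardizer = std,
                 seed = seed, params = params),
            class = "mssm_ensemble")
}

#' Ensemble class-1 probabilities (mean of the three members)
#'
#' @param object an `mssm_ensemble`.
#' @param x subjects x features matrix on the same feature space the ensemble
#'   was fitted on.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.mssm_ensemble <- function(object, x, ...) {
  zoo <- model_zoo()
  xs <- apply_standardizer(object$standardizer, x)
  probs <- vapply(seq_along(object$member_families), function(i)
    as.numeric(zoo[[object$member_families[i]]]$predict(object$members[[i]],
                                                        xs)),
    numeric(nrow(x)))
  rowMeans(matrix(probs, nrow = nrow(x)))
}

#' @export
print.mssm_ensemble <- function(x, ...) {
  cat("mssm_ensemble: top-3 of", nrow(x$ranking), "families\n")
  print(utils::head(x$ranking, 5), row.names = FALSE)
  invisible(x)
}

#' Scalar-feature baseline classifier
#'
#' Runs the identical ensemble machinery on a single scalar column (e.g.
#' hippocampal volume normalized by eTIV, a cognitive score, or mean
#' thickness), for like-for-like comparison with the vertex-wise models.
#'
#' @param values numeric vector, one scalar per subject.
#' @param labels binary labels.
#' @param split character vector of train/val/test assignments
#'   ([make_splits()]).
#' @param seed integer seed.
#' @param families,params passed to [select_ensemble()].
#' @return list: `ensemble`, `threshold` (chosen on validation), `report`
#'   (test-set `eval_report`).
#' @export
scalar_baseline <- function(values, labels, split, seed = 1L,
                            families = names(model_zoo()), params = list()) {
  x <- matrix(as.numeric(values), ncol = 1L)
  y <- encode_labels(labels)
  pool <- split %in% c("train", "val")
  ens <- select_ensemble(x[pool, , drop = FALSE], y[pool],
                         refit_idx = which(split[pool] == "train"),
                         families = families, seed = seed, params = params)
  pv <- predict(ens, x[split == "val", , drop = FALSE])
  thr <- as.numeric(choose_threshold(pv, y[split == "val"]))
  pt <- predict(ens, x[split == "test", , drop = FALSE])
  list(ensemble = ens, threshold = thr,
       report = eval_report(pt, y[split == "test"], threshold = thr))
}
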