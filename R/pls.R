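#' Stack per-subject feature matrices into a subjects x vertices x features array
#'
#' @param features named list of `feature_stack` matrices (vertex x feature),
#'   one per subject, identical dimensions and column names.
#' @return 3-D array with dimnames (subject, NULL, feature).
#' @export
stack_features <- function(features) {
  d <- dim(features[[1]])
  nm <- colnames(features[[1]])
  for (f in features) {
    if (!all(dim(f) == d)) stop("all subjects must share feature dimensions")
    if (!identical(colnames(f), nm)) stop("feature names differ across subjects")
  }
  arr <- array(NA_real_, c(length(features), d[1], d[2]),
               dimnames = list(names(features), NULL, nm))
  for (i in seq_along(features)) arr[i, , ] <- unclass(features[[i]])
  arr
}

#' Vertex-wise single-component PLS reduction
#'
#' At each vertex the 9 features (thickness + 8 contrast ratios) are reduced
#' to one component by PLS1 regression against the binary diagnosis label:
#' each feature is min-max normalized to `[0, 1]` over the *training*
#' subjects, features and label are centred, and the first-component weight
#' vector is the normalized covariance `w = X'y / ||X'y||`. The sign is fixed
#' so that the component correlates non-negatively with the label in
#' training, making vertex maps comparable across vertices.
#'
#' Zero-variance features get weight 0 before normalization; vertices with an
#' all-zero covariance (or any undefined training value) are flagged
#' undefined.
#'
#' @param x subjects x vertices x features array ([stack_features()]) of
#'   training subjects only.
#' @param labels binary vector (0/1, logical, or 2-level factor), length
#'   `dim(x)[1]`; 1 is the disease class.
#' @return object of class `mssm_pls`: per-vertex normalization bounds,
#'   centring constants, unit weight vectors, defined-vertex mask, and a hash
#'   of the training subject IDs.
#' @export
fit_vertex_pls <- function(x, labels) {
  y <- encode_labels(labels)
  if (length(y) != dim(x)[1]) stop("labels length must match subject count")
  if (min(table(y)) < 2L) stop("need >= 2 training subjects per class")
  ns <- dim(x)[1]; nv <- dim(x)[2]; nf <- dim(x)[3]
  fmin <- matrix(NA_real_, nv, nf)
  fmax <- matrix(NA_real_, nv, nf)
  xbar <- matrix(NA_real_, nv, nf)   # mean of normalized features
  w <- matrix(0, nv, nf)
  yc <- y - mean(y)
  defined <- rep(TRUE, nv)
  for (j in seq_len(nf)) {
    m <- x[, , j, drop = TRUE]                       # subjects x vertices
    if (is.null(dim(m))) m <- matrix(m, nrow = ns)
    bad <- colSums(is.na(m)) > 0
    defined <- defined & !bad
    lo <- suppressWarnings(apply(m, 2, min))
    hi <- suppressWarnings(apply(m, 2, max))
    fmin[, j] <- lo; fmax[, j] <- hi
    rng <- hi - lo
    zero <- !is.finite(rng) | rng == 0
    nmz <- sweep(m, 2, lo, "-")
    nmz <- sweep(nmz, 2, ifelse(zero, 1, rng), "/")
    nmz[, zero] <- 0
    mu <- colMeans(nmz)
    xbar[, j] <- mu
    xc <- sweep(nmz, 2, mu, "-")
    w[, j] <- as.numeric(crossprod(xc, yc))          # covariance direction
    w[zero, j] <- 0
  }
  nrm <- sqrt(rowSums(w^2))
  defined <- defined & nrm > 0
  nrm[nrm == 0] <- 1
  w <- w / nrm
  w[!defined, ] <- NA_real_
  fit <- structure(list(feature_names = dimnames(x)[[3]],
                        fmin = fmin, fmax = fmax, xbar = xbar, w = w,
                        defined = defined,
                        y_mean = mean(y),
                        fitted_on = object_hash(dimnames(x)[[1]])),
                   class = "mssm_pls")
  # enforce the sign convention on the training scores themselves
  sc <- predict(fit, x)
  r <- suppressWarnings(stats::cor(sc, y))
  flip <- !is.na(r) & r < 0
  fit$w[flip, ] <- -fit$w[flip, ]
  fit
}

#' @export
print.mssm_pls <- function(x, ...) {
  cat(sprintf("mssm_pls: %d vertices (%d defined), %d features [%s]\n",
              nrow(x$w), sum(x$defined), ncol(x$w),
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Apply a fitted vertex-wise PLS reduction
#'
#' Normalizes with the *training* min/max (new subjects may fall outside
#' `[0, 1]`; values are not clipped), centres with the training means and
#' projects on the per-vertex weight vector, yielding one reduced value per
#' vertex per subject.
#'
#' @param object an `mssm_pls`.
#' @param x subjects x vertices x features array; feature names must match
#'   the fitted model.
#' @param ... unused.
#' @return subjects x vertices matrix of reduced values (`NA` at undefined
#'   vertices).
#' @export
predict.mssm_pls <- function(object, x, ...) {
  if (length(dim(x)) != 3L) stop("x must be a subjects x vertices x features array")
  if (dim(x)[3] != ncol(object$w))
    stop(sprintf("feature count mismatch: model fitted on %d features, got %d",
                 ncol(object$w), dim(x)[3]))
  if (!is.null(dimnames(x)[[3]]) &&
      !identical(dimnames(x)[[3]], object$feature_names))
    stop("feature names do not match the fitted model")
  ns <- dim(x)[1]; nv <- dim(x)[2]; nf <- dim(x)[3]
  if (nv != nrow(object$w)) stop("vertex count mismatch with the fitted model")
  out <- matrix(0, ns, nv)
  for (j in seq_len(nf)) {
    m <- x[, , j, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = ns)
    rng <- object$fmax[, j] - object$fmin[, j]
    zero <- !is.finite(rng) | rng == 0
    nmz <- sweep(m, 2, object$fmin[, j], "-")
    nmz <- sweep(nmz, 2, ifelse(zero, 1, rng), "/")
    nmz[, zero] <- 0
    xc <- sweep(nmz, 2, object$xbar[, j], "-")
    out <- out + sweep(xc, 2, object$w[, j], "*")
  }
  out[, !object$defined] <- NA_real_
  dimnames(out) <- list(dimnames(x)[[1]], NULL)
  out
}

encode_labels <- function(labels, positive = NULL) {
  if (!is.null(positive)) return(as.integer(labels == positive))
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) != 2L) stop("labels must be binary")
    as.integer(droplevels(labels)) - 1L
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else if (is.character(labels)) {
    u <- sort(unique(labels))
    if (length(u) != 2L) stop("labels must be binary")
    # disease classes conventionally first alphabetically (AD < CN,
    # MCI-C < MCI-NC): treat the *first* level as the positive class
    as.integer(labels == u[1])
  } else {
    u <- sort(unique(labels))
    if (length(u) != 2L) stop("labels must be binary")
    as.integer(labels == u[2])
  }
}
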