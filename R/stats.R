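#' Vertex-wise two-sample t contrast
#'
#' Pooled-variance two-sample t-test at every vertex, two-sided p-values and
#' Cohen's d (mean difference over pooled SD). Vertices with zero pooled
#' variance or undefined values are returned as `NA`.
#'
#' @param group_a,group_b subjects x vertices matrices of per-vertex values
#'   (e.g. reduced MSSM maps or thickness maps); >= 2 rows each.
#' @param fdr_q FDR level for the significance mask.
#' @param covariates optional numeric matrix or data frame of nuisance
#'   covariates, rows `rbind(group_a, group_b)`; when given, every vertex is
#'   residualized on the covariates (pooled across groups, no group term)
#'   before the contrast — the covariate-adjusted alternative to relying on a
#'   matched cohort. Degrees of freedom are reduced accordingly.
#' @return list of class `stat_map`: `t`, `p`, `d`, `significant` (BH-FDR
#'   mask at `fdr_q`), `df`, `fdr_q`, `n_defined`.
#' @export
vertex_ttest <- function(group_a, group_b, fdr_q = 0.05, covariates = NULL) {
  na <- nrow(group_a); nb <- nrow(group_b)
  if (na < 2L || nb < 2L) stop("need >= 2 subjects per group")
  if (ncol(group_a) != ncol(group_b)) stop("vertex counts differ between groups")
  df_adjust <- 0L
  if (!is.null(covariates)) {
    Z <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    if (nrow(Z) != na + nb)
      stop("covariates must have one row per subject of both groups")
    both <- rbind(group_a, group_b)
    fitted <- Z %*% solve(crossprod(Z), crossprod(Z, both))
    resid <- both - fitted
    group_a <- resid[seq_len(na), , drop = FALSE]
    group_b <- resid[na + seq_len(nb), , drop = FALSE]
    df_adjust <- ncol(Z) - 1L
  }
  ma <- colMeans(group_a); mb <- colMeans(group_b)
  va <- apply(group_a, 2, stats::var)
  vb <- apply(group_b, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  sp <- sqrt(sp2)
  bad <- !is.finite(sp) | sp == 0
  tt <- (ma - mb) / (sp * sqrt(1 / na + 1 / nb))
  d <- (ma - mb) / sp
  tt[bad] <- NA; d[bad] <- NA
  df <- na + nb - 2L - df_adjust
  p <- 2 * stats::pt(-abs(tt), df = df)
  structure(list(t = tt, p = p, d = d,
                 significant = bh_fdr(p, fdr_q),
                 df = df, fdr_q = fdr_q,
                 n_defined = sum(!bad)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map: %d vertices (%d defined), df=%d, %.1f%% significant at q=%g\n",
              length(x$t), x$n_defined, x$df, percent_significant(x), x$fdr_q))
  invisible(x)
}

#' Benjamini-Hochberg step-up significance mask
#'
#' One FDR family over all defined vertices (both hemispheres pooled).
#' `NA` p-values are never significant.
#'
#' @param pvals p-values in `[0, 1]` (`NA` allowed).
#' @param q FDR level.
#' @return logical mask, same length as `pvals`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  out <- rep(FALSE, length(pvals))
  ok <- !is.na(pvals)
  if (!any(ok)) return(out)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must be in [0, 1]")
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH") <= q
  out
}

#' Percentage of defined vertices significant
#'
#' @param stat a `stat_map`.
#' @return percentage in `[0, 100]` of defined vertices in the significance
#'   mask.
#' @export
percent_significant <- function(stat) {
  def <- !is.na(stat$p)
  if (!any(def)) return(0)
  100 * sum(stat$significant[def]) / sum(def)
}

#' Effect-size comparison of two statistical maps
#'
#' Per-vertex difference of Cohen's d magnitudes between two contrasts of the
#' same cohort (e.g. the multiscale map vs thickness alone) and the mask of
#' vertices where the first is the stronger effect.
#'
#' @param stat_a,stat_b `stat_map`s over the same vertices.
#' @return list: `d_diff` (= d_a - d_b), `abs_d_diff` (= |d_a| - |d_b|),
#'   `a_stronger` (logical, |d_a| > |d_b|).
#' @export
effect_size_comparison <- function(stat_a, stat_b) {
  if (length(stat_a$d) != length(stat_b$d)) stop("vertex counts differ")
  list(d_diff = stat_a$d - stat_b$d,
       abs_d_diff = abs(stat_a$d) - abs(stat_b$d),
       a_stronger = abs(stat_a$d) > abs(stat_b$d))
}

#' Correlation of the "extra-region" signal with a cognitive score
#'
#' The extra region is the set of vertices significant in the multiscale map
#' but not in thickness. Per subject, `y` is the mean reduced value over the
#' extra region, `x_all` the mean thickness over the whole cortex, and
#' `x_sig` the mean thickness over thickness-significant vertices. Pearson
#' and Spearman correlations of `y` with the score are reported raw and
#' partialled on `x_all` or `x_sig` (partial correlation by residualizing
#' both variables on the control; Spearman partials operate on ranks first).
#'
#' @param mssm_values subjects x vertices matrix of reduced multiscale values.
#' @param ct_values subjects x vertices matrix of thickness values.
#' @param mssm_sig,ct_sig logical significance masks (e.g. from
#'   [vertex_ttest()] on the analysis cohort).
#' @param score numeric cognitive score per subject (e.g. FAQ).
#' @return list of class `extra_region_analysis`: `extra_mask`, `n_extra`,
#'   per-subject `y`, `x_all`, `x_sig`, and a `correlations` data frame with
#'   columns control / pearson / spearman / p_pearson / p_spearman. If the
#'   extra region is empty, `empty = TRUE` with no correlations.
#' @export
extra_region_correlation <- function(mssm_values, ct_values, mssm_sig, ct_sig,
                                     score) {
  extra <- mssm_sig & !ct_sig
  stopifnot(length(extra) == ncol(mssm_values))
  if (!any(extra)) {
    return(structure(list(empty = TRUE, extra_mask = extra, n_extra = 0L),
                     class = "extra_region_analysis"))
  }
  y <- rowMeans(mssm_values[, extra, drop = FALSE])
  x_all <- rowMeans(ct_values)
  x_sig <- if (any(ct_sig)) rowMeans(ct_values[, ct_sig, drop = FALSE])
           else rep(NA_real_, nrow(ct_values))
  one <- function(control_name, control) {
    if (is.null(control)) {
      pe <- stats::cor.test(y, score, method = "pearson")
      sp <- suppressWarnings(stats::cor.test(y, score, method = "spearman"))
      data.frame(control = control_name, pearson = unname(pe$estimate),
                 spearman = unname(sp$estimate),
                 p_pearson = pe$p.value, p_spearman = sp$p.value)
    } else if (all(is.na(control))) {
      data.frame(control = control_name, pearson = NA_real_,
                 spearman = NA_real_, p_pearson = NA_real_,
                 p_spearman = NA_real_)
    } else {
      data.frame(control = control_name,
                 pearson = partial_cor(y, score, control, ranked = FALSE),
                 spearman = partial_cor(y, score, control, ranked = TRUE),
                 p_pearson = NA_real_, p_spearman = NA_real_)
    }
  }
  correlations <- rbind(one("none", NULL), one("x_all", x_all),
                        one("x_sig", x_sig))
  structure(list(empty = FALSE, extra_mask = extra, n_extra = sum(extra),
                 y = y, x_all = x_all, x_sig = x_sig,
                 correlations = correlations),
            class = "extra_region_analysis")
}

#' Partial correlation controlling for one variable
#'
#' Residualizes both `a` and `b` on `control` with least squares and
#' correlates the residuals (equivalent to the recursive partial-correlation
#' formula for a single control). With `ranked = TRUE` all three variables
#' are rank-transformed first (Spearman partial).
#'
#' @param a,b vectors of equal length.
#' @param control control variable.
#' @param ranked operate on ranks.
#' @return partial correlation coefficient.
#' @export
partial_cor <- function(a, b, control, ranked = FALSE) {
  if (ranked) {
    a <- rank(a); b <- rank(b); control <- rank(control)
  }
  ra <- stats::residuals(stats::lm(a ~ control))
  rb <- stats::residuals(stats::lm(b ~ control))
  stats::cor(ra, rb)
}

#' @export
print.extra_region_analysis <- function(x, ...) {
  if (x$empty) {
    cat("extra_region_analysis: empty extra region (no vertices significant in MSSM only)\n")
  } else {
    cat(sprintf("extra_region_analysis: %d extra-region vertices\n", x$n_extra))
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}
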