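#' Run the complete synthetic phantom study in memory
#'
#' The package's reference experiment, mirroring the real-data analysis on
#' synthetic cortical phantoms: an affected/control cohort is generated,
#' multiscale features are sampled and smoothed, vertex-wise group statistics
#' compare the PLS-reduced multiscale map against thickness alone, the
#' classifier is trained on a 60/20/20 split and evaluated on the held-out
#' test subjects, scalar baselines run through the identical ensemble
#' machinery, and (optionally) the trained model transfers without refitting
#' to a second cohort with intermediate effect sizes.
#'
#' The default problem size — icosphere level 3 (642 vertices), 30 mm white
#' radius, 40 affected / 40 control subjects — is the package's desk-scale
#' study condition; all intensity, noise, bias and effect parameters are the
#' generator defaults.
#'
#' @param seed integer seed; every random choice derives from it.
#' @param phantom a [phantom_config()]; default the desk-scale geometry.
#' @param effect an [effect_spec()]; default [ad_effect()] on the phantom
#'   mesh (thinning cap inside a wider contrast-loss cap).
#' @param n_affected,n_control cohort group sizes.
#' @param config an [mssm_config()]; its seed is overridden by `seed`.
#' @param what components to run: any of `"stats"`, `"classify"`,
#'   `"transfer"`, `"baselines"`.
#' @param baseline_features which scalar baselines to run when `"baselines"`
#'   is requested: any of `"hippocampus"`, `"noise"`.
#' @param transfer_scale multiplier applied to both effect deltas for the
#'   transfer ("MCI-like") cohort (default one half).
#' @param n_transfer per-group size of the transfer cohort.
#' @return list of class `mssm_study` with (depending on `what`):
#'   `cohort`, `splits`, `stat_mssm`, `stat_ct`, `effect_cmp`, `extra`,
#'   `model_mssm`, `model_ct`, `report_mssm`, `report_ct`,
#'   `report_hippocampus`, `report_noise`, `report_transfer`.
#' @export
run_study <- function(seed,
                      phantom = phantom_config(subdivisions = 3L,
                                               base_radius_mm = 30),
                      effect = NULL,
                      n_affected = 40L, n_control = 40L,
                      config = mssm_config(),
                      what = c("stats", "classify", "transfer", "baselines"),
                      baseline_features = c("hippocampus", "noise"),
                      transfer_scale = 0.5, n_transfer = 40L) {
  config$seed <- as.integer(seed)
  mesh <- phantom_mesh(phantom)
  if (is.null(effect)) effect <- ad_effect(mesh)
  cohort <- make_cohort(phantom, effect, n_affected, n_control,
                        seed = derive_seed(seed, "adcn"))
  x <- cohort_features(cohort, config)
  splits <- make_splits(cohort$cohort, config$split_fractions,
                        seed = derive_seed(seed, "split"))
  out <- list(seed = seed, cohort = splits, effect = effect,
              features = x)
  ad <- splits$label == "AD"

  if ("stats" %in% what) {
    # group-analysis mode: the reduction is fitted on the full cohort, as in
    # a vertex-wise group contrast (no held-out inference is made from it)
    pls_all <- fit_vertex_pls(x, encode_labels(splits$label, positive = "AD"))
    red <- predict(pls_all, x)
    th <- x[, , "thickness", drop = TRUE]
    out$reduced <- red
    out$stat_mssm <- vertex_ttest(red[ad, , drop = FALSE],
                                  red[!ad, , drop = FALSE], config$fdr_q)
    out$stat_ct <- vertex_ttest(th[ad, , drop = FALSE],
                                th[!ad, , drop = FALSE], config$fdr_q)
    out$effect_cmp <- effect_size_comparison(out$stat_mssm, out$stat_ct)
    out$extra <- extra_region_correlation(red[ad, , drop = FALSE],
                                          th[ad, , drop = FALSE],
                                          out$stat_mssm$significant,
                                          out$stat_ct$significant,
                                          splits$FAQ[ad])
  }
  te <- splits$split == "test"
  if (any(c("classify", "transfer") %in% what)) {
    out$model_mssm <- mssm_train(x, splits$label, splits$split,
                                 positive = "AD", config = config)
    out$report_mssm <- mssm_evaluate(out$model_mssm, x[te, , , drop = FALSE],
                                     splits$label[te])
  }
  if ("classify" %in% what) {
    ct_config <- config
    ct_config$seed <- derive_seed(seed, "ct")
    out$model_ct <- mssm_train(x, splits$label, splits$split,
                               positive = "AD", config = ct_config,
                               feature = "thickness")
    out$report_ct <- mssm_evaluate(out$model_ct, x[te, , , drop = FALSE],
                                   splits$label[te])
  }
  if ("baselines" %in% what) {
    y <- encode_labels(splits$label, positive = "AD")
    if ("hippocampus" %in% baseline_features) {
      hip <- splits$hippocampal_volume / splits$eTIV
      out$report_hippocampus <- scalar_baseline(hip, y, splits$split,
                                                seed = derive_seed(seed, "hip"),
                                                families = config$models)$report
    }
    if ("noise" %in% baseline_features) {
      noise <- with_seed(derive_seed(seed, "noisefeat"),
                         stats::rnorm(nrow(splits)))
      out$report_noise <- scalar_baseline(noise, y, splits$split,
                                          seed = derive_seed(seed, "noise"),
                                          families = config$models)$report
    }
  }
  if ("transfer" %in% what) {
    mci_eff <- effect_spec(effect$thickness_mask,
                           effect$thickness_delta_mm * transfer_scale,
                           effect$contrast_mask,
                           effect$contrast_delta * transfer_scale,
                           effect$subject_sd)
    mci <- make_cohort(phantom, mci_eff, n_transfer, n_transfer,
                       seed = derive_seed(seed, "mci"),
                       labels = c("MCI-C", "MCI-NC"))
    xm <- cohort_features(mci, config)
    out$transfer_cohort <- mci$cohort
    out$report_transfer <- transfer_predict(out$model_mssm, xm,
                                            mci$cohort$label,
                                            positive = "MCI-C")
  }
  class(out) <- "mssm_study"
  out
}

#' @export
print.mssm_study <- function(x, ...) {
  cat(sprintf("mssm_study (seed %d): %d subjects\n", x$seed, nrow(x$cohort)))
  if (!is.null(x$stat_mssm))
    cat(sprintf("  %% significant vertices: MSSM %.1f vs thickness %.1f\n",
                percent_significant(x$stat_mssm),
                percent_significant(x$stat_ct)))
  for (nm in c("report_mssm", "report_ct", "report_hippocampus",
               "report_noise", "report_transfer"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-18s AUROC %.3f\n", sub("report_", "", nm),
                  x[[nm]]$auroc))
  invisible(x)
}

#' Null-calibration experiment
#'
#' Trains the full pipeline on a cohort with zero effect deltas and evaluates
#' it on an independent zero-effect cohort, measuring the downstream AUROC a
#' disease-free world produces. Used to calibrate the null band that real
#' effects must exceed.
#'
#' @param seed integer seed.
#' @param phantom a [phantom_config()].
#' @param n_train per-group size of the training cohort.
#' @param n_eval per-group size of the independent evaluation cohort.
#' @param config an [mssm_config()].
#' @return list: `auroc` (on the independent cohort), `model`.
#' @export
run_null_study <- function(seed,
                           phantom = phantom_config(subdivisions = 3L,
                                                    base_radius_mm = 30),
                           n_train = 40L, n_eval = 60L,
                           config = mssm_config()) {
  config$seed <- as.integer(seed)
  mesh <- phantom_mesh(phantom)
  null_eff <- effect_spec(subject_sd = 0)
  cohort <- make_cohort(phantom, null_eff, n_train, n_train,
                        seed = derive_seed(seed, "null-train"))
  x <- cohort_features(cohort, config)
  splits <- make_splits(cohort$cohort, config$split_fractions,
                        seed = derive_seed(seed, "split"))
  model <- mssm_train(x, splits$label, splits$split, positive = "AD",
                      config = config)
  eval_co <- make_cohort(phantom, null_eff, n_eval, n_eval,
                         seed = derive_seed(seed, "null-eval"))
  xe <- cohort_features(eval_co, config)
  probs <- predict(model, xe)
  list(auroc = auroc(probs, encode_labels(eval_co$cohort$label,
                                          positive = "AD")),
       model = model)
}
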