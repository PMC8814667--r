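#' Run pipeline stages with on-disk artifacts and provenance
#'
#' Executes one stage (or `"all"`) of the mapping pipeline, writing its
#' outputs plus a JSON provenance record (stage, config, seed, config hash,
#' package and R versions) into `out_dir/<stage>/`. Stages:
#'
#' * `phantom` — synthetic AD/CN cohort (sizes `n_affected`/`n_control`,
#'   default 65/90 mirroring a typical AD/control cohort) and an
#'   intermediate-effect MCI-C/MCI-NC cohort (default 42/42), written as
#'   per-subject OFF surfaces + NIfTI volumes + `cohort.csv` + `truth.json`.
#' * `sample` — per-subject 9-column feature stacks (CSV per feature plus the
#'   binary matrix container with JSON sidecar).
#' * `smooth` — surface-smoothed feature stacks.
#' * `pls` — split assignment, vertex-wise PLS fit on the training split,
#'   reduced maps for every subject.
#' * `stats` — vertex-wise AD-vs-CN contrasts of the reduced map and of
#'   thickness, FDR masks, effect-size comparison, extra-region correlation
#'   against the FAQ-like score; summary JSON.
#' * `train` — ensemble selection and fit.
#' * `evaluate` — test-split evaluation report (JSON + ROC/PR CSV).
#' * `transfer` — the trained model applied unchanged to the MCI cohort.
#'
#' A missing prerequisite artifact is an error naming it. With a fixed
#' `config$seed` the whole tree is byte-identical across runs.
#'
#' @param config an [mssm_config()]; `config$seed` drives every stage.
#' @param stage one of phantom, sample, smooth, pls, stats, train, evaluate,
#'   transfer, all.
#' @param out_dir artifact directory.
#' @param phantom a [phantom_config()].
#' @param effect an [effect_spec()] for the AD-like cohort; default
#'   [ad_effect()] on the phantom mesh.
#' @param n_affected,n_control AD-like cohort group sizes.
#' @param n_mci per-group size of the transfer (MCI-like) cohort; its effect
#'   deltas are half the AD deltas.
#' @return invisibly, the path of the stage directory (for `"all"`, of
#'   `out_dir`).
#' @export
run_pipeline <- function(config = mssm_config(),
                         stage = c("all", "phantom", "sample", "smooth", "pls",
                                   "stats", "train", "evaluate", "transfer"),
                         out_dir = "mssm_out",
                         phantom = phantom_config(),
                         effect = NULL,
                         n_affected = 65L, n_control = 90L, n_mci = 42L) {
  stage <- match.arg(stage)
  if (stage == "all") {
    for (s in c("phantom", "sample", "smooth", "pls", "stats", "train",
                "evaluate", "transfer"))
      run_pipeline(config, s, out_dir, phantom, effect,
                   n_affected, n_control, n_mci)
    return(invisible(out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sdir <- file.path(out_dir, stage)
  dir.create(sdir, showWarnings = FALSE)
  need <- function(path, what) {
    if (!file.exists(path))
      stop(sprintf("missing prerequisite artifact for stage '%s': %s (%s)",
                   stage, path, what))
    path
  }
  mesh <- phantom_mesh(phantom)
  if (is.null(effect)) effect <- ad_effect(mesh)

  if (stage == "phantom") {
    make_cohort(phantom, effect, n_affected, n_control,
                seed = derive_seed(config$seed, "adcn"),
                labels = c("AD", "CN"), out_dir = file.path(sdir, "adcn"))
    mci_effect <- effect_spec(effect$thickness_mask,
                              effect$thickness_delta_mm / 2,
                              effect$contrast_mask, effect$contrast_delta / 2,
                              effect$subject_sd)
    make_cohort(phantom, mci_effect, n_mci, n_mci,
                seed = derive_seed(config$seed, "mci"),
                labels = c("MCI-C", "MCI-NC"),
                out_dir = file.path(sdir, "mci"))
  } else if (stage %in% c("sample", "smooth")) {
    for (coh in c("adcn", "mci")) {
      src <- if (stage == "sample") {
        need(file.path(out_dir, "phantom", coh, "cohort.csv"), "phantom stage output")
        file.path(out_dir, "phantom", coh)
      } else {
        need(file.path(out_dir, "sample", coh), "sample stage output")
        file.path(out_dir, "sample", coh)
      }
      dst <- file.path(sdir, coh)
      dir.create(dst, showWarnings = FALSE, recursive = TRUE)
      cohort <- read_cohort(need(file.path(src, "cohort.csv"), "cohort table"))
      file.copy(file.path(src, "cohort.csv"),
                file.path(dst, "cohort.csv"), overwrite = TRUE)
      for (id in cohort$subject_id) {
        if (stage == "sample") {
          pdir <- file.path(src, id)
          white <- read_surface(file.path(pdir, "white.off"))
          pial <- read_surface(file.path(pdir, "pial.off"))
          vol <- read_volume(file.path(pdir, "t1.nii.gz"))
          f <- contrast_features(white, pial, vol,
                                 depth_fractions = config$depth_fractions,
                                 wm_offsets_mm = config$wm_offsets_mm,
                                 ratio_direction = config$ratio_direction,
                                 interpolation = config$interpolation)
        } else {
          f <- read_vertex_matrix(need(file.path(src, paste0(id, ".bin")),
                                       "per-subject feature stack"))
          f <- smooth_map(f, mesh, fwhm_mm = config$smoothing_fwhm_mm)
          if (!config$smooth_thickness)
            f[, "thickness"] <- read_vertex_matrix(
              file.path(src, paste0(id, ".bin")))[, "thickness"]
        }
        write_vertex_matrix(f, file.path(dst, paste0(id, ".bin")))
        write_vertex_map(f[, "thickness"],
                         file.path(dst, paste0(id, "_thickness.csv")))
      }
    }
  } else if (stage == "pls") {
    for (coh in c("adcn", "mci")) {
      need(file.path(out_dir, "smooth", coh), "smooth stage output")
    }
    cohort <- read_cohort(file.path(out_dir, "smooth", "adcn", "cohort.csv"))
    cohort <- make_splits(cohort, config$split_fractions,
                          seed = derive_seed(config$seed, "split"))
    write_cohort(cohort, file.path(sdir, "splits.csv"))
    x <- read_feature_dir(file.path(out_dir, "smooth", "adcn"),
                          cohort$subject_id)
    y <- encode_labels(cohort$label, positive = "AD")
    fit <- fit_vertex_pls(x[cohort$split == "train", , , drop = FALSE],
                          y[cohort$split == "train"])
    saveRDS(fit, file.path(sdir, "pls_model.rds"))
    write_vertex_matrix(fit$w, file.path(sdir, "pls_weights.bin"))
    red <- predict(fit, x)
    write_vertex_matrix(t(red), file.path(sdir, "reduced_adcn.bin"))
    mci <- read_cohort(file.path(out_dir, "smooth", "mci", "cohort.csv"))
    xm <- read_feature_dir(file.path(out_dir, "smooth", "mci"),
                           mci$subject_id)
    write_vertex_matrix(t(predict(fit, xm)),
                        file.path(sdir, "reduced_mci.bin"))
  } else if (stage == "stats") {
    need(file.path(out_dir, "pls", "reduced_adcn.bin"), "pls stage output")
    cohort <- read_cohort(file.path(out_dir, "pls", "splits.csv"))
    red <- t(read_vertex_matrix(file.path(out_dir, "pls", "reduced_adcn.bin")))
    x <- read_feature_dir(file.path(out_dir, "smooth", "adcn"),
                          cohort$subject_id)
    th <- x[, , "thickness", drop = TRUE]
    ad <- cohort$label == "AD"
    st_m <- vertex_ttest(red[ad, , drop = FALSE], red[!ad, , drop = FALSE],
                         fdr_q = config$fdr_q)
    st_t <- vertex_ttest(th[ad, , drop = FALSE], th[!ad, , drop = FALSE],
                         fdr_q = config$fdr_q)
    cmp <- effect_size_comparison(st_m, st_t)
    utils::write.csv(
      data.frame(vertex_index = seq_along(st_m$t) - 1L,
                 t_mssm = st_m$t, p_mssm = st_m$p, d_mssm = st_m$d,
                 sig_mssm = st_m$significant,
                 t_ct = st_t$t, p_ct = st_t$p, d_ct = st_t$d,
                 sig_ct = st_t$significant),
      file.path(sdir, "statmap.csv"), row.names = FALSE, quote = FALSE)
    extra <- extra_region_correlation(red[ad, , drop = FALSE],
                                      th[ad, , drop = FALSE],
                                      st_m$significant, st_t$significant,
                                      cohort$FAQ[ad])
    summ <- list(percent_significant_mssm = percent_significant(st_m),
                 percent_significant_thickness = percent_significant(st_t),
                 mssm_stronger_fraction = mean(cmp$a_stronger, na.rm = TRUE),
                 n_extra_vertices = if (extra$empty) 0L else extra$n_extra,
                 extra_region_correlations = if (extra$empty) NULL
                   else extra$correlations)
    jsonlite::write_json(summ, file.path(sdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else if (stage == "train") {
    need(file.path(out_dir, "pls", "splits.csv"), "pls stage output")
    cohort <- read_cohort(file.path(out_dir, "pls", "splits.csv"))
    x <- read_feature_dir(file.path(out_dir, "smooth", "adcn"),
                          cohort$subject_id)
    model <- mssm_train(x, cohort$label, cohort$split, positive = "AD",
                        config = config)
    saveRDS(model, file.path(sdir, "model.rds"))
    utils::write.csv(model$ensemble$ranking,
                     file.path(sdir, "family_ranking.csv"), row.names = FALSE)
  } else if (stage == "evaluate") {
    need(file.path(out_dir, "train", "model.rds"), "train stage output")
    model <- readRDS(file.path(out_dir, "train", "model.rds"))
    cohort <- read_cohort(file.path(out_dir, "pls", "splits.csv"))
    te <- cohort$split == "test"
    x <- read_feature_dir(file.path(out_dir, "smooth", "adcn"),
                          cohort$subject_id[te])
    rep <- mssm_evaluate(model, x, cohort$label[te])
    write_eval_report(rep, sdir, "eval")
  } else if (stage == "transfer") {
    need(file.path(out_dir, "train", "model.rds"), "train stage output")
    model <- readRDS(file.path(out_dir, "train", "model.rds"))
    mci <- read_cohort(file.path(out_dir, "smooth", "mci", "cohort.csv"))
    xm <- read_feature_dir(file.path(out_dir, "smooth", "mci"),
                           mci$subject_id)
    rep <- transfer_predict(model, xm, mci$label, positive = "MCI-C")
    write_eval_report(rep, sdir, "transfer_eval")
  }
  write_provenance(sdir, stage, config)
  invisible(sdir)
}

read_feature_dir <- function(dir, subject_ids) {
  fs <- lapply(subject_ids, function(id) {
    path <- file.path(dir, paste0(id, ".bin"))
    if (!file.exists(path))
      stop("missing prerequisite artifact: feature stack ", path)
    read_vertex_matrix(path)
  })
  names(fs) <- subject_ids
  stack_features(fs)
}

write_eval_report <- function(rep, dir, name) {
  jsonlite::write_json(
    list(auroc = rep$auroc, auprc = rep$auprc, accuracy = rep$accuracy,
         sensitivity = rep$sensitivity, specificity = rep$specificity,
         threshold = rep$threshold, n = rep$n),
    file.path(dir, paste0(name, ".json")), auto_unbox = TRUE, digits = NA)
  utils::write.csv(rep$roc, file.path(dir, paste0(name, "_roc.csv")),
                   row.names = FALSE)
  utils::write.csv(rep$pr, file.path(dir, paste0(name, "_pr.csv")),
                   row.names = FALSE)
  invisible(rep)
}

write_provenance <- function(sdir, stage, config) {
  jsonlite::write_json(
    list(stage = stage, seed = config$seed,
         config = unclass(config), config_hash = object_hash(unclass(config)),
         package_version = as.character(utils::packageVersion("mssm")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    file.path(sdir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
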