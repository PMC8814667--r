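#' Pipeline run configuration
#'
#' Collects every tunable of the mapping and classification procedure with its
#' default: four intracortical depth fractions, two white-matter offsets,
#' 5 mm FWHM surface smoothing, FDR level 0.05, a 60/20/20 train/val/test
#' split, and the nine-family model zoo.
#'
#' @param depth_fractions cortical depth fractions, strictly inside (0, 1).
#' @param wm_offsets_mm white-matter sampling offsets below the gray/white
#'   border, mm.
#' @param smoothing_fwhm_mm full-width-half-maximum of the surface smoothing
#'   kernel, mm.
#' @param fdr_q false-discovery-rate level for vertex-wise significance.
#' @param split_fractions train/validation/test fractions; must sum to 1.
#' @param seed integer seed governing every random choice downstream.
#' @param models classifier families to consider (see [model_zoo()]).
#' @param n_init random initializations per family during selection.
#' @param n_folds cross-validation folds during selection.
#' @param ratio_direction `"gm_over_wm"` (default; T1-like ratios < 1) or
#'   `"wm_over_gm"`.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @param smooth_thickness smooth the thickness map with the same kernel as
#'   the contrast maps.
#' @param refit_train_val refit selected models on train+validation instead of
#'   train only.
#' @return list of class `mssm_config`.
#' @export
mssm_config <- function(depth_fractions = c(0.2, 0.4, 0.6, 0.8),
                        wm_offsets_mm = c(0.5, 1.0),
                        smoothing_fwhm_mm = 5.0,
                        fdr_q = 0.05,
                        split_fractions = c(0.6, 0.2, 0.2),
                        seed = 1L,
                        models = names(model_zoo()),
                        n_init = 5L,
                        n_folds = 4L,
                        ratio_direction = "gm_over_wm",
                        interpolation = "trilinear",
                        smooth_thickness = TRUE,
                        refit_train_val = FALSE) {
  cfg <- list(depth_fractions = as.numeric(depth_fractions),
              wm_offsets_mm = as.numeric(wm_offsets_mm),
              smoothing_fwhm_mm = as.numeric(smoothing_fwhm_mm),
              fdr_q = as.numeric(fdr_q),
              split_fractions = as.numeric(split_fractions),
              seed = as.integer(seed),
              models = models,
              n_init = as.integer(n_init),
              n_folds = as.integer(n_folds),
              ratio_direction = match.arg(ratio_direction,
                                          c("gm_over_wm", "wm_over_gm")),
              interpolation = match.arg(interpolation,
                                        c("trilinear", "nearest")),
              smooth_thickness = isTRUE(smooth_thickness),
              refit_train_val = isTRUE(refit_train_val))
  validate_config(cfg)
  class(cfg) <- "mssm_config"
  cfg
}

validate_config <- function(cfg) {
  if (any(cfg$depth_fractions <= 0 | cfg$depth_fractions >= 1))
    stop("depth_fractions must lie strictly inside (0, 1)")
  if (any(cfg$wm_offsets_mm <= 0)) stop("wm_offsets_mm must be positive")
  if (cfg$smoothing_fwhm_mm < 0) stop("smoothing_fwhm_mm must be >= 0")
  if (abs(sum(cfg$split_fractions) - 1) > 1e-8)
    stop("split_fractions must sum to 1")
  if (cfg$fdr_q <= 0 || cfg$fdr_q >= 1) stop("fdr_q must be in (0, 1)")
  invisible(cfg)
}

#' Read / write a configuration file
#'
#' Flat key-value YAML; keys mirror the arguments of [mssm_config()].
#' Unknown keys are an error. CLI flags override file values.
#'
#' @param path YAML file path.
#' @return `read_config`: an `mssm_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mssm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(mssm_config, vals)
}

#' @rdname read_config
#' @param config an `mssm_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable content hash (MD5 over the serialized object) used for provenance
# records and train/test-hygiene checks.
object_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 3L)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(bytes, tf)
  unname(tools::md5sum(tf))
}

# Derive a child seed (< 2^31) from a base seed and a label, so that every
# random stage has its own reproducible stream.
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (c in utf8ToInt(lab)) h <- (h * 33 + c) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
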