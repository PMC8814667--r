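#' Phantom geometry and intensity configuration
#'
#' The phantom is a spherical cortical ribbon: the white surface is an
#' icosphere of radius `base_radius_mm`, the pial surface sits one local
#' thickness outward along the vertex normal, and the volume is piecewise
#' constant (WM inside the white surface, GM in the ribbon, CSF outside) with
#' T1-like ordering WM > GM > CSF, then multiplied by a smooth bias field and
#' degraded with additive Gaussian noise. A voxel belongs to the innermost
#' region containing its center.
#'
#' Defaults: icosphere level 4 (2562 vertices), white radius 40 mm, uniform
#' 2.5 mm thickness, intensities 110/75/20, noise sd 5, a +/-10% bias field
#' built from 3 low-frequency cosine modes with random directions and phases,
#' and 1 x 1 x 1.2 mm voxels.
#'
#' @param subdivisions icosphere subdivision level (level 4 = 2562 vertices).
#' @param base_radius_mm white-surface radius, mm.
#' @param thickness_mm cortical thickness, mm; scalar or per-vertex vector.
#' @param thickness_subject_sd standard deviation of a per-subject global
#'   thickness offset (mm), emulating normal between-subject variation in
#'   mean cortical thickness; truncated at 4 sd.
#' @param wm,gm,csf mean tissue intensities (arbitrary units).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param bias_amplitude peak fractional deviation of the multiplicative bias
#'   field (0.1 = +/-10%).
#' @param bias_wavelength_mm spatial wavelength of the bias modes, mm.
#' @param voxel_size_mm length-3 voxel size, mm.
#' @param margin_mm padding between the pial surface and the volume edge, mm.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(subdivisions = 4L, base_radius_mm = 40,
                           thickness_mm = 2.5,
                           thickness_subject_sd = 0.15,
                           wm = 110, gm = 75, csf = 20,
                           noise_sd = 5,
                           bias_amplitude = 0.1,
                           bias_wavelength_mm = 100,
                           voxel_size_mm = c(1, 1, 1.2),
                           margin_mm = 3) {
  cfg <- list(subdivisions = as.integer(subdivisions),
              base_radius_mm = base_radius_mm,
              thickness_mm = thickness_mm,
              thickness_subject_sd = thickness_subject_sd,
              wm = wm, gm = gm, csf = csf,
              noise_sd = noise_sd,
              bias_amplitude = bias_amplitude,
              bias_wavelength_mm = bias_wavelength_mm,
              voxel_size_mm = as.numeric(voxel_size_mm),
              margin_mm = margin_mm)
  if (!(cfg$wm > cfg$gm && cfg$gm > cfg$csf))
    stop("tissue intensities must satisfy WM > GM > CSF")
  if (any(cfg$thickness_mm <= 0)) stop("thickness must be positive everywhere")
  if (cfg$thickness_subject_sd < 0) stop("thickness_subject_sd must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(cfg$voxel_size_mm) != 3L || any(cfg$voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive numbers")
  class(cfg) <- "phantom_config"
  cfg
}

#' Disease-like effect specification
#'
#' Separable effects on the phantom: cortical thinning (thickness reduced by
#' `thickness_delta_mm` inside `thickness_mask`) and gray/white contrast loss
#' (GM intensity shifted toward WM by the fraction `contrast_delta` of the
#' WM-GM gap inside `contrast_mask`). Affected subjects draw a shared severity
#' factor `max(0, 1 + N(0, subject_sd))` scaling both deltas, emulating
#' between-subject variation in disease burden.
#'
#' @param thickness_mask,contrast_mask logical or integer vertex masks.
#' @param thickness_delta_mm mean thickness reduction in affected subjects, mm.
#' @param contrast_delta mean fractional GM-intensity shift toward WM.
#' @param subject_sd standard deviation of the per-subject severity factor.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(thickness_mask = integer(0), thickness_delta_mm = 0,
                        contrast_mask = integer(0), contrast_delta = 0,
                        subject_sd = 0.2) {
  if (thickness_delta_mm < 0 || contrast_delta < 0)
    stop("effect deltas must be >= 0")
  structure(list(thickness_mask = thickness_mask,
                 thickness_delta_mm = thickness_delta_mm,
                 contrast_mask = contrast_mask,
                 contrast_delta = contrast_delta,
                 subject_sd = subject_sd),
            class = "effect_spec")
}

#' Spherical-cap vertex mask
#'
#' Vertices within `angle_deg` of the direction `center`; the standard way to
#' place "signature" regions on the phantom sphere.
#'
#' @param mesh a `surface_mesh`.
#' @param angle_deg angular radius of the cap, degrees.
#' @param center direction of the cap center (any length; normalized).
#' @return logical vertex mask.
#' @export
cap_mask <- function(mesh, angle_deg, center = c(0, 0, 1)) {
  u <- center / sqrt(sum(center^2))
  d <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  as.vector(d %*% u) >= cos(angle_deg * pi / 180)
}

#' Default disease-like effect: thinning in a cap, contrast loss in a wider cap
#'
#' The contrast-loss region deliberately extends beyond the thinning region,
#' emulating disease effects on tissue contrast in cortex that is not (yet)
#' measurably thinner — the situation in which multiscale mapping should add
#' sensitivity over thickness alone.
#'
#' @param mesh the phantom white `surface_mesh`.
#' @param thickness_angle,contrast_angle cap angular radii, degrees.
#' @param thickness_delta_mm,contrast_delta,subject_sd see [effect_spec()].
#' @param center cap center direction.
#' @return an `effect_spec`.
#' @export
ad_effect <- function(mesh, thickness_angle = 25, contrast_angle = 50,
                      thickness_delta_mm = 0.6, contrast_delta = 0.25,
                      subject_sd = 0.2, center = c(0, 0, 1)) {
  effect_spec(thickness_mask = cap_mask(mesh, thickness_angle, center),
              thickness_delta_mm = thickness_delta_mm,
              contrast_mask = cap_mask(mesh, contrast_angle, center),
              contrast_delta = contrast_delta,
              subject_sd = subject_sd)
}

# ---- internal geometry caches ----------------------------------------------

.phantom_cache <- new.env(parent = emptyenv())

phantom_mesh <- function(config) {
  key <- paste0("mesh/", config$subdivisions, "/", config$base_radius_mm)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- icosphere(config$subdivisions, config$base_radius_mm)
  .phantom_cache[[key]]
}

phantom_grid <- function(config) {
  maxt <- max(config$thickness_mm) + 4 * config$thickness_subject_sd
  extent <- config$base_radius_mm + maxt + config$margin_mm
  vs <- config$voxel_size_mm
  dims <- as.integer(ceiling(2 * extent / vs)) + 1L
  origin <- -vs * (dims - 1) / 2
  affine <- diag(c(vs, 1))
  affine[1:3, 4] <- origin
  key <- paste0("grid/", paste(dims, collapse = ","), "/",
                paste(vs, collapse = ","), "/",
                config$base_radius_mm, "/", config$subdivisions, "/", maxt)
  if (is.null(.phantom_cache[[key]])) {
    ii <- (seq_len(dims[1]) - 1) * vs[1] + origin[1]
    jj <- (seq_len(dims[2]) - 1) * vs[2] + origin[2]
    kk <- (seq_len(dims[3]) - 1) * vs[3] + origin[3]
    x <- rep(ii, times = dims[2] * dims[3])
    y <- rep(rep(jj, each = dims[1]), times = dims[3])
    z <- rep(kk, each = dims[1] * dims[2])
    r <- sqrt(x^2 + y^2 + z^2)
    band <- which(r > config$base_radius_mm & r <= config$base_radius_mm + maxt)
    mesh <- phantom_mesh(config)
    dirs <- mesh$vertices / config$base_radius_mm   # unit directions
    nearest <- integer(length(band))
    chunk <- 20000L
    for (s in seq(1L, length(band), by = chunk)) {
      idx <- band[s:min(s + chunk - 1L, length(band))]
      dots <- cbind(x[idx], y[idx], z[idx]) %*% t(dirs)
      nearest[s:(s + length(idx) - 1L)] <- max.col(dots, ties.method = "first")
    }
    .phantom_cache[[key]] <- list(dims = dims, affine = affine, r = r,
                                  x = x, y = y, z = z,
                                  band = band, nearest = nearest)
  }
  .phantom_cache[[key]]
}

# ---- subject generation ----------------------------------------------------

#' Generate one phantom subject
#'
#' Builds the white/pial surface pair and the intensity volume for a single
#' subject. `effect`, if given, is applied at face value (no severity jitter;
#' cohort-level jitter is [make_cohort()]'s job).
#'
#' @param config a `phantom_config`.
#' @param effect an `effect_spec`, or `NULL` for an unaffected subject.
#' @param rng_seed integer seed for the bias phases and the noise.
#' @return list with elements `white`, `pial` (surface_mesh), `volume`
#'   (volume_image) and `thickness` (per-vertex mm actually realized).
#' @export
make_phantom_subject <- function(config, effect = NULL, rng_seed = 1L) {
  mesh <- phantom_mesh(config)
  nv <- n_vertices(mesh)
  thickness <- rep_len(config$thickness_mm, nv)
  if (config$thickness_subject_sd > 0) {
    off <- with_seed(derive_seed(rng_seed, "thick"),
                     stats::rnorm(1, 0, config$thickness_subject_sd))
    off <- max(-4, min(4, off / config$thickness_subject_sd)) *
      config$thickness_subject_sd
    thickness <- thickness + off
  }
  csel <- rep(FALSE, nv)
  cdelta <- 0
  if (!is.null(effect)) {
    tm <- as_mask(effect$thickness_mask, nv)
    csel <- as_mask(effect$contrast_mask, nv)
    if (effect$thickness_delta_mm > 0) {
      if (any(effect$thickness_delta_mm >= thickness[tm]))
        stop("degenerate ribbon: thickness_delta >= thickness inside the mask")
      thickness[tm] <- thickness[tm] - effect$thickness_delta_mm
    }
    cdelta <- effect$contrast_delta
  }
  normals <- vertex_normals(mesh)
  pial <- surface_mesh(mesh$vertices + thickness * normals, mesh$faces,
                       hemisphere = mesh$hemisphere)

  g <- phantom_grid(config)
  val <- rep(config$csf, length(g$r))
  val[g$r <= config$base_radius_mm] <- config$wm
  tv <- thickness[g$nearest]
  in_gm <- g$r[g$band] <= config$base_radius_mm + tv
  gm_idx <- g$band[in_gm]
  val[gm_idx] <- config$gm
  if (cdelta > 0 && any(csel)) {
    hit <- csel[g$nearest[in_gm]]
    val[gm_idx[hit]] <- config$gm + cdelta * (config$wm - config$gm)
  }
  with_seed(rng_seed, {
    if (config$bias_amplitude > 0) {
      b <- rep(1, length(val))
      for (k in 1:3) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        phi <- stats::runif(1, 0, 2 * pi)
        proj <- g$x * u[1] + g$y * u[2] + g$z * u[3]
        b <- b + (config$bias_amplitude / 3) *
          cos(2 * pi * proj / config$bias_wavelength_mm + phi)
      }
      val <- val * b
    }
    if (config$noise_sd > 0)
      val <- val + stats::rnorm(length(val), 0, config$noise_sd)
  })
  vol <- volume_image(array(val, g$dims), g$affine)
  list(white = mesh, pial = pial, volume = vol, thickness = thickness)
}

as_mask <- function(mask, nv) {
  if (is.logical(mask)) {
    if (length(mask) != nv) stop("logical mask length must equal vertex count")
    return(mask)
  }
  mask <- as.integer(mask)
  if (length(mask) && (min(mask) < 1L || max(mask) > nv))
    stop("mask indices must be a subset of 1..n_vertices")
  out <- rep(FALSE, nv)
  out[mask] <- TRUE
  out
}

#' Generate a synthetic cohort
#'
#' Affected subjects carry the effect scaled by per-subject severity factors;
#' controls carry none. Thinning and contrast loss are treated as distinct
#' but related disease processes: each affected subject draws
#' `s = max(0, 1 + a z0 + a z_p)` per process, with `z0` shared and `z_p`
#' process-specific (`a = subject_sd / sqrt(2)`), giving severity correlation
#' 0.5 between the two processes. The cohort table includes synthetic
#' clinical columns generated from the severities (a FAQ-like functional
#' score driven by the contrast process, a hippocampal-volume-like regional
#' volume driven by the mean burden, and an eTIV-like normalizer) plus
#' age/sex/education covariates, so the correlation and scalar-baseline
#' analyses have a ground truth. Everything is reproducible from `seed`.
#'
#' @param config a `phantom_config`.
#' @param effect an `effect_spec` applied to affected subjects.
#' @param n_affected,n_control group sizes (>= 2 each).
#' @param seed integer seed.
#' @param labels length-2 character: label for affected and control subjects.
#' @param out_dir if non-NULL, write per-subject surfaces (OFF) + volume
#'   (NIfTI), `cohort.csv` and `truth.json` into this directory.
#' @return list of class `synthetic_cohort`: `cohort` (cohort_table),
#'   `subjects` (named list with white/pial/volume/thickness), `severity`
#'   (data frame with per-subject thickness/contrast severities), `effect`,
#'   `config`.
#' @export
make_cohort <- function(config, effect, n_affected, n_control, seed = 1L,
                        labels = c("AD", "CN"), out_dir = NULL) {
  if (n_affected < 2L || n_control < 2L)
    stop("need at least 2 subjects per group")
  n <- n_affected + n_control
  ids <- sprintf("S%03d", seq_len(n))
  grp <- rep(labels, c(n_affected, n_control))
  severity <- with_seed(derive_seed(seed, "severity"), {
    a <- effect$subject_sd / sqrt(2)
    z0 <- stats::rnorm(n); zt <- stats::rnorm(n); zc <- stats::rnorm(n)
    s <- data.frame(thickness = pmax(0, 1 + a * (z0 + zt)),
                    contrast = pmax(0, 1 + a * (z0 + zc)))
    s[grp == labels[2], ] <- 0
    s
  })
  rownames(severity) <- ids
  subjects <- vector("list", n)
  names(subjects) <- ids
  for (i in seq_len(n)) {
    eff_i <- if (grp[i] == labels[1]) {
      effect_spec(thickness_mask = effect$thickness_mask,
                  thickness_delta_mm = effect$thickness_delta_mm *
                    severity$thickness[i],
                  contrast_mask = effect$contrast_mask,
                  contrast_delta = effect$contrast_delta * severity$contrast[i],
                  subject_sd = effect$subject_sd)
    } else NULL
    subjects[[i]] <- make_phantom_subject(config, eff_i,
                                          rng_seed = derive_seed(seed, "subj", i))
  }
  cohort <- with_seed(derive_seed(seed, "clinical"), {
    burden <- (severity$thickness + severity$contrast) / 2
    faq <- ifelse(grp == labels[1],
                  pmax(0, 11.8 * severity$contrast + stats::rnorm(n, 0, 2)),
                  pmax(0, stats::rnorm(n, 0.2, 0.7)))
    etiv <- stats::rnorm(n, 1.6e6, 1.2e5)
    hippo <- 4000 * (1 - 0.25 * burden) + stats::rnorm(n, 0, 250)
    data.frame(subject_id = ids, label = grp,
               age = round(stats::rnorm(n, 74, 7), 1),
               sex = sample(c("F", "M"), n, replace = TRUE),
               education = round(stats::rnorm(n, 16, 2.5)),
               FAQ = round(faq, 1),
               hippocampal_volume = round(hippo, 1),
               eTIV = round(etiv, 1),
               stringsAsFactors = FALSE)
  })
  cohort <- as_cohort(cohort, labels = unique(grp))
  out <- structure(list(cohort = cohort, subjects = subjects,
                        severity = severity, effect = effect, config = config),
                   class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort_dir(out, out_dir)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects (%s)\n", nrow(x$cohort),
              paste(sprintf("%s=%d", names(table(x$cohort$label)),
                            table(x$cohort$label)), collapse = ", ")))
  invisible(x)
}

write_cohort_dir <- function(sc, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(sc$subjects)) {
    sdir <- file.path(out_dir, id)
    dir.create(sdir, showWarnings = FALSE)
    s <- sc$subjects[[id]]
    write_surface(s$white, file.path(sdir, "white.off"))
    write_surface(s$pial, file.path(sdir, "pial.off"))
    write_volume(s$volume, file.path(sdir, "t1.nii.gz"))
  }
  write_cohort(sc$cohort, file.path(out_dir, "cohort.csv"))
  truth <- list(
    thickness_mask = which(as_mask(sc$effect$thickness_mask,
                                   n_vertices(sc$subjects[[1]]$white))),
    contrast_mask = which(as_mask(sc$effect$contrast_mask,
                                  n_vertices(sc$subjects[[1]]$white))),
    thickness_delta_mm = sc$effect$thickness_delta_mm,
    contrast_delta = sc$effect$contrast_delta,
    severity = sc$severity)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
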