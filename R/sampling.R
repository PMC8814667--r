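#' Intracortical depth surface
#'
#' Linear interpolation along the white-to-pial vertex correspondence:
#' `vertex_i = (1 - fraction) * white_i + fraction * pial_i`. Fraction 0 is
#' the gray/white border, 1 the gray/CSF border.
#'
#' @param white,pial corresponding `surface_mesh` pair (equal vertex counts).
#' @param fraction depth fraction in `[0, 1]`.
#' @return a `surface_mesh` with the faces of `white`.
#' @export
depth_surface <- function(white, pial, fraction) {
  if (n_vertices(white) != n_vertices(pial))
    stop("white and pial surfaces must have equal vertex counts")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  surface_mesh((1 - fraction) * white$vertices + fraction * pial$vertices,
               white$faces, hemisphere = white$hemisphere, validate = FALSE)
}

#' Subjacent white-matter surface
#'
#' Displaces each white-surface vertex by `offset_mm` against its outward
#' normal, i.e. into the white matter.
#'
#' @param white white `surface_mesh`.
#' @param offset_mm displacement below the gray/white border, mm (>= 0).
#' @return a `surface_mesh`.
#' @export
wm_surface <- function(white, offset_mm) {
  if (offset_mm < 0) stop("offset_mm must be >= 0")
  if (offset_mm == 0) return(white)
  surface_mesh(white$vertices - offset_mm * vertex_normals(white),
               white$faces, hemisphere = white$hemisphere, validate = FALSE)
}

#' Per-vertex cortical thickness
#'
#' Euclidean distance between corresponding white and pial vertices, mm.
#'
#' @param white,pial corresponding `surface_mesh` pair.
#' @return numeric vector, one value per vertex.
#' @export
cortical_thickness <- function(white, pial) {
  if (n_vertices(white) != n_vertices(pial))
    stop("white and pial surfaces must have equal vertex counts")
  sqrt(rowSums((pial$vertices - white$vertices)^2))
}

#' Sample a volume at mesh vertices
#'
#' World coordinates are mapped through the inverse affine to continuous
#' 0-based voxel indices and interpolated (trilinear by default). Vertices
#' whose interpolation support leaves the grid are returned as `NA` (flagged
#' undefined, never silently zero).
#'
#' @param mesh a `surface_mesh`.
#' @param volume a `volume_image`.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return numeric vector of sampled intensities, one per vertex, `NA` where
#'   undefined; attribute `"n_undefined"` counts them.
#' @export
sample_volume <- function(mesh, volume, interpolation = "trilinear") {
  interpolation <- match.arg(interpolation, c("trilinear", "nearest"))
  inv <- solve(volume$affine)
  w <- cbind(mesh$vertices, 1) %*% t(inv)
  ijk <- w[, 1:3, drop = FALSE]   # continuous 0-based indices
  d <- dim(volume$data)
  vals <- rep(NA_real_, nrow(ijk))
  if (interpolation == "nearest") {
    idx <- round(ijk)
    ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
          idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
          idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    lin <- idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3]) + 1
    vals[ok] <- volume$data[lin]
  } else {
    f <- floor(ijk)
    # vertices exactly on the upper grid face use the last full cell
    hi <- ijk == matrix(d - 1, nrow(ijk), 3, byrow = TRUE)
    f[hi] <- f[hi] - 1
    ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 2 &
          f[, 2] >= 0 & f[, 2] <= d[2] - 2 &
          f[, 3] >= 0 & f[, 3] <= d[3] - 2
    fo <- f[ok, , drop = FALSE]
    t3 <- ijk[ok, , drop = FALSE] - fo
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- (if (dx) t3[, 1] else 1 - t3[, 1]) *
             (if (dy) t3[, 2] else 1 - t3[, 2]) *
             (if (dz) t3[, 3] else 1 - t3[, 3])
      lin <- (fo[, 1] + dx) + d[1] * ((fo[, 2] + dy) + d[2] * (fo[, 3] + dz)) + 1
      acc <- acc + wgt * volume$data[lin]
    }
    vals[ok] <- acc
  }
  attr(vals, "n_undefined") <- sum(!ok)
  vals
}

#' Multiscale contrast-ratio feature stack
#'
#' The unit that flows through smoothing, PLS and classification: a vertex by
#' feature matrix whose first column is cortical thickness and whose remaining
#' 8 columns are gray/white contrast ratios — GM intensity sampled at each
#' depth fraction divided by WM intensity sampled at each subjacent offset,
#' grouped by offset: `thickness, G20/W0.5, G40/W0.5, G60/W0.5, G80/W0.5,
#' G20/W1.0, G40/W1.0, G60/W1.0, G80/W1.0` under the defaults.
#'
#' Vertices with undefined samples or non-positive WM intensity are `NA` for
#' the affected features.
#'
#' @param white,pial corresponding surface pair.
#' @param volume a `volume_image`.
#' @param depth_fractions GM depth fractions (default 0.2, 0.4, 0.6, 0.8).
#' @param wm_offsets_mm WM offsets below the gray/white border, mm
#'   (default 0.5, 1.0).
#' @param ratio_direction `"gm_over_wm"` (default) or `"wm_over_gm"`.
#' @param interpolation passed to [sample_volume()].
#' @return numeric matrix, class `feature_stack`, n_vertices x
#'   (1 + length(depth_fractions) * length(wm_offsets_mm)).
#' @export
contrast_features <- function(white, pial, volume,
                              depth_fractions = c(0.2, 0.4, 0.6, 0.8),
                              wm_offsets_mm = c(0.5, 1.0),
                              ratio_direction = "gm_over_wm",
                              interpolation = "trilinear") {
  ratio_direction <- match.arg(ratio_direction, c("gm_over_wm", "wm_over_gm"))
  gm <- sapply(depth_fractions, function(fr)
    sample_volume(depth_surface(white, pial, fr), volume, interpolation))
  wmv <- sapply(wm_offsets_mm, function(off)
    sample_volume(wm_surface(white, off), volume, interpolation))
  nv <- n_vertices(white)
  gm <- matrix(gm, nrow = nv); wmv <- matrix(wmv, nrow = nv)
  cols <- list(thickness = cortical_thickness(white, pial))
  for (wi in seq_along(wm_offsets_mm)) {
    den <- wmv[, wi]
    den[!is.na(den) & den <= 0] <- NA
    for (gi in seq_along(depth_fractions)) {
      nm <- sprintf("G%d.W%g", round(100 * depth_fractions[gi]),
                    wm_offsets_mm[wi])
      ratio <- if (ratio_direction == "gm_over_wm") gm[, gi] / den
               else den / gm[, gi]
      ratio[!is.na(ratio) & ratio <= 0] <- NA
      cols[[nm]] <- ratio
    }
  }
  out <- do.call(cbind, cols)
  class(out) <- c("feature_stack", class(out))
  out
}
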