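#' 3-D intensity volume with voxel-to-world affine
#'
#' Wraps a 3-D numeric array and a 4x4 affine mapping 0-based voxel indices
#' (i, j, k, 1) to world millimetres (RAS). All geometric operations go
#' through the affine; raw indices are never interpreted as millimetres.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(data, affine) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("affine is singular: voxel-to-world transform must be invertible")
  if (!all(is.finite(data))) stop("volume data must be finite")
  structure(list(data = data, affine = affine), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  vs <- voxel_size(x)
  cat(sprintf("volume_image: %s voxels, voxel size %.3g x %.3g x %.3g mm\n",
              paste(dim(x$data), collapse = " x "), vs[1], vs[2], vs[3]))
  invisible(x)
}

#' Voxel size derived from the affine
#' @param vol a `volume_image`.
#' @return length-3 numeric, mm per voxel along each axis.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti preserving data and affine. `write_volume` stores
#' float32; round-trips are lossless for float32 data.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @return `read_volume`: a `volume_image`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file does not exist: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  d <- array(as.numeric(img), dim(img))
  if (length(dim(d)) == 4L && dim(d)[4] == 1L) d <- array(d, dim(d)[1:3])
  volume_image(d, aff[1:4, 1:4])
}

#' @rdname read_volume
#' @param vol a `volume_image`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write cohort tables
#'
#' A cohort table is a UTF-8 CSV with a header row, one row per subject.
#' Required columns: `subject_id` (unique) and `label` (one of AD, CN, MCI-C,
#' MCI-NC). Optional columns: covariates (`age`, `sex`, `education`), named
#' scores (e.g. `FAQ`, `hippocampal_volume`, `eTIV`), and `split`
#' (train/val/test, assigned by [make_splits()]).
#'
#' @param path CSV path.
#' @param labels allowed diagnosis labels.
#' @return `read_cohort`: a `data.frame` of class `cohort_table`.
#' @export
read_cohort <- function(path, labels = c("AD", "CN", "MCI-C", "MCI-NC")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_cohort(df, labels = labels)
}

#' @rdname read_cohort
#' @param cohort a cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_cohort
#' @param df data frame with at least `subject_id` and `label`.
#' @export
as_cohort <- function(df, labels = c("AD", "CN", "MCI-C", "MCI-NC")) {
  if (!all(c("subject_id", "label") %in% names(df)))
    stop("cohort table needs columns subject_id and label")
  if (anyDuplicated(df$subject_id))
    stop("subject_id values must be unique")
  bad <- setdiff(unique(df$label), labels)
  if (length(bad))
    stop("labels outside the declared set: ", paste(bad, collapse = ", "))
  class(df) <- c("cohort_table", "data.frame")
  df
}
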