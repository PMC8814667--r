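#' Compute (and smooth) feature stacks for a whole cohort
#'
#' Runs [contrast_features()] for every subject of a synthetic cohort (or any
#' named list of `white`/`pial`/`volume` triples) and, when
#' `config$smoothing_fwhm_mm > 0`, smooths every column on the white surface
#' with the calibrated kernel. Returns the subjects x vertices x features
#' array the reduction and classification stages consume.
#'
#' @param cohort a `synthetic_cohort` (or list with `subjects` and `cohort`).
#' @param config an [mssm_config()].
#' @param smooth apply surface smoothing (default `TRUE`).
#' @return subjects x vertices x features array.
#' @export
cohort_features <- function(cohort, config = mssm_config(), smooth = TRUE) {
  subs <- cohort$subjects
  fs <- vector("list", length(subs))
  names(fs) <- names(subs)
  n_it <- NULL
  for (id in names(subs)) {
    s <- subs[[id]]
    f <- contrast_features(s$white, s$pial, s$volume,
                           depth_fractions = config$depth_fractions,
                           wm_offsets_mm = config$wm_offsets_mm,
                           ratio_direction = config$ratio_direction,
                           interpolation = config$interpolation)
    if (smooth && config$smoothing_fwhm_mm > 0) {
      if (is.null(n_it))
        n_it <- suppressWarnings(
          calibrate_smoothing(s$white, config$smoothing_fwhm_mm))
      sm <- smooth_map(f, s$white, fwhm_mm = config$smoothing_fwhm_mm,
                       n_iterations = n_it)
      if (!config$smooth_thickness) sm[, "thickness"] <- f[, "thickness"]
      f <- sm
    }
    fs[[id]] <- f
  }
  stack_features(fs)
}

#' Write / read a per-vertex map as CSV
#'
#' Two columns: `vertex_index` (0-based) and `value`; undefined vertices are
#' written as empty fields.
#'
#' @param values numeric vector, one value per vertex.
#' @param path CSV path.
#' @return `read_vertex_map`: the numeric vector.
#' @export
write_vertex_map <- function(values, path) {
  df <- data.frame(vertex_index = seq_along(values) - 1L, value = values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_vertex_map
#' @export
read_vertex_map <- function(path) {
  df <- utils::read.csv(path)
  out <- rep(NA_real_, max(df$vertex_index) + 1L)
  out[df$vertex_index + 1L] <- df$value
  out
}

#' Write / read a vertex x feature matrix as a binary container
#'
#' Little-endian float64 column-major payload (`.bin`) with a JSON sidecar
#' (`.json`) recording dimensions, column names and the undefined-value
#' encoding (NaN).
#'
#' @param m numeric matrix (vertices x features).
#' @param path path of the `.bin` payload; the sidecar replaces the extension
#'   with `.json`.
#' @return `read_vertex_matrix`: the matrix with its column names.
#' @export
write_vertex_matrix <- function(m, path) {
  m <- as.matrix(unclass(m))
  sidecar <- sub("\\.bin$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  con <- file(path, "wb")
  writeBin(as.numeric(m), con, size = 8L, endian = "little")
  close(con)
  jsonlite::write_json(list(n_vertices = nrow(m), n_features = ncol(m),
                            feature_names = colnames(m),
                            dtype = "float64", order = "column-major",
                            undefined = "NaN"),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vertex_matrix
#' @export
read_vertex_matrix <- function(path) {
  sidecar <- sub("\\.bin$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = meta$n_vertices * meta$n_features,
                  size = 8L, endian = "little")
  m <- matrix(vals, meta$n_vertices, meta$n_features)
  colnames(m) <- meta$feature_names
  m
}
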