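#' Read a surface mesh from disk
#'
#' Supported formats: OFF, ASCII PLY (the canonical interchange formats here)
#' and the FreeSurfer binary triangle surface (read-only convenience; the
#' TRIANGLE_FILE dialect with magic bytes 0xFF 0xFF 0xFE). The format is
#' detected from the file header, not the extension. Coordinates are taken as
#' world-space millimetres.
#'
#' @param path file path.
#' @param hemisphere hemisphere tag to attach.
#' @return a `surface_mesh`.
#' @export
read_surface <- function(path, hemisphere = "single") {
  if (!file.exists(path)) stop("surface file does not exist: ", path)
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 3L)
  close(con)
  if (length(magic) < 3L)
    stop(sprintf("truncated surface file %s at byte offset %d", path,
                 length(magic)))
  mesh <- if (identical(as.integer(magic), c(255L, 255L, 254L))) {
    read_surface_fs(path)
  } else {
    head <- readLines(path, n = 1L, warn = FALSE)
    if (grepl("^OFF", head)) {
      read_surface_off(path)
    } else if (grepl("^ply", head)) {
      read_surface_ply(path)
    } else {
      stop(sprintf("unrecognized surface format in %s (byte offset 0)", path))
    }
  }
  mesh$hemisphere <- match.arg(hemisphere, c("left", "right", "single"))
  if (!is_closed_manifold(mesh))
    warning("surface mesh is not a closed manifold (some edges not in exactly 2 faces)")
  mesh
}

read_surface_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!grepl("^OFF", lines[[1]]))
    stop(sprintf("not an OFF file: %s (byte offset 0)", path))
  toks <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  nv <- as.integer(toks[1]); nf <- as.integer(toks[2])
  pos <- 3L  # skip n_edges
  need <- pos + 3L * nv
  if (length(toks) < need)
    stop(sprintf("truncated OFF file %s: expected %d vertex coordinates",
                 path, 3L * nv))
  v <- matrix(toks[(pos + 1):(pos + 3 * nv)], ncol = 3L, byrow = TRUE)
  pos <- pos + 3L * nv
  f <- matrix(NA_integer_, nf, 3L)
  for (k in seq_len(nf)) {
    if (length(toks) < pos + 1L)
      stop(sprintf("truncated OFF file %s in face block (face %d)", path, k))
    deg <- as.integer(toks[pos + 1L])
    if (deg != 3L) stop("only triangle faces are supported (OFF face degree ", deg, ")")
    f[k, ] <- as.integer(toks[(pos + 2):(pos + 4)]) + 1L
    pos <- pos + 4L
  }
  surface_mesh(v, f)
}

read_surface_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- which(trimws(lines) == "end_header")[1]
  if (is.na(endh)) stop(sprintf("PLY header without end_header in %s", path))
  header <- lines[seq_len(endh)]
  if (any(grepl("^format\\s+binary", header)))
    stop("binary PLY is not supported; use ASCII PLY or OFF")
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", header, value = TRUE)[1]))
  body <- lines[-seq_len(endh)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf)
    stop(sprintf("truncated PLY file %s: %d body lines, need %d",
                 path, length(body), nv + nf))
  v <- matrix(scan(text = paste(body[seq_len(nv)], collapse = "\n"),
                   quiet = TRUE), nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  ftok <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), as.integer)
  if (any(vapply(ftok, `[`, integer(1), 1L) != 3L))
    stop("only triangle faces are supported in PLY input")
  f <- do.call(rbind, lapply(ftok, function(t) t[2:4] + 1L))
  surface_mesh(v, f)
}

read_surface_fs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (!identical(magic, c(255L, 255L, 254L)))
    stop(sprintf("not a FreeSurfer triangle surface: %s (byte offset 0)", path))
  # comment line terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L)
      stop(sprintf("truncated FreeSurfer surface %s (byte offset %d)",
                   path, seek(con)))
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  v <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(v) < 3L * nv || length(f) < 3L * nf)
    stop(sprintf("truncated FreeSurfer surface %s (byte offset %d)",
                 path, seek(con)))
  surface_mesh(matrix(v, ncol = 3L, byrow = TRUE),
               matrix(f, ncol = 3L, byrow = TRUE) + 1L)
}

#' Write a surface mesh
#'
#' @param mesh a `surface_mesh`.
#' @param path output path; format from extension: `.off` or `.ply` (ASCII).
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "off") {
    con <- file(path, "wb")  # binary mode: stable LF line endings
    on.exit(close(con))
    writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f))), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (ext == "ply") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else {
    stop("unsupported surface output format: .", ext)
  }
  invisible(path)
}
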