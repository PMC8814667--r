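#' Triangle surface mesh in world coordinates
#'
#' Constructs a `surface_mesh`, the container used for white, pial, depth and
#' white-matter-offset surfaces. Vertex coordinates are world-space millimetres
#' (RAS); faces are 1-based vertex-index triples. White/pial pairs must share
#' the vertex count so that vertex `i` on one surface corresponds to vertex `i`
#' on the other.
#'
#' @param vertices numeric matrix, n x 3, world mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param hemisphere one of `"left"`, `"right"`, `"single"`.
#' @param validate check face indices and basic sanity.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, hemisphere = "single",
                         validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  hemisphere <- match.arg(hemisphere, c("left", "right", "single"))
  if (validate) {
    if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
    if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
    if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
    if (nrow(faces) > 0L) {
      if (min(faces) < 1L || max(faces) > nrow(vertices))
        stop("face index out of range: faces must reference 1..n_vertices")
    }
  }
  structure(list(vertices = vertices, faces = faces, hemisphere = hemisphere),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, hemisphere=%s\n",
              nrow(x$vertices), nrow(x$faces), x$hemisphere))
  ext <- apply(x$vertices, 2L, range)
  cat(sprintf("  extent (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Undirected edge list of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return two-column integer matrix of unique undirected edges (i < j), with
#'   attribute `"count"` giving the number of incident faces per edge.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  uniq <- !duplicated(key)
  out <- e[uniq, , drop = FALSE]
  attr(out, "count") <- as.integer(tab[paste(out[, 1], out[, 2])])
  out
}

#' Check closed-manifold property (every edge in exactly two faces)
#' @param mesh a `surface_mesh`.
#' @return logical scalar.
#' @export
is_closed_manifold <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  all(attr(mesh_edges(mesh), "count") == 2L)
}

#' Outward vertex normals (angle-weighted)
#'
#' Per-vertex unit normals formed by averaging incident face normals weighted
#' by the face corner angle at the vertex — the standard deterministic choice
#' for displacing surfaces along the local outward direction.
#'
#' @param mesh a `surface_mesh` with counter-clockwise (outward) face winding.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e12 <- p2 - p1; e13 <- p3 - p1
  e23 <- p3 - p2; e21 <- -e12
  e31 <- -e13; e32 <- -e23
  fn <- cbind(e12[, 2] * e13[, 3] - e12[, 3] * e13[, 2],
              e12[, 3] * e13[, 1] - e12[, 1] * e13[, 3],
              e12[, 1] * e13[, 2] - e12[, 2] * e13[, 1])
  nf <- sqrt(rowSums(fn^2))
  nf[nf == 0] <- 1
  fn <- fn / nf
  ang <- function(a, b) {
    ca <- rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
    acos(pmin(1, pmax(-1, ca)))
  }
  w1 <- ang(e12, e13); w2 <- ang(e21, e23); w3 <- ang(e31, e32)
  acc <- matrix(0, nrow(v), 3L)
  scatter_add <- function(acc, idx, contrib) {
    agg <- rowsum(contrib, idx)
    rows <- as.integer(rownames(agg))
    acc[rows, ] <- acc[rows, , drop = FALSE] + agg
    acc
  }
  acc <- scatter_add(acc, f[, 1], fn * w1)
  acc <- scatter_add(acc, f[, 2], fn * w2)
  acc <- scatter_add(acc, f[, 3], fn * w3)
  nn <- sqrt(rowSums(acc^2))
  nn[nn == 0] <- 1
  acc / nn
}

#' Vertex adjacency as a sparse matrix
#'
#' @param mesh a `surface_mesh`.
#' @param include_self add the identity (self counted with the weight of one
#'   neighbour), as used by the smoothing iteration.
#' @return sparse pattern matrix (`Matrix::sparseMatrix`) with 0/1 entries.
#' @export
mesh_adjacency <- function(mesh, include_self = FALSE) {
  e <- mesh_edges(mesh)
  n <- n_vertices(mesh)
  i <- c(e[, 1], e[, 2])
  j <- c(e[, 2], e[, 1])
  if (include_self) {
    i <- c(i, seq_len(n))
    j <- c(j, seq_len(n))
  }
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
}

#' Unit icosphere mesh
#'
#' Recursively subdivided icosahedron projected to the unit sphere; the
#' phantom's base geometry. Subdivision level `L` yields `10 * 4^L + 2`
#' vertices (level 4 gives 2562).
#'
#' @param subdivisions non-negative integer subdivision level.
#' @param radius sphere radius in mm.
#' @return a closed, manifold `surface_mesh` with outward winding.
#' @export
icosphere <- function(subdivisions = 4L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- e[, 1] * (nrow(v) + 1) + e[, 2]
    ukey <- unique(key)
    mididx <- nrow(v) + match(key, ukey)
    ue <- e[!duplicated(key), , drop = FALSE]
    mid <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    nf <- nrow(f)
    m12 <- mididx[seq_len(nf)]
    m23 <- mididx[nf + seq_len(nf)]
    m31 <- mididx[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  surface_mesh(v * radius, f)
}
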