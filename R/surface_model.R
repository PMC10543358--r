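#' Triangulated cortical surface mesh
#'
#' Vertices are mm coordinates in the FreeSurfer surface (TKR) frame, faces
#' are 0-based triangles. Normals, mean curvature and named vertex labels
#' (e.g. `"V1"`) are optional and attached by the geometry operations.
#'
#' @param vertices numeric N x 3 matrix (mm).
#' @param faces integer M x 3 matrix of 0-based vertex indices.
#' @param normals optional N x 3 unit normals.
#' @param curvature optional length-N mean curvature (1/mm).
#' @param labels named list of 0-based vertex index vectors.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL, curvature = NULL,
                         labels = list()) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  n <- nrow(vertices)
  if (ncol(vertices) != 3) stopf("vertices must be N x 3")
  if (nrow(faces) && (min(faces) < 0 || max(faces) >= n))
    stopf("face indices out of range [0, %d)", n)
  for (nm in names(labels)) {
    idx <- labels[[nm]]
    if (length(idx) && (min(idx) < 0 || max(idx) >= n))
      stopf("label '%s' has out-of-range vertex indices", nm)
  }
  structure(list(vertices = vertices, faces = faces, normals = normals,
                 curvature = curvature, labels = labels),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces%s%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$normals)) ", normals" else "",
              if (!is.null(x$curvature)) ", curvature" else ""))
  if (length(x$labels))
    cat("  labels:", paste(sprintf("%s (%d)", names(x$labels),
                                   lengths(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

# Per-face geometry shared by the normal and curvature operators.
face_geometry <- function(mesh) {
  f <- mesh$faces + 1L
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a; e3 <- c_ - b
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- row_norms(cr)                     # 2 * face area
  list(f = f, a = a, b = b, c = c_, e1 = e1, e2 = e2, e3 = e3,
       cross = cr, area2 = area2, fnormal = cr / pmax(area2, 1e-300))
}

corner_angle <- function(u, v) {
  # angle between row vectors u and v
  cu <- rowSums(u * v) / pmax(row_norms(u) * row_norms(v), 1e-300)
  acos(pmin(pmax(cu, -1), 1))
}

#' Compute per-vertex normals
#'
#' Each vertex normal is the angle-weighted average of its incident face
#' normals (weights are the face's interior angle at the vertex), normalized
#' to unit length. Orientation follows the face winding. Isolated vertices
#' get `NaN` normals.
#'
#' @param mesh a [surface_mesh] with at least one face.
#' @return the mesh with `$normals` filled in.
#' @export
compute_vertex_normals <- function(mesh) {
  if (!nrow(mesh$faces)) stopf("mesh has no faces; normals undefined")
  g <- face_geometry(mesh)
  if (any(g$area2 <= 0)) stopf("mesh contains degenerate zero-area faces")
  ang1 <- corner_angle(g$b - g$a, g$c - g$a)
  ang2 <- corner_angle(g$a - g$b, g$c - g$b)
  ang3 <- corner_angle(g$a - g$c, g$b - g$c)
  n <- nrow(mesh$vertices)
  acc <- matrix(0, n, 3)
  idx_all <- c(g$f[, 1], g$f[, 2], g$f[, 3])
  w_all <- c(ang1, ang2, ang3)
  nrm_all <- rbind(g$fnormal, g$fnormal, g$fnormal) * w_all
  for (d in 1:3) {
    s <- rowsum(nrm_all[, d], idx_all)
    acc[as.integer(rownames(s)), d] <- s
  }
  lens <- row_norms(acc)
  isolated <- !(seq_len(n) %in% idx_all)
  normals <- acc / pmax(lens, 1e-300)
  normals[isolated | lens < 1e-300, ] <- NaN
  mesh$normals <- normals
  mesh
}

# boundary vertices: endpoints of edges referenced by exactly one face
boundary_vertices <- function(mesh) {
  f <- mesh$faces + 1L
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
             cbind(f[, 3], f[, 1]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bk <- names(cnt)[cnt == 1L]
  if (!length(bk)) return(integer(0))
  unique(as.integer(unlist(strsplit(bk, " "))))
}

#' Compute discrete mean curvature
#'
#' Mean curvature H (1/mm) per interior vertex via the cotangent
#' Laplace–Beltrami operator with mixed Voronoi areas: the magnitude of the
#' mean-curvature normal gives |H| and its sign is taken from the projection
#' onto the vertex normal (positive for a sphere with outward normals).
#' Boundary vertices are set to `NaN`. One-rings whose cotangent weights are
#' numerically degenerate fall back to uniform Laplacian weights (with a
#' message).
#'
#' @param mesh a [surface_mesh]; normals are computed if absent.
#' @return the mesh with `$curvature` filled in.
#' @export
compute_mean_curvature <- function(mesh) {
  if (is.null(mesh$normals)) mesh <- compute_vertex_normals(mesh)
  g <- face_geometry(mesh)
  n <- nrow(mesh$vertices)
  v <- mesh$vertices
  f <- g$f

  cot_of <- function(u, w) {
    # cotangent of angle between row vectors u, w
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    rowSums(u * w) / pmax(row_norms(cr), 1e-300)
  }
  # cotangents at each corner (corner k is opposite edge not containing k)
  cot1 <- cot_of(g$b - g$a, g$c - g$a)   # at vertex f[,1]
  cot2 <- cot_of(g$a - g$b, g$c - g$b)   # at vertex f[,2]
  cot3 <- cot_of(g$a - g$c, g$b - g$c)   # at vertex f[,3]

  # accumulate cotangent Laplacian: for edge (i,j) opposite corner k,
  # contribution cot_k * (x_j - x_i) to vertex i (and symmetric).
  lap <- matrix(0, n, 3)
  add_edge <- function(i, j, w) {
    d <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    wd <- d * w
    for (dd in 1:3) {
      s <- rowsum(wd[, dd], i)
      lap[as.integer(rownames(s)), dd] <<- lap[as.integer(rownames(s)), dd] + s
      s <- rowsum(-wd[, dd], j)
      lap[as.integer(rownames(s)), dd] <<- lap[as.integer(rownames(s)), dd] + s
    }
  }
  add_edge(f[, 2], f[, 3], cot1)
  add_edge(f[, 1], f[, 3], cot2)
  add_edge(f[, 1], f[, 2], cot3)

  # mixed Voronoi areas (Meyer et al. scheme)
  area <- g$area2 / 2
  amix <- numeric(n)
  sq <- function(m) rowSums(m^2)
  l23 <- sq(g$c - g$b); l13 <- sq(g$c - g$a); l12 <- sq(g$b - g$a)
  obtuse1 <- cot1 < 0; obtuse2 <- cot2 < 0; obtuse3 <- cot3 < 0
  any_obtuse <- obtuse1 | obtuse2 | obtuse3
  # non-obtuse: Voronoi area at corner i = (|e_ij|^2 cot_k + |e_ik|^2 cot_j)/8
  a1 <- ifelse(any_obtuse, ifelse(obtuse1, area / 2, area / 4),
               (l12 * cot3 + l13 * cot2) / 8)
  a2 <- ifelse(any_obtuse, ifelse(obtuse2, area / 2, area / 4),
               (l12 * cot3 + l23 * cot1) / 8)
  a3 <- ifelse(any_obtuse, ifelse(obtuse3, area / 2, area / 4),
               (l13 * cot2 + l23 * cot1) / 8)
  for (k in 1:3) {
    s <- rowsum(list(a1, a2, a3)[[k]], f[, k])
    amix[as.integer(rownames(s))] <- amix[as.integer(rownames(s))] + s
  }

  bad <- !is.finite(rowSums(lap)) | amix <= 0
  if (any(bad & amix > 0)) {
    message(sprintf(
      "curvature: uniform-weight fallback at %d degenerate one-ring(s)",
      sum(bad & amix > 0)))
    adj <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)],
                        f[, c(2, 1)], f[, c(3, 2)], f[, c(3, 1)]))
    for (i in which(bad & amix > 0)) {
      nb <- adj[adj[, 1] == i, 2]
      lap[i, ] <- colSums(v[nb, , drop = FALSE]) - length(nb) * v[i, ]
    }
  }

  # mean-curvature normal: Lap(x) = -2 H n (n outward), so the sign of H is
  # the negated projection of the Laplacian onto the vertex normal
  K <- lap / pmax(2 * amix, 1e-300)
  H <- row_norms(K) / 2
  sgn <- -sign(rowSums(K * mesh$normals))
  sgn[sgn == 0] <- 1
  H <- H * sgn
  H[boundary_vertices(mesh)] <- NaN
  H[amix <= 0] <- NaN
  mesh$curvature <- H
  mesh
}

mesh_edge_graph <- function(mesh) {
  f <- mesh$faces + 1L
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  w <- row_norms(mesh$vertices[e[, 1], , drop = FALSE] -
                 mesh$vertices[e[, 2], , drop = FALSE])
  g <- igraph::make_empty_graph(n = nrow(mesh$vertices), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(e)))
  igraph::E(g)$weight <- w
  g
}

#' Geodesic distance over the mesh edge graph
#'
#' Shortest-path (Dijkstra) distance along mesh edges with Euclidean edge
#' weights, in mm. This graph geodesic upper-bounds the exact polyhedral
#' geodesic; the overestimate is bounded by the mesh anisotropy and is
#' negligible at the mm scales of interest here.
#'
#' @param mesh a [surface_mesh].
#' @param src 0-based source vertex index.
#' @param dst 0-based destination vertex indices.
#' @return numeric vector of distances (mm), `Inf` (with a warning) for
#'   destinations disconnected from `src`.
#' @export
geodesic_distance <- function(mesh, src, dst) {
  g <- mesh_edge_graph(mesh)
  d <- igraph::distances(g, v = src + 1L, to = dst + 1L,
                         algorithm = "dijkstra")[1, ]
  if (any(is.infinite(d)))
    warnf("%d destination vertex(es) unreachable from source",
          sum(is.infinite(d)))
  unname(d)
}

#' Vertices that fall inside a binary volume mask
#'
#' Maps each vertex through `world_from_tkr` into the grid's world frame,
#' converts to voxel indices through the inverse of the grid's `vox2world`,
#' and keeps vertices whose nearest voxel is inside the grid and has value 1.
#'
#' @param mesh a [surface_mesh].
#' @param grid a binary [volume_grid].
#' @param world_from_tkr `affine_transform` from `surface_tkr` to the grid's
#'   world frame.
#' @return 0-based vertex indices (vertices mapping outside the grid are
#'   silently excluded).
#' @export
vertices_in_volume_mask <- function(mesh, grid, world_from_tkr) {
  world <- apply_transform(world_from_tkr, mesh$vertices)
  vox <- apply_transform(invert_transform(grid$vox2world), world)
  ijk <- round(vox) + 1  # to 1-based array indices
  shape <- grid$shape[1:3]
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= shape[1] &
            ijk[, 2] >= 1 & ijk[, 2] <= shape[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= shape[3]
  hit <- rep(FALSE, nrow(ijk))
  if (any(inside)) {
    lin <- (ijk[inside, 3] - 1) * shape[1] * shape[2] +
           (ijk[inside, 2] - 1) * shape[1] + ijk[inside, 1]
    hit[inside] <- as.numeric(grid$data)[lin] == 1
  }
  which(hit) - 1L
}

#' Per-vertex summary statistics written as TSV
#'
#' Convenience export of vertex index, coordinates, normal and curvature,
#' the quantities the line-planning workflow consumes.
#' @param mesh a [surface_mesh] (normals/curvature computed if absent).
#' @param path output TSV path.
#' @export
surface_stats <- function(mesh, path = NULL) {
  if (is.null(mesh$normals)) mesh <- compute_vertex_normals(mesh)
  if (is.null(mesh$curvature)) mesh <- compute_mean_curvature(mesh)
  df <- data.frame(vertex = seq_len(nrow(mesh$vertices)) - 1L,
                   x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                   z = mesh$vertices[, 3],
                   nx = mesh$normals[, 1], ny = mesh$normals[, 2],
                   nz = mesh$normals[, 3], curvature = mesh$curvature)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
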