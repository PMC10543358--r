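#' Dispersion of a point under repeated transforms
#'
#' Applies each transform to `point` and summarizes the Euclidean distances
#' to `reference` (which defaults to the point itself). This quantifies the
#' positional variability of a target coordinate under repeated
#' between-session registrations.
#'
#' @param transforms list of `affine_transform`s.
#' @param point length-3 mm coordinate.
#' @param reference length-3 mm reference coordinate (default: `point`).
#' @return a `dispersion_report`: list with `distances`, `mean`, `sd`,
#'   `max` (mm).
#' @export
point_dispersion <- function(transforms, point, reference = point) {
  if (!length(transforms)) stopf("need at least one transform")
  dists <- vapply(transforms, function(x)
    vnorm(as.numeric(apply_transform(x, point)) - reference), numeric(1))
  structure(list(distances = dists, mean = mean(dists),
                 sd = if (length(dists) > 1) stats::sd(dists) else 0,
                 max = max(dists)),
            class = "dispersion_report")
}

#' @export
print.dispersion_report <- function(x, ...) {
  cat(sprintf("<dispersion_report: n=%d, mean %.3f mm, sd %.3f, max %.3f>\n",
              length(x$distances), x$mean, x$sd, x$max))
  invisible(x)
}

#' Target displacement under run-to-run motion transforms
#'
#' As [point_dispersion()], with each distance labelled by run.
#' @param run_transforms list of per-run `affine_transform`s.
#' @param target length-3 mm target coordinate.
#' @export
motion_displacement <- function(run_transforms, target) {
  rep <- point_dispersion(run_transforms, target)
  names(rep$distances) <- paste0("run", seq_along(rep$distances))
  rep
}

#' Curvature distribution within the back-projected line
#'
#' Summarizes absolute mean curvature over the vertices the nominal line
#' intersects (flatness is the planning objective, so magnitudes are
#' reported).
#'
#' @param mesh a [surface_mesh] with curvature.
#' @param line_vertices 0-based vertex indices.
#' @return list with `mean`, `sd`, `values` (1/mm).
#' @export
curvature_in_line <- function(mesh, line_vertices) {
  if (!length(line_vertices)) stopf("line vertex set is empty")
  if (is.null(mesh$curvature)) stopf("curvature not computed on mesh")
  v <- abs(mesh$curvature[line_vertices + 1L])
  v <- v[is.finite(v)]
  if (!length(v)) stopf("no finite curvature values in the line")
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       values = v)
}

#' Tissue fractions inside the line mask
#'
#' Percentages of gray matter, white matter and CSF among the labelled
#' voxels of `seg` that fall inside `line_mask` (background / label 0 is
#' excluded; percentages sum to 100).
#'
#' @param seg a [volume_grid] of integer labels (1 = GM, 2 = WM, 3 = CSF by
#'   default).
#' @param line_mask a binary [volume_grid] aligned with `seg`.
#' @param labels named integer vector mapping class names to label values.
#' @return named numeric vector of percentages `c(GM=, WM=, CSF=)`.
#' @export
tissue_fractions <- function(seg, line_mask,
                             labels = c(GM = 1L, WM = 2L, CSF = 3L)) {
  if (!all(seg$shape == line_mask$shape))
    stopf("segmentation and mask grids are not aligned")
  inside <- seg$data[line_mask$data == 1]
  inside <- inside[inside %in% labels]
  if (!length(inside)) stopf("no labelled voxels inside the line mask")
  counts <- vapply(labels, function(l) sum(inside == l), numeric(1))
  100 * counts / sum(counts)
}

#' Best-matching vertex between line and whole-brain pRF estimates
#'
#' For every finite vertex of the pRF map (restricted to `candidates` when
#' given), computes the visual-field distance between that vertex's pRF
#' center and the line-scanning pRF center; the match is the argmin (ties
#' broken by smaller geodesic distance to the target, then lower index).
#' Reports the Euclidean (scanner-frame chord) and geodesic distances from
#' match to target in mm — the functional targeting-accuracy metric.
#'
#' @param prf_map `prf_map` paired to `mesh`.
#' @param line_prf [prf_params] estimated from the line data.
#' @param mesh a [surface_mesh].
#' @param target a `target_vertex`.
#' @param candidates 0-based vertex indices to search (default: the mesh's
#'   `"V1"` label when present, else all vertices).
#' @return a `match_report`: list with `target_index`, `match_index`,
#'   `visual_distance` (degrees), `euclid_mm`, `geodesic_mm`,
#'   `per_vertex_visual_distance`.
#' @export
best_match_distance <- function(prf_map, line_prf, mesh, target,
                                candidates = NULL) {
  pair_prf_map(prf_map, mesh)
  if (is.null(candidates)) {
    candidates <- if ("V1" %in% names(mesh$labels)) mesh$labels[["V1"]]
                  else seq_len(nrow(mesh$vertices)) - 1L
  }
  idx <- candidates + 1L
  dx <- prf_map$x0[idx] - line_prf$x0
  dy <- prf_map$y0[idx] - line_prf$y0
  vd <- sqrt(dx^2 + dy^2)
  finite <- is.finite(vd)
  if (!any(finite)) stopf("no vertices with finite pRF centers")
  vmin <- min(vd[finite])
  tied <- which(finite & vd <= vmin + 1e-12)
  if (length(tied) > 1) {
    geo <- geodesic_distance(mesh, target$index, candidates[tied])
    tied <- tied[order(geo, candidates[tied])]
  }
  match_i <- candidates[tied[1]]
  euclid <- vnorm(mesh$vertices[match_i + 1L, ] -
                  mesh$vertices[target$index + 1L, ])
  geod <- geodesic_distance(mesh, target$index, match_i)
  structure(list(target_index = target$index, match_index = match_i,
                 visual_distance = vmin, euclid_mm = euclid,
                 geodesic_mm = geod,
                 per_vertex_visual_distance =
                   stats::setNames(vd, candidates)),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report: target %d, match %d; visual %.3f deg, euclid %.2f mm, geodesic %.2f mm>\n",
    x$target_index, x$match_index, x$visual_distance, x$euclid_mm,
    x$geodesic_mm))
  invisible(x)
}

#' Paired t test and Cohen's D for paired samples
#'
#' On the difference scores `d = a - b`: `t = mean(d) / (sd(d)/sqrt(n))`
#' with `n - 1` degrees of freedom, two-sided p from the Student t
#' distribution, and `D = mean(d)/sd(d)` (Cohen's D computed on the
#' differences).
#'
#' @param a,b paired numeric vectors of equal length (>= 2).
#' @return list with `t`, `df`, `p`, `cohens_d`, `n`.
#' @export
paired_comparison <- function(a, b) {
  if (length(a) != length(b)) stopf("a and b must be paired (equal length)")
  n <- length(a)
  if (n < 2) stopf("need at least 2 pairs")
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0))
      return(list(t = 0, df = n - 1, p = 1, cohens_d = 0, n = n))
    stopf("zero-variance non-zero differences: t undefined")
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1,
       p = 2 * stats::pt(-abs(t), df = n - 1),
       cohens_d = mean(d) / sdd, n = n)
}
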