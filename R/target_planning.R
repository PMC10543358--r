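#' Eligible target vertices under pRF and label criteria
#'
#' A vertex is eligible when it lies in the named label (typically `"V1"`),
#' its pRF eccentricity is below `ecc_max`, its variance explained is at
#' least `r2_min`, and its parameters are finite. The variance-explained
#' threshold is subject-dependent in practice (commonly 0.35-0.7) and is
#' taken as input, never auto-selected.
#'
#' @param prf_map a `prf_map` paired to the mesh (one row per vertex).
#' @param mesh a [surface_mesh] carrying the label.
#' @param label label name to search within.
#' @param ecc_max maximum pRF eccentricity (degrees; default 3).
#' @param r2_min minimum variance explained.
#' @return 0-based vertex indices; an error with per-criterion counts when
#'   empty.
#' @export
eligible_vertices <- function(prf_map, mesh, label = "V1", ecc_max = 3,
                              r2_min = 0.35) {
  if (!label %in% names(mesh$labels))
    stopf("label '%s' not present on mesh (have: %s)", label,
          paste(names(mesh$labels), collapse = ", "))
  pair_prf_map(prf_map, mesh)
  idx <- mesh$labels[[label]] + 1L
  x0 <- prf_map$x0[idx]; y0 <- prf_map$y0[idx]
  sg <- prf_map$sigma[idx]; r2 <- prf_map$r2[idx]
  finite <- is.finite(x0) & is.finite(y0) & is.finite(sg) & is.finite(r2)
  ecc <- sqrt(x0^2 + y0^2)
  ok_ecc <- finite & ecc < ecc_max
  ok_r2 <- finite & r2 >= r2_min
  keep <- ok_ecc & ok_r2
  if (!any(keep))
    stopf(paste0("no eligible vertices in '%s' (%d total): ",
                 "%d finite, %d pass ecc < %g, %d pass r2 >= %g"),
          label, length(idx), sum(finite), sum(ok_ecc), ecc_max,
          sum(ok_r2), r2_min)
  sort(idx[keep] - 1L)
}

#' Select the target vertex: flattest eligible cortex
#'
#' Among the eligible vertices, picks the one with minimal absolute mean
#' curvature (flattest cortex — the quantity a perpendicular line placement
#' benefits from), ties broken by lowest vertex index. Set
#' `use_abs = FALSE` to minimize signed curvature instead.
#'
#' @param mesh a [surface_mesh] with curvature computed.
#' @param eligible 0-based vertex indices.
#' @param prf_map optional `prf_map` to attach the vertex's pRF.
#' @param use_abs minimize `|H|` (default) or signed `H`.
#' @return a `target_vertex`: list with `index` (0-based), `coord_tkr`,
#'   `normal`, `curvature`, `prf`.
#' @export
select_target_vertex <- function(mesh, eligible, prf_map = NULL,
                                 use_abs = TRUE) {
  if (!length(eligible)) stopf("eligible set is empty")
  if (is.null(mesh$curvature)) stopf("curvature not computed on mesh")
  if (is.null(mesh$normals)) mesh <- compute_vertex_normals(mesh)
  crit <- mesh$curvature[eligible + 1L]
  if (use_abs) crit <- abs(crit)
  if (all(is.na(crit))) stopf("curvature is NaN on every eligible vertex")
  # lowest-index tie-break: eligible is sorted, which.min takes the first
  eligible <- sort(eligible)
  crit <- mesh$curvature[eligible + 1L]
  if (use_abs) crit <- abs(crit)
  best <- eligible[which.min(crit)]
  prf <- if (!is.null(prf_map))
    prf_params(prf_map$x0[best + 1L], prf_map$y0[best + 1L],
               prf_map$sigma[best + 1L], r2 = prf_map$r2[best + 1L])
  else NULL
  structure(list(index = best,
                 coord_tkr = mesh$vertices[best + 1L, ],
                 coord_scanner = NULL,
                 normal = mesh$normals[best + 1L, ],
                 curvature = mesh$curvature[best + 1L],
                 prf = prf),
            class = "target_vertex")
}

#' @export
print.target_vertex <- function(x, ...) {
  cat(sprintf("<target_vertex %d: curvature %.4f 1/mm>\n", x$index,
              x$curvature))
  cat("  coord_tkr:", paste(sprintf("%.2f", x$coord_tkr), collapse = ", "),
      "mm\n")
  if (!is.null(x$coord_scanner))
    cat("  coord_scanner:",
        paste(sprintf("%.2f", x$coord_scanner), collapse = ", "), "mm\n")
  invisible(x)
}

#' Convert a surface (TKR) coordinate to scanner RAS
#'
#' Uses the anatomical volume's two voxel-to-world matrices:
#' `scanner = vox2ras %*% inv(vox2ras_tkr) %*% coord`.
#'
#' @param coord length-3 mm coordinate (or N x 3 matrix) in `surface_tkr`.
#' @param vox2ras `affine_transform` voxel -> `scanner_ras`.
#' @param vox2ras_tkr `affine_transform` voxel -> `surface_tkr`.
#' @return coordinate(s) in scanner RAS (mm).
#' @export
tkr_to_scanner <- function(coord, vox2ras, vox2ras_tkr) {
  if (!identical(vox2ras$source_frame, "voxel") ||
      !identical(vox2ras_tkr$source_frame, "voxel"))
    stopf("both affines must map from the 'voxel' frame")
  if (!identical(vox2ras$dest_frame, "scanner_ras"))
    stopf("vox2ras must map to 'scanner_ras'")
  if (!identical(vox2ras_tkr$dest_frame, "surface_tkr"))
    stopf("vox2ras_tkr must map to 'surface_tkr'")
  xfm <- compose_transforms(vox2ras, invert_transform(vox2ras_tkr))
  apply_transform(xfm, coord)
}

# polar factor of a 3x3 matrix (nearest rotation, unit determinant)
polar_rotation <- function(m) {
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    s$u[, 3] <- -s$u[, 3]
    r <- s$u %*% t(s$v)
  }
  r
}

#' Map a target vertex into another session's frame
#'
#' Applies a between-session registration to the target coordinate
#' (homogeneous transform) and to the normal (rotation block only, no
#' translation, renormalized). The mapping direction of the registration
#' file is declared by the caller and never guessed.
#'
#' @param target a `target_vertex` with `coord_scanner` set.
#' @param reg an `affine_transform` (rigid expected).
#' @param direction `"forward"` applies `reg` as-is, `"inverse"` applies
#'   its inverse.
#' @return the target with mapped `coord_scanner` and `normal`.
#' @export
map_target_between_sessions <- function(target, reg,
                                        direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (is.null(target$coord_scanner))
    stopf("target has no scanner coordinate; run tkr_to_scanner first")
  if (direction == "inverse") reg <- invert_transform(reg)
  rot <- reg$matrix[1:3, 1:3]
  if (!is_rigid(reg)) {
    warnf("registration is not rigid; normal mapped through its polar rotation")
    rot <- polar_rotation(rot)
  }
  target$coord_scanner <- as.numeric(apply_transform(reg, target$coord_scanner))
  nrm <- as.numeric(rot %*% target$normal)
  target$normal <- nrm / vnorm(nrm)
  target
}

#' Angles between a line direction and the cardinal axes
#'
#' The angle of the (unoriented) line to each of the left-right, anterior-
#' posterior and foot-head axes, by the rule of cosines:
#' `theta_i = acos(|n . e_i| / ||n||)`, reported in degrees in `[0, 90]`.
#'
#' @param normal length-3 direction vector (need not be unit).
#' @return named numeric vector `c(LR=, AP=, FH=)` in degrees.
#' @export
normal_to_cardinal_angles <- function(normal) {
  n <- vnorm(normal)
  if (n == 0) stopf("zero direction vector")
  ang <- acos(pmin(abs(normal) / n, 1)) * 180 / pi
  stats::setNames(ang, c("LR", "AP", "FH"))
}

#' Choose the base slice orientation for a line direction
#'
#' Coronal by default; sagittal when the line's angle to the left-right axis
#' exceeds 45 degrees (a line mostly along the AP axis cannot lie in a
#' coronal plane at a reasonable angulation). Exactly 45 degrees stays
#' coronal.
#'
#' @param angles_cardinal named angles from [normal_to_cardinal_angles()].
#' @return `"coronal"` or `"sagittal"`.
#' @export
choose_slice_orientation <- function(angles_cardinal) {
  if (angles_cardinal[["LR"]] > 45) "sagittal" else "coronal"
}

# Base-slice frames (scanner RAS axes x=LR, y=AP, z=FH).
# u = in-plane frequency-encoding axis, v = second in-plane axis,
# w = through-plane axis.
slice_frame <- function(base_orientation) {
  switch(base_orientation,
         coronal = list(u = c(1, 0, 0), v = c(0, 0, 1), w = c(0, 1, 0)),
         sagittal = list(u = c(0, 1, 0), v = c(0, 0, 1), w = c(1, 0, 0)),
         stopf("unknown base orientation '%s'", base_orientation))
}

# Decompose direction d into two rotations (a1 about u, applied second;
# a2 about v, applied first) taking the frequency axis u onto d:
#   d = cos(a2) u + sin(a1) sin(a2) v - cos(a1) sin(a2) w
angulation_from_direction <- function(direction, base_orientation) {
  fr <- slice_frame(base_orientation)
  d <- direction / vnorm(direction)
  p <- sum(d * fr$u); q <- sum(d * fr$v); r <- sum(d * fr$w)
  if (p < 0) { p <- -p; q <- -q; r <- -r }  # unoriented line: fold to u >= 0
  a2 <- acos(pmin(pmax(p, -1), 1))
  a1 <- if (abs(sin(a2)) < 1e-12) 0 else atan2(q, -r)
  c(a1, a2) * 180 / pi
}

direction_from_angulation <- function(angulation, base_orientation) {
  fr <- slice_frame(base_orientation)
  a1 <- angulation[1] * pi / 180
  a2 <- angulation[2] * pi / 180
  cos(a2) * fr$u + sin(a1) * sin(a2) * fr$v - cos(a1) * sin(a2) * fr$w
}

#' Plan the line placement for a target vertex
#'
#' Translates a scanner-frame target (coordinate + unit normal) into the
#' console-facing placement: line center, base slice orientation
#' (coronal/sagittal rule), the two angulation rotations that take the base
#' slice's frequency-encoding axis onto the line direction, the cardinal-
#' axis angles, and the nominal line geometry.
#'
#' @param target a `target_vertex` with `coord_scanner` and `normal`.
#' @param gap_mm gap between the outer-volume-suppression bands (nominal
#'   line length; default 4).
#' @param slice_thickness_mm slice thickness (default 2.5).
#' @param line_res_mm resolution along the line (default 0.25).
#' @return a `line_plan` with fields `center`, `direction`,
#'   `base_orientation`, `angles_cardinal`, `angulation`, `gap_mm`,
#'   `slice_thickness_mm`, `line_res_mm`.
#' @export
plan_line <- function(target, gap_mm = 4, slice_thickness_mm = 2.5,
                      line_res_mm = 0.25) {
  if (is.null(target$coord_scanner))
    stopf("target has no scanner coordinate; run tkr_to_scanner first")
  d <- target$normal
  if (!all(is.finite(d)) || vnorm(d) == 0) stopf("degenerate target normal")
  d <- d / vnorm(d)
  ang <- normal_to_cardinal_angles(d)
  base <- choose_slice_orientation(ang)
  angulation <- angulation_from_direction(d, base)
  # canonical (unoriented) direction as reconstructed from the parameters
  drec <- direction_from_angulation(angulation, base)
  structure(list(center = as.numeric(target$coord_scanner),
                 direction = drec,
                 base_orientation = base,
                 angles_cardinal = ang,
                 angulation = angulation,
                 gap_mm = gap_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 line_res_mm = line_res_mm),
            class = "line_plan")
}

#' @export
print.line_plan <- function(x, ...) {
  cat(sprintf("<line_plan: %s base, angulation (%.2f, %.2f) deg>\n",
              x$base_orientation, x$angulation[1], x$angulation[2]))
  cat("  center:", paste(sprintf("%.2f", x$center), collapse = ", "), "mm\n")
  cat("  angles to (LR, AP, FH):",
      paste(sprintf("%.1f", x$angles_cardinal), collapse = ", "), "deg\n")
  invisible(x)
}

#' Reconstruct the line direction from a plan's orientation parameters
#' @param plan a `line_plan`.
#' @return unit direction vector in scanner RAS.
#' @export
plan_direction <- function(plan) {
  direction_from_angulation(plan$angulation, plan$base_orientation)
}

#' Serialize / deserialize a line plan as JSON
#' @param plan a `line_plan`.
#' @param path output path.
#' @export
write_line_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_line_plan
#' @export
read_line_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$angles_cardinal <- stats::setNames(as.numeric(p$angles_cardinal),
                                       c("LR", "AP", "FH"))
  structure(p, class = "line_plan")
}

#' Binary nominal-line mask on a slice grid
#'
#' The nominal line is the band between the suppression pulses: the central
#' `round(gap_mm / phase_res)` voxels along the phase-encoding axis, at full
#' extent along the frequency-encoding axis. With the default 4 mm gap at
#' 0.25 mm phase resolution the band is 16 voxels wide. When the band cannot
#' be perfectly centered, the extra voxel goes on the lower-index side.
#'
#' @param slice_grid a [volume_grid] whose first axis is phase encoding and
#'   second axis frequency encoding (third axis, if present, slice
#'   thickness).
#' @param gap_mm suppression-band gap (mm).
#' @param phase_res_mm voxel size along the phase axis (mm); defaults to the
#'   grid's voxel spacing on axis 1.
#' @return a binary [volume_grid] of the same geometry.
#' @export
build_nominal_line_mask <- function(slice_grid, gap_mm = 4,
                                    phase_res_mm = NULL) {
  shape <- slice_grid$shape
  if (is.null(phase_res_mm))
    phase_res_mm <- vnorm(slice_grid$vox2world$matrix[1:3, 1])
  n_phase <- shape[1]
  extent <- n_phase * phase_res_mm
  if (gap_mm > extent + 1e-9)
    stopf("gap (%g mm) exceeds the phase-axis field of view (%g mm)",
          gap_mm, extent)
  n_band <- max(1L, as.integer(round(gap_mm / phase_res_mm)))
  n_band <- min(n_band, n_phase)
  start <- floor((n_phase - n_band) / 2) + 1L
  mask <- array(0L, dim = shape)
  idx <- as.list(rep(TRUE, length(shape)))
  idx[[1]] <- start:(start + n_band - 1L)
  mask <- do.call(`[<-`, c(list(mask), idx, list(value = 1L)))
  volume_grid(mask, slice_grid$vox2world)
}

#' Build the slice grid of a planned line in scanner space
#'
#' Constructs a slice-aligned [volume_grid] centered on the plan's line
#' center, with the frequency axis along the line direction and the phase
#' axis in-plane perpendicular to it, for nominal-mask construction and
#' back-projection onto the surface.
#'
#' @param plan a `line_plan`.
#' @param fov_mm in-plane field of view (mm).
#' @param phase_res_mm phase-axis voxel size (mm).
#' @return a [volume_grid] of zeros with correct geometry (phase axis 1,
#'   frequency axis 2, slice axis 3).
#' @export
plan_slice_grid <- function(plan, fov_mm = 40, phase_res_mm = 0.25) {
  freq <- plan_direction(plan)
  fr <- slice_frame(plan$base_orientation)
  w <- fr$w                        # through-plane axis of the base slice
  phase <- c(freq[2] * w[3] - freq[3] * w[2],
             freq[3] * w[1] - freq[1] * w[3],
             freq[1] * w[2] - freq[2] * w[1])
  phase <- phase / vnorm(phase)
  thr <- c(freq[2] * phase[3] - freq[3] * phase[2],
           freq[3] * phase[1] - freq[1] * phase[3],
           freq[1] * phase[2] - freq[2] * phase[1])
  n_inplane <- as.integer(round(fov_mm / phase_res_mm))
  shape <- c(n_inplane, n_inplane, 1L)
  m <- diag(4)
  m[1:3, 1] <- phase * phase_res_mm
  m[1:3, 2] <- freq * phase_res_mm
  m[1:3, 3] <- thr * plan$slice_thickness_mm
  # voxel (i,j,k) 0-based; center the grid on the plan center
  ctr_vox <- c((n_inplane - 1) / 2, (n_inplane - 1) / 2, 0)
  m[1:3, 4] <- plan$center - m[1:3, 1:3] %*% ctr_vox
  volume_grid(array(0L, dim = shape),
              affine_transform(m, "voxel", "scanner_ras"))
}
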