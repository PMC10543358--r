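# vertex selection and scanner-frame line placement

make_labeled_map <- function(n, seed = 1) {
  set.seed(seed)
  prf_map(data.frame(x0 = rnorm(n, sd = 2), y0 = rnorm(n, sd = 2),
                     sigma = runif(n, 0.2, 2), r2 = runif(n)))
}

test_that("eligibility filtering matches an exhaustive oracle", {
  mesh <- make_folded_sheet(10, 10, fold_amplitude = 1, fold_wavelength = 10,
                            spacing = 1, v1_band_fraction = 1)
  map <- make_labeled_map(100, seed = 3)
  map$sigma[c(4, 40)] <- NaN
  ecc_max <- 2.2; r2_min <- 0.4
  got <- eligible_vertices(map, mesh, "V1", ecc_max, r2_min)
  # oracle: explicit per-vertex loop over every criterion
  want <- c()
  for (v in mesh$labels$V1) {
    i <- v + 1
    if (all(is.finite(c(map$x0[i], map$y0[i], map$sigma[i], map$r2[i]))) &&
        sqrt(map$x0[i]^2 + map$y0[i]^2) < ecc_max && map$r2[i] >= r2_min)
      want <- c(want, v)
  }
  expect_identical(got, as.integer(sort(want)))
  expect_gt(length(got), 0)

  # no thresholds -> the whole finite label
  all_v <- eligible_vertices(map, mesh, "V1", Inf, -Inf)
  expect_identical(all_v,
                   as.integer(sort(mesh$labels$V1[
                     is.finite(map$sigma[mesh$labels$V1 + 1])])))
  # impossible threshold -> informative error
  expect_error(eligible_vertices(map, mesh, "V1", 3, 1.1),
               "no eligible vertices")
  expect_error(eligible_vertices(map, mesh, "V9"), "label 'V9'")
})

test_that("target selection minimizes |curvature| with index tie-break", {
  mesh <- compute_mean_curvature(compute_vertex_normals(
    make_folded_sheet(25, 12, fold_amplitude = 2, fold_wavelength = 12,
                      spacing = 0.8)))
  # hand-set curvatures on a three-vertex eligible set
  m2 <- mesh
  elig <- c(10L, 20L, 30L)
  m2$curvature[elig + 1L] <- c(0.2, -0.01, 0.05)
  expect_equal(select_target_vertex(m2, elig)$index, 20L)
  # singleton
  expect_equal(select_target_vertex(mesh, 40L)$index, 40L)
  # brute-force argmin oracle on a large random eligible set
  set.seed(17)
  elig <- sort(sample(interior_vertices(mesh), 150))
  target <- select_target_vertex(mesh, elig)
  oracle <- elig[order(abs(mesh$curvature[elig + 1L]), elig)][1]
  expect_equal(target$index, oracle)
  expect_equal(sqrt(sum(target$normal^2)), 1, tolerance = 1e-6)
  # all-NaN curvature errors
  m3 <- mesh; m3$curvature[] <- NaN
  expect_error(select_target_vertex(m3, elig), "NaN")
})

test_that("TKR to scanner conversion composes the two volume affines", {
  v2r <- affine_transform(rbind(c(1, 0, 0, -5), c(0, 0, 1, 3),
                                c(0, -1, 0, 7), c(0, 0, 0, 1)),
                          "voxel", "scanner_ras")
  v2rt_same <- affine_transform(v2r$matrix, "voxel", "surface_tkr")
  co <- c(4, -2, 9)
  expect_equal(tkr_to_scanner(co, v2r, v2rt_same), co)

  # vox2ras differing by a translation shifts the coordinate by it
  m <- v2r$matrix; m[1:3, 4] <- m[1:3, 4] + c(1, -2, 3)
  v2r_t <- affine_transform(m, "voxel", "scanner_ras")
  expect_equal(tkr_to_scanner(co, v2r_t, v2rt_same), co + c(1, -2, 3))

  # random invertible pair: scanner -> tkr -> scanner is the identity
  set.seed(23)
  for (i in 1:20) {
    a <- random_rigid(i)
    b <- random_rigid(i + 100)
    v2ras <- affine_transform(a$matrix, "voxel", "scanner_ras")
    v2tkr <- affine_transform(b$matrix, "voxel", "surface_tkr")
    x <- rnorm(3, sd = 20)
    fwd <- tkr_to_scanner(x, v2ras, v2tkr)
    back <- apply_transform(
      compose_transforms(v2tkr, invert_transform(v2ras)), fwd)
    expect_equal(as.numeric(back), x, tolerance = 1e-9)
  }
  expect_error(tkr_to_scanner(co, v2rt_same, v2rt_same), "scanner_ras")
})

test_that("between-session mapping moves coordinates and rotates normals", {
  tgt <- structure(list(index = 0L, coord_tkr = c(0, 0, 0),
                        coord_scanner = c(10, -5, 2),
                        normal = c(0, 1, 0), curvature = 0, prf = NULL),
                   class = "target_vertex")
  ident <- affine_transform(diag(4))
  out <- map_target_between_sessions(tgt, ident)
  expect_equal(out$coord_scanner, tgt$coord_scanner)
  expect_equal(out$normal, tgt$normal)

  m <- diag(4); m[1:3, 4] <- c(1, 2, 3)
  out <- map_target_between_sessions(tgt, affine_transform(m))
  expect_equal(out$coord_scanner, c(11, -3, 5))
  expect_equal(out$normal, c(0, 1, 0))

  # 30-degree rotation about z, verified against the closed-form matrix
  th <- 30 * pi / 180
  rz <- diag(4)
  rz[1:2, 1:2] <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  out <- map_target_between_sessions(tgt, affine_transform(rz))
  expect_equal(out$normal, c(-sin(th), cos(th), 0), tolerance = 1e-12)
  ang <- acos(sum(out$normal * tgt$normal))
  expect_equal(ang, th, tolerance = 1e-12)

  # inverse direction flag undoes the forward mapping
  fwd <- map_target_between_sessions(tgt, affine_transform(rz))
  back <- map_target_between_sessions(fwd, affine_transform(rz), "inverse")
  expect_equal(back$coord_scanner, tgt$coord_scanner, tolerance = 1e-12)

  # non-rigid registration warns and uses the polar rotation for the normal
  s <- diag(c(2, 1, 1, 1))
  expect_warning(out <- map_target_between_sessions(tgt, affine_transform(s)),
                 "not rigid")
  expect_equal(sqrt(sum(out$normal^2)), 1, tolerance = 1e-12)
})

test_that("cardinal angles match direct arccos on random unit vectors", {
  expect_equal(unname(normal_to_cardinal_angles(c(0, 1, 0))), c(90, 0, 90))
  expect_equal(unname(normal_to_cardinal_angles(c(1, 1, 0) / sqrt(2))),
               c(45, 45, 90), tolerance = 1e-12)
  expect_error(normal_to_cardinal_angles(c(0, 0, 0)), "zero")
  set.seed(41)
  for (i in 1:1000) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    got <- normal_to_cardinal_angles(n)
    want <- acos(abs(n)) * 180 / pi
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("slice orientation follows the 45-degree left-right rule", {
  expect_equal(choose_slice_orientation(c(LR = 30, AP = 70, FH = 68.4)),
               "coronal")
  expect_equal(choose_slice_orientation(c(LR = 60, AP = 40, FH = 66.2)),
               "sagittal")
  expect_equal(choose_slice_orientation(c(LR = 45, AP = 45, FH = 90)),
               "coronal")
})

test_that("angulation parameterization round-trips the line direction", {
  mk_target <- function(n) structure(
    list(index = 0L, coord_tkr = c(0, 0, 0), coord_scanner = c(1, 2, 3),
         normal = n / sqrt(sum(n^2)), curvature = 0, prf = NULL),
    class = "target_vertex")

  # normal along the coronal frequency axis (LR) -> zero angulation
  plan <- plan_line(mk_target(c(1, 0, 0)))
  expect_equal(plan$base_orientation, "coronal")
  expect_equal(unname(plan$angulation), c(0, 0), tolerance = 1e-12)

  # normal along FH with a coronal base: the frequency axis is rotated 90
  # degrees within the slice plane and the direction reconstructs exactly
  ang_fh <- linetarget:::angulation_from_direction(c(0, 0, 1), "coronal")
  expect_equal(ang_fh[2], 90, tolerance = 1e-9)
  drec <- linetarget:::direction_from_angulation(ang_fh, "coronal")
  expect_equal(abs(sum(drec * c(0, 0, 1))), 1, tolerance = 1e-9)
  # the planner itself picks sagittal for an FH line (LR angle 90 > 45) and
  # still reconstructs the direction
  plan <- plan_line(mk_target(c(1e-9, 0, 1)))
  expect_equal(plan$base_orientation, "sagittal")
  expect_equal(abs(sum(plan_direction(plan) * c(0, 0, 1))), 1,
               tolerance = 1e-6)

  # 500 random normals: reconstruction within 1e-6 rad, in-plane rule holds
  set.seed(55)
  for (i in 1:500) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    plan <- plan_line(mk_target(n))
    d <- plan_direction(plan)
    err <- acos(pmin(abs(sum(d * n)), 1))
    expect_lt(err, 1e-6)
    # direction never leaves the chosen base slice plane by more than 45 deg
    fr <- linetarget:::slice_frame(plan$base_orientation)
    out_of_plane <- asin(pmin(abs(sum(d * fr$w)), 1)) * 180 / pi
    expect_lte(out_of_plane, 45 + 1e-9)
  }
})

test_that("planned lines are perpendicular to the synthetic cortex", {
  lam <- 20
  mesh <- make_folded_sheet(nx = 100, ny = 20, fold_amplitude = 2,
                            fold_wavelength = lam, spacing = 0.3)
  mesh <- compute_mean_curvature(compute_vertex_normals(mesh))
  map <- make_retinotopy(mesh, seed = 5)
  elig <- eligible_vertices(map, mesh, "V1", ecc_max = 3, r2_min = 0.3)
  elig <- intersect(elig, interior_vertices(mesh))
  target <- select_target_vertex(mesh, elig, map)
  target$coord_scanner <- as.numeric(target$coord_tkr)
  plan <- plan_line(target)
  d <- plan_direction(plan)
  # analytic tangents of z = a sin(kx): (1, 0, a k cos(kx)) and (0, 1, 0)
  k <- 2 * pi / lam
  x <- target$coord_tkr[1]
  t1 <- c(1, 0, 2 * k * cos(k * x)); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(0, 1, 0)
  expect_lt(abs(sum(d * t1)), 1e-3)
  expect_lt(abs(sum(d * t2)), 1e-3)
})

test_that("nominal line masks have the right band width and placement", {
  grid <- volume_grid(array(0L, dim = c(160, 160, 1)),
                      vox2world_scaled(c(0.25, 0.25, 2.5)))
  mask <- build_nominal_line_mask(grid, gap_mm = 4)
  band <- which(apply(mask$data[, , 1], 1, max) == 1)
  expect_length(band, 16)
  expect_true(all(diff(band) == 1))
  expect_equal(mask$shape, grid$shape)
  # centered: 160 voxels, band 16 -> rows 73..88
  expect_equal(range(band), c(73, 88))

  # gap equal to the FOV -> all ones
  mask_full <- build_nominal_line_mask(grid, gap_mm = 40)
  expect_true(all(mask_full$data == 1))
  expect_error(build_nominal_line_mask(grid, gap_mm = 41), "exceeds")

  # 1 mm gap at 0.4 mm resolution: round(2.5) = 2 voxels, extra space on
  # the lower-index side
  g2 <- volume_grid(array(0L, dim = c(5, 4, 1)),
                    vox2world_scaled(c(0.4, 0.4, 2.5)))
  m2 <- build_nominal_line_mask(g2, gap_mm = 1)
  band2 <- which(apply(m2$data[, , 1], 1, max) == 1)
  expect_identical(band2, c(2L, 3L))
})

test_that("back-projected nominal masks contain the target vertex", {
  lam <- 20
  mesh <- make_folded_sheet(nx = 60, ny = 16, fold_amplitude = 2,
                            fold_wavelength = lam, spacing = 0.5)
  mesh <- compute_mean_curvature(compute_vertex_normals(mesh))
  ident <- affine_transform(diag(4), "surface_tkr", "scanner_ras")
  set.seed(77)
  flat <- intersect(which(abs(mesh$curvature) < 0.1) - 1L,
                    interior_vertices(mesh))
  hits <- 0L
  n_cases <- 50
  cand <- sample(flat, n_cases)
  for (v in cand) {
    tgt <- structure(list(index = v, coord_tkr = mesh$vertices[v + 1L, ],
                          coord_scanner = as.numeric(mesh$vertices[v + 1L, ]),
                          normal = mesh$normals[v + 1L, ], curvature = 0,
                          prf = NULL), class = "target_vertex")
    plan <- plan_line(tgt)
    slice <- plan_slice_grid(plan, fov_mm = 30, phase_res_mm = 0.25)
    mask <- build_nominal_line_mask(slice, gap_mm = 4)
    inside <- vertices_in_volume_mask(mesh, mask, ident)
    if (v %in% inside) hits <- hits + 1L
  }
  expect_equal(hits, n_cases)
})
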