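# mesh fixtures built in code

# closed UV sphere cap (poles excluded so every vertex has a full fan except
# the boundary rows, which the operators flag)
uv_sphere <- function(radius = 20, n_theta = 24, n_phi = 48) {
  th <- seq(0.3, pi - 0.3, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  v <- do.call(rbind, lapply(th, function(t)
    cbind(radius * sin(t) * cos(ph), radius * sin(t) * sin(ph),
          radius * cos(t))))
  fidx <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  i <- rep(seq_len(n_theta - 1L), each = n_phi)
  j <- rep(seq_len(n_phi), times = n_theta - 1L)
  f <- rbind(cbind(fidx(i, j), fidx(i + 1L, j), fidx(i + 1L, j + 1L)),
             cbind(fidx(i, j), fidx(i + 1L, j + 1L), fidx(i, j + 1L)))
  surface_mesh(v, f - 1L)
}

# open cylinder along z, radius r
cylinder_mesh <- function(radius = 10, height = 30, n_circ = 48, n_z = 20) {
  ph <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  zs <- seq(0, height, length.out = n_z)
  v <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(ph), radius * sin(ph), z)))
  fidx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  i <- rep(seq_len(n_z - 1L), each = n_circ)
  j <- rep(seq_len(n_circ), times = n_z - 1L)
  f <- rbind(cbind(fidx(i, j), fidx(i, j + 1L), fidx(i + 1L, j + 1L)),
             cbind(fidx(i, j), fidx(i + 1L, j + 1L), fidx(i + 1L, j)))
  surface_mesh(v, f - 1L)
}

# flat rectangular grid sheet in z = 0 with CCW winding (+z normals)
flat_sheet <- function(nx = 10, ny = 8, spacing = 1) {
  make_folded_sheet(nx, ny, fold_amplitude = 0, fold_wavelength = 10,
                    spacing = spacing)
}

interior_vertices <- function(mesh) {
  setdiff(seq_len(nrow(mesh$vertices)),
          linetarget:::boundary_vertices(mesh)) - 1L
}

# small, fast stimulus design for fitting tests (whole-brain-like tr)
small_design <- function(tr = 1.5, grid_extent = 10, n_pix = 31,
                         step = 0.5) {
  build_bar_design(orientations = c(0, 45, 90, 135), directions = c(1, -1),
                   bar_widths = 1.25, grid_extent = grid_extent, step = step,
                   tr = tr, blank_s = 15, n_pix = n_pix)
}

# line-scanning design (fast frame rate, slow bar) kept small for tests
line_design <- function(tr = 0.105, grid_extent = 8, n_pix = 25,
                        step = 0.03) {
  build_bar_design(orientations = c(0, 90), directions = c(1, -1),
                   bar_widths = c(0.625, 1.25), grid_extent = grid_extent,
                   step = step, tr = tr, blank_s = 15, n_pix = n_pix)
}

random_rigid <- function(seed) {
  make_transform_jitter(1, sigma_trans = 5, sigma_rot = 20, seed = seed)[[1]]
}

# identity vox2world with given voxel sizes
vox2world_scaled <- function(voxdim, origin = c(0, 0, 0)) {
  m <- diag(4)
  diag(m)[1:3] <- voxdim
  m[1:3, 4] <- origin
  affine_transform(m, "voxel", "scanner_ras")
}

expect_frame_error <- function(expr) expect_error(expr, "frame|mismatch")
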