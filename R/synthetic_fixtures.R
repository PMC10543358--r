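#' Folded-sheet cortical surrogate with analytic geometry
#'
#' A rectangular sheet `z = a sin(2 pi x / lambda)`, triangulated on an
#' `nx x ny` grid, standing in for a patch of folded cortex. The analytic
#' unit normal and mean curvature of the graph surface are attached as
#' attributes (`analytic_normals`, `analytic_curvature`) so the discrete
#' operators can be checked against closed forms. A synthetic `"V1"` label
#' covers a central band of the sheet.
#'
#' @param nx,ny grid vertices per axis (>= 3).
#' @param fold_amplitude fold amplitude `a` (mm).
#' @param fold_wavelength fold wavelength `lambda` (mm).
#' @param spacing grid spacing (mm).
#' @param v1_band_fraction fraction of the x-extent covered by the `"V1"`
#'   label (centered).
#' @return a [surface_mesh] with labels and analytic attributes.
#' @export
make_folded_sheet <- function(nx = 40, ny = 30, fold_amplitude = 2,
                              fold_wavelength = 20, spacing = 1,
                              v1_band_fraction = 0.6) {
  if (nx < 3 || ny < 3) stopf("nx and ny must be >= 3")
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  k <- 2 * pi / fold_wavelength
  xv <- rep(xs, times = ny)
  yv <- rep(ys, each = nx)
  zv <- fold_amplitude * sin(k * xv)
  vertices <- cbind(xv, yv, zv)
  # triangulate grid cells; counter-clockwise so normals point +z on a flat
  # sheet
  faces <- matrix(0L, 0, 3)
  idx <- function(i, j) (j - 1L) * nx + i - 1L   # 0-based
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- idx(i, j); v10 <- idx(i + 1L, j)
  v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  # analytic geometry of z = f(x): normal (-f', 0, 1)/norm,
  # mean curvature H = f'' / (2 (1 + f'^2)^(3/2)) (cylindrical surface,
  # one principal curvature is zero); sign convention matches the discrete
  # operator (positive where the surface bends toward the normal).
  fp <- fold_amplitude * k * cos(k * xv)
  fpp <- -fold_amplitude * k^2 * sin(k * xv)
  nrm <- cbind(-fp, 0, 1) / sqrt(1 + fp^2)
  Hana <- -fpp / (2 * (1 + fp^2)^1.5)
  band <- abs(xv - mean(range(xs))) <= v1_band_fraction / 2 * diff(range(xs))
  mesh <- surface_mesh(vertices, faces,
                       labels = list(V1 = which(band) - 1L))
  attr(mesh, "analytic_normals") <- nrm
  attr(mesh, "analytic_curvature") <- Hana
  mesh
}

#' Synthetic retinotopic pRF map on a mesh
#'
#' Emulates V1's retinotopic organization on a sheet-like mesh: pRF
#' eccentricity increases linearly along one surface axis and polar angle
#' along the other, with a configurable visual-field gradient magnitude.
#' pRF size grows linearly with eccentricity and the variance-explained
#' field carries seeded spatial noise.
#'
#' @param mesh a [surface_mesh] (sheet parameterized by its x/y vertex
#'   coordinates).
#' @param ecc_range eccentricity range (degrees) spanned along the x axis.
#' @param polar_range polar-angle range (radians) spanned along the y axis.
#' @param sigma_fn function eccentricity -> sigma (degrees).
#' @param r2_mean,r2_noise_sd mean and spatial-noise sd of the r2 field.
#' @param seed RNG seed; the map is a pure function of it.
#' @return a `prf_map` with one row per vertex; the visual-field gradient
#'   (deg/mm along x) is attached as attribute `gradient_deg_per_mm`.
#' @export
make_retinotopy <- function(mesh, ecc_range = c(0.5, 3),
                            polar_range = c(-pi / 4, pi / 4),
                            sigma_fn = function(ecc) 0.3 + 0.15 * ecc,
                            r2_mean = 0.6, r2_noise_sd = 0.1, seed = 1) {
  v <- mesh$vertices
  xr <- range(v[, 1]); yr <- range(v[, 2])
  u <- (v[, 1] - xr[1]) / max(diff(xr), 1e-12)
  w <- (v[, 2] - yr[1]) / max(diff(yr), 1e-12)
  ecc <- ecc_range[1] + u * diff(ecc_range)
  polar <- polar_range[1] + w * diff(polar_range)
  x0 <- ecc * cos(polar)
  y0 <- ecc * sin(polar)
  r2 <- with_seed(seed, pmin(pmax(
    stats::rnorm(nrow(v), r2_mean, r2_noise_sd), 0), 0.95))
  map <- prf_map(data.frame(x0 = x0, y0 = y0, sigma = sigma_fn(ecc),
                            r2 = r2))
  attr(map, "gradient_deg_per_mm") <- diff(ecc_range) / max(diff(xr), 1e-12)
  map
}

#' Ground truth for a simulated line session
#'
#' Fully determines a simulation: per-position tissue labels and depths,
#' the true pRF of the gray-matter positions, and the noise specification.
#'
#' @param n_gm,n_wm,n_csf positions per tissue class (ordered CSF |
#'   GM superficial-to-deep | WM along the line).
#' @param true_prf a [prf_params]: the pRF shared by the GM positions.
#' @param drift_slope linear drift in raw units per second.
#' @param cardiac_hz,resp_hz physiological frequencies (Hz).
#' @param cardiac_amp,resp_amp physiological amplitudes (raw units).
#' @param thermal_sd thermal (Gaussian) noise sd per coil sample.
#' @param bold_amp task amplitude at the superficial GM position (raw
#'   units); deeper positions scale linearly down to half this value.
#' @param seed RNG seed.
#' @return a `line_ground_truth` list.
#' @export
line_ground_truth <- function(n_gm = 16, n_wm = 8, n_csf = 8,
                              true_prf = prf_params(1.5, -1, 0.6),
                              drift_slope = 0.02, cardiac_hz = 1.0,
                              resp_hz = 0.3, cardiac_amp = 0.5,
                              resp_amp = 0.5, thermal_sd = 0.2,
                              bold_amp = 1, seed = 1) {
  seg <- c(rep("CSF", n_csf), rep("GM", n_gm), rep("WM", n_wm))
  depth <- rep(NA_real_, length(seg))
  depth[seg == "GM"] <- seq(0, 1, length.out = n_gm)
  structure(list(seg = seg, depth = depth, true_prf = true_prf,
                 noise_spec = list(drift_slope = drift_slope,
                                   cardiac_hz = cardiac_hz,
                                   resp_hz = resp_hz,
                                   cardiac_amp = cardiac_amp,
                                   resp_amp = resp_amp,
                                   thermal_sd = thermal_sd,
                                   bold_amp = bold_amp),
                 seed = seed),
            class = "line_ground_truth")
}

#' Simulate a multi-coil multi-echo line-scanning session
#'
#' Per line position the BOLD signal is the pRF prediction of the ground
#' truth, normalized to unit peak (so `bold_amp` is the peak task amplitude
#' in raw signal units and `bold_amp / thermal_sd` is the thermal SNR) and
#' scaled by a depth factor interpolating 2 (superficial) to 1 (deep),
#' mirroring the roughly two-fold superficial amplification seen in
#' depth-resolved data. A linear drift and cardiac/respiratory sinusoids
#' are shared across all tissue; WM and CSF positions carry noise and
#' physiology but no task signal. Per coil the signal is multiplied by a
#' smooth sensitivity profile and thermal Gaussian noise is added; per echo
#' it is scaled by `exp(-TE / T2*)`. The output is a pure function of the
#' ground truth's seed.
#'
#' @param gt a `line_ground_truth`.
#' @param design a `stimulus_design` whose `tr` is the sampling interval.
#' @param n_coils number of receive coils.
#' @param echo_times echo times (s).
#' @param t2star T2* used for echo weighting (s; default 0.028).
#' @param baseline_signal raw baseline signal level.
#' @return list with `series` (a [multicoil_line_series]), `seg`, `depth`,
#'   `line_mask` (all TRUE), `clean` (noise-free depth-scaled task matrix
#'   P x T), `sensitivities` (C x P).
#' @export
simulate_line_session <- function(gt, design, n_coils = 4,
                                  echo_times = c(0.006, 0.014, 0.022),
                                  t2star = 0.028, baseline_signal = 100) {
  dt <- design$tr
  if (dt >= 1 / (2 * gt$noise_spec$cardiac_hz))
    warnf("dt = %g s cannot resolve the %g Hz cardiac frequency (aliasing)",
          dt, gt$noise_spec$cardiac_hz)
  Tn <- dim(design$apertures)[1]
  P <- length(gt$seg)
  tsec <- (seq_len(Tn) - 1) * dt
  task <- prf_prediction(gt$true_prf, design, hrf_double_gamma(dt))
  # unit-peak task regressor so bold_amp is the peak amplitude in raw units
  if (max(abs(task)) > 0) task <- task / max(abs(task))
  ns <- gt$noise_spec
  clean <- matrix(0, P, Tn)
  gm <- which(gt$seg == "GM")
  depth_factor <- 2 - gt$depth[gm]   # 2 superficial -> 1 deep
  for (i in seq_along(gm))
    clean[gm[i], ] <- ns$bold_amp * depth_factor[i] * task
  with_seed(gt$seed, {
    card_phase <- stats::runif(1, 0, 2 * pi)
    resp_phase <- stats::runif(1, 0, 2 * pi)
    physio <- ns$cardiac_amp * sin(2 * pi * ns$cardiac_hz * tsec + card_phase) +
      ns$resp_amp * sin(2 * pi * ns$resp_hz * tsec + resp_phase)
    drift <- ns$drift_slope * tsec
    base <- baseline_signal +
      matrix(rep(drift + physio, each = P), P, Tn) + clean
    # smooth coil sensitivity profiles: gaussian bumps along the line
    pos <- seq_len(P)
    centers <- seq(1, P, length.out = n_coils)
    sens <- t(sapply(centers, function(c0)
      0.4 + exp(-(pos - c0)^2 / (2 * (P / 3)^2))))
    data <- array(0, dim = c(n_coils, length(echo_times), P, Tn))
    for (ci in seq_len(n_coils)) for (ei in seq_along(echo_times)) {
      sig <- base * sens[ci, ] * exp(-echo_times[ei] / t2star)
      data[ci, ei, , ] <- sig +
        matrix(stats::rnorm(P * Tn, sd = ns$thermal_sd), P, Tn)
    }
    list(series = multicoil_line_series(data, dt, echo_times),
         seg = gt$seg, depth = gt$depth, line_mask = rep(TRUE, P),
         clean = clean, sensitivities = sens)
  })
}

# random small-rotation matrix from independent per-axis angles (radians)
small_rotation <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Seeded rigid-transform jitter
#'
#' Generates `n` rigid transforms with per-axis rotation angles and
#' translations drawn from centered normals, emulating the variability of
#' repeated between-session registrations and run-to-run motion. Zero
#' sigmas give exact identities.
#'
#' @param n number of transforms.
#' @param sigma_trans translation sd per axis (mm).
#' @param sigma_rot rotation sd per axis (degrees).
#' @param seed RNG seed.
#' @param source_frame,dest_frame frame tags for the transforms.
#' @return list of rigid `affine_transform`s.
#' @export
make_transform_jitter <- function(n, sigma_trans = 0.2, sigma_rot = 0.1,
                                  seed = 1, source_frame = "scanner_ras",
                                  dest_frame = "scanner_ras") {
  if (sigma_trans < 0 || sigma_rot < 0) stopf("sigmas must be >= 0")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ang <- stats::rnorm(3, sd = sigma_rot) * pi / 180
      tr <- stats::rnorm(3, sd = sigma_trans)
      m <- diag(4)
      m[1:3, 1:3] <- small_rotation(ang[1], ang[2], ang[3])
      m[1:3, 4] <- tr
      affine_transform(m, source_frame, dest_frame)
    })
  })
}
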