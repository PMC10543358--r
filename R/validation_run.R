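#' One end-to-end synthetic targeting-validation run
#'
#' Exercises the whole framework on generated data with known ground truth:
#' build a folded-sheet cortex and a seeded retinotopic map, select the
#' target vertex (eccentricity, variance-explained and curvature criteria),
#' plan the line, simulate a multi-coil multi-echo line session whose true
#' pRF is the target's, run the preprocessing chain, fit a Gaussian pRF to
#' the mean gray-matter time course, and locate the best-matching vertex.
#'
#' In the `noiseless` condition every noise source is zeroed; the SVD
#' denoising step is switched off there (with no thermal noise the data are
#' exactly low rank, so there is no noise floor for the scree elbow to
#' find) and uniform tSNR weights are used (tSNR is undefined on constant
#' series).
#'
#' @param seed integer seed driving every random component.
#' @param noiseless zero all noise sources (drift, physiology, thermal).
#' @param thermal_snr peak task amplitude over thermal noise sd (ignored
#'   when `noiseless`); default 5.
#' @param design a `stimulus_design`; the default is the line-session bar
#'   paradigm (2 orientations x 2 directions x 2 widths at 0.105 s frames).
#' @param mesh_args list of [make_folded_sheet()] arguments.
#' @return list with `center_error_deg` (fitted vs true pRF center),
#'   `sigma_rel_error`, `fit_r2`, `visual_distance_deg`, `euclid_mm`,
#'   `geodesic_mm` (match to target), `target_index`, `match_index`.
#' @export
synthetic_recovery_run <- function(seed, noiseless = FALSE, thermal_snr = 5,
                                   design = NULL,
                                   mesh_args = list(nx = 60, ny = 16,
                                                    fold_amplitude = 2,
                                                    fold_wavelength = 20,
                                                    spacing = 0.5)) {
  if (is.null(design))
    design <- build_bar_design(orientations = c(0, 90), directions = c(1, -1),
                               bar_widths = c(0.625, 1.25), grid_extent = 8,
                               step = 0.03, tr = 0.105, blank_s = 15,
                               n_pix = 25)
  mesh <- do.call(make_folded_sheet, mesh_args)
  mesh <- compute_mean_curvature(compute_vertex_normals(mesh))
  map <- make_retinotopy(mesh, seed = seed)
  elig <- eligible_vertices(map, mesh, "V1", ecc_max = 3, r2_min = 0.3)
  # planning needs a full one-ring: restrict to interior vertices
  bnd <- boundary_vertices(mesh) - 1L
  elig <- setdiff(elig, bnd)
  target <- select_target_vertex(mesh, elig, map)
  target$coord_scanner <- as.numeric(target$coord_tkr)
  plan <- plan_line(target)

  true_prf <- prf_params(target$prf$x0, target$prf$y0,
                         max(target$prf$sigma, 0.2))
  gt <- line_ground_truth(
    true_prf = true_prf,
    drift_slope = if (noiseless) 0 else 0.02,
    cardiac_amp = if (noiseless) 0 else 0.5,
    resp_amp = if (noiseless) 0 else 0.5,
    thermal_sd = if (noiseless) 0 else 1 / thermal_snr,
    bold_amp = 1, seed = seed)
  sim <- simulate_line_session(gt, design)
  clean <- preprocess_line_series(
    sim$series, sim$seg, sim$line_mask,
    sensitivities = sim$sensitivities,
    tsnr = if (noiseless) matrix(1, dim(sim$series$data)[1],
                                 length(sim$seg)) else NULL,
    baseline_frames = design$blank_frames,
    denoise = !noiseless)
  gm <- which(sim$seg == "GM")
  ts <- colMeans(clean$data[gm, , drop = FALSE])
  fit <- fit_prf(ts, design, hrf_double_gamma(design$tr))
  match <- best_match_distance(map, fit, mesh, target)
  list(center_error_deg = sqrt((fit$x0 - true_prf$x0)^2 +
                               (fit$y0 - true_prf$y0)^2),
       sigma_rel_error = abs(fit$sigma - true_prf$sigma) / true_prf$sigma,
       fit_r2 = fit$r2,
       visual_distance_deg = match$visual_distance,
       euclid_mm = match$euclid_mm,
       geodesic_mm = match$geodesic_mm,
       target_index = target$index,
       match_index = match$match_index)
}
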