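#' Run configuration for the targeting pipeline
#'
#' Validates the configuration the pipeline stages consume. Unknown keys
#' are rejected. Defaults mirror the acquisition this package targets:
#' eccentricity < 3 deg, 4 mm suppression gap, 0.25 mm line resolution,
#' 2.5 mm slice, DCT cutoff 0.01 Hz, aCompCor cutoff 0.18 Hz with 5
#' components, Savitzky-Golay 11/3.
#'
#' @param ... configuration values overriding the defaults; `outdir` is
#'   required by [run_pipeline()].
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    outdir = NULL,
    mesh = NULL, prf_map = NULL, transforms = NULL,
    label = "V1", ecc_max = 3, r2_min = 0.35,
    gap_mm = 4, line_res_mm = 0.25, slice_thickness_mm = 2.5,
    dct_cutoff_hz = 0.01, acompcor_cutoff_hz = 0.18, n_components = 5,
    savgol_window = 11, savgol_order = 3,
    seed = 1,
    sim = list()
  )
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  for (k in c("ecc_max", "gap_mm", "line_res_mm", "slice_thickness_mm",
              "dct_cutoff_hz", "acompcor_cutoff_hz", "savgol_window"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stopf("config '%s' must be a positive number", k)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the 'yaml' package is required to read YAML configs")
  do.call(run_config, yaml::read_yaml(path))
}

write_provenance <- function(outdir, stage, inputs, params, seed) {
  rec <- list(stage = stage, inputs = inputs, parameters = params,
              seed = seed,
              package = "linetarget",
              version = as.character(utils::packageVersion("linetarget")),
              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(rec, file.path(outdir, paste0(stage, ".prov.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the offline targeting pipeline end to end
#'
#' Executes the requested stages in fixed order
#' `simulate -> select-target -> plan-line -> preprocess -> fit-prf ->
#' validate`, each writing its artifacts plus a JSON provenance sidecar
#' (inputs, parameters, seed, package version) into `config$outdir`. Later
#' stages read earlier stages' outputs from disk, so a stage whose upstream
#' artifact is missing fails with the name of the stage to run first. The
#' default configuration runs on the synthetic preset (folded sheet +
#' seeded retinotopy + simulated line session), so the whole chain is
#' exercisable without any acquired data.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   `c("simulate", "select-target", "plan-line", "preprocess", "fit-prf",
#'   "validate")`.
#' @return (invisibly) a named list of stage outputs.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "select-target", "plan-line",
                                    "preprocess", "fit-prf", "validate")) {
  all_stages <- c("simulate", "select-target", "plan-line", "preprocess",
                  "fit-prf", "validate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  if (is.null(config$outdir)) stopf("config must set 'outdir'")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  need <- function(path, producer) {
    if (!file.exists(path))
      stopf("missing artifact '%s': run stage '%s' first",
            basename(path), producer)
    path
  }
  paths <- list(
    mesh = file.path(outdir, "mesh.surf"),
    prf = file.path(outdir, "prf_map.tsv"),
    target = file.path(outdir, "target.json"),
    plan = file.path(outdir, "plan.json"),
    line = file.path(outdir, "line_clean.tsv"),
    sim = file.path(outdir, "sim.rds.json"),
    fits = file.path(outdir, "fits.tsv"),
    report = file.path(outdir, "validation.json")
  )

  sim_defaults <- list(nx = 40, ny = 30, fold_amplitude = 2,
                       fold_wavelength = 20, spacing = 1,
                       thermal_sd = 0.2, n_coils = 4)
  simp <- utils::modifyList(sim_defaults, config$sim)

  # line-session paradigm: fast frames, slow bar (~28 s per pass)
  design <- build_bar_design(orientations = c(0, 90), directions = c(1, -1),
                             bar_widths = c(0.625, 1.25), grid_extent = 8,
                             step = 0.03, tr = 0.105, blank_s = 15,
                             n_pix = 25)

  if ("simulate" %in% stages) {
    mesh <- make_folded_sheet(simp$nx, simp$ny, simp$fold_amplitude,
                              simp$fold_wavelength, simp$spacing)
    map <- make_retinotopy(mesh, seed = config$seed)
    write_surface(mesh, paths$mesh)
    write_prf_map(map, paths$prf)
    out$simulate <- list(mesh = mesh, prf_map = map)
    write_provenance(outdir, "simulate", list(), simp, config$seed)
  }

  load_mesh <- function() {
    mesh <- read_surface(need(paths$mesh, "simulate"))
    # labels are not stored in the surface file; regenerate the synthetic
    # V1 band deterministically from the sheet extent
    m2 <- make_folded_sheet(simp$nx, simp$ny, simp$fold_amplitude,
                            simp$fold_wavelength, simp$spacing)
    mesh$labels <- m2$labels
    mesh
  }

  if ("select-target" %in% stages) {
    mesh <- load_mesh()
    map <- read_prf_map(need(paths$prf, "simulate"))
    mesh <- compute_vertex_normals(mesh)
    mesh <- compute_mean_curvature(mesh)
    elig <- eligible_vertices(map, mesh, config$label, config$ecc_max,
                              config$r2_min)
    target <- select_target_vertex(mesh, elig, map)
    target$coord_scanner <- as.numeric(target$coord_tkr)  # identity session
    jsonlite::write_json(list(index = target$index,
                              coord_tkr = target$coord_tkr,
                              coord_scanner = target$coord_scanner,
                              normal = target$normal,
                              curvature = target$curvature),
                         paths$target, auto_unbox = TRUE, digits = NA)
    out$`select-target` <- target
    write_provenance(outdir, "select-target", list(prf = paths$prf),
                     list(ecc_max = config$ecc_max, r2_min = config$r2_min),
                     config$seed)
  }

  read_target <- function() {
    tj <- jsonlite::read_json(need(paths$target, "select-target"),
                              simplifyVector = TRUE)
    structure(list(index = tj$index, coord_tkr = as.numeric(tj$coord_tkr),
                   coord_scanner = as.numeric(tj$coord_scanner),
                   normal = as.numeric(tj$normal),
                   curvature = tj$curvature, prf = NULL),
              class = "target_vertex")
  }

  if ("plan-line" %in% stages) {
    target <- read_target()
    plan <- plan_line(target, config$gap_mm, config$slice_thickness_mm,
                      config$line_res_mm)
    write_line_plan(plan, paths$plan)
    out$`plan-line` <- plan
    write_provenance(outdir, "plan-line", list(target = paths$target),
                     list(gap_mm = config$gap_mm), config$seed)
  }

  if ("preprocess" %in% stages) {
    need(paths$plan, "plan-line")
    # the simulated line samples the targeted cortex: its true pRF is the
    # selected target's
    target <- read_target()
    map <- read_prf_map(need(paths$prf, "simulate"))
    tp <- prf_params(map$x0[target$index + 1L], map$y0[target$index + 1L],
                     max(map$sigma[target$index + 1L], 0.2))
    gt <- line_ground_truth(true_prf = tp, thermal_sd = simp$thermal_sd,
                            seed = config$seed)
    sim <- simulate_line_session(gt, design, n_coils = simp$n_coils)
    clean <- preprocess_line_series(
      sim$series, sim$seg, sim$line_mask,
      sensitivities = sim$sensitivities,
      baseline_frames = design$blank_frames,
      dct_cutoff_hz = config$dct_cutoff_hz,
      acompcor_cutoff_hz = config$acompcor_cutoff_hz,
      n_components = config$n_components,
      savgol_window = config$savgol_window,
      savgol_order = config$savgol_order)
    df <- as.data.frame(t(clean$data))
    names(df) <- paste0("pos", seq_len(nrow(clean$data)) - 1L)
    utils::write.table(df, paths$line, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    writeLines(sim$seg, file.path(outdir, "line_seg.txt"))
    out$preprocess <- clean
    write_provenance(outdir, "preprocess", list(plan = paths$plan),
                     list(chain = clean$chain), config$seed)
  }

  if ("fit-prf" %in% stages) {
    df <- utils::read.table(need(paths$line, "preprocess"), header = TRUE,
                            sep = "\t")
    seg <- readLines(file.path(outdir, "line_seg.txt"))
    gm <- which(seg == "GM")
    ts <- rowMeans(as.matrix(df[, gm, drop = FALSE]))
    fit <- fit_prf(ts, design, hrf_double_gamma(design$tr))
    utils::write.table(
      data.frame(x0 = fit$x0, y0 = fit$y0, sigma = fit$sigma,
                 beta = fit$beta, baseline = fit$baseline, r2 = fit$r2),
      paths$fits, sep = "\t", row.names = FALSE, quote = FALSE)
    out$`fit-prf` <- fit
    write_provenance(outdir, "fit-prf", list(line = paths$line), list(),
                     config$seed)
  }

  if ("validate" %in% stages) {
    fits <- utils::read.table(need(paths$fits, "fit-prf"), header = TRUE,
                              sep = "\t")
    mesh <- load_mesh()
    mesh <- compute_vertex_normals(mesh)
    mesh <- compute_mean_curvature(mesh)
    map <- read_prf_map(need(paths$prf, "simulate"))
    target <- read_target()
    line_prf <- prf_params(fits$x0[1], fits$y0[1], fits$sigma[1],
                           fits$beta[1], fits$baseline[1], fits$r2[1])
    match <- best_match_distance(map, line_prf, mesh, target)
    xfms <- make_transform_jitter(100, 0.2, 0.1, seed = config$seed + 1)
    disp <- point_dispersion(xfms, target$coord_scanner)
    report <- list(
      match = list(target_index = match$target_index,
                   match_index = match$match_index,
                   visual_distance_deg = match$visual_distance,
                   euclid_mm = match$euclid_mm,
                   geodesic_mm = match$geodesic_mm),
      registration_dispersion_mm = list(mean = disp$mean, sd = disp$sd,
                                        max = disp$max),
      line_r2 = fits$r2[1])
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                         digits = NA)
    out$validate <- report
    write_provenance(outdir, "validate", list(fits = paths$fits), list(),
                     config$seed)
  }
  invisible(out)
}
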