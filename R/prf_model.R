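#' Gaussian pRF parameters
#'
#' A population receptive field is modelled as an isotropic 2-D Gaussian in
#' the visual field: center `(x0, y0)` and spread `sigma`, all in degrees of
#' visual angle, plus a response amplitude `beta` (%BOLD per unit
#' stimulus–pRF overlap) and a `baseline` offset (%BOLD). `r2` is in-sample
#' variance explained.
#'
#' @param x0,y0 pRF center (visual degrees).
#' @param sigma Gaussian spread (visual degrees, > 0).
#' @param beta response amplitude.
#' @param baseline offset.
#' @param r2 goodness of fit in `(-Inf, 1]`.
#' @export
prf_params <- function(x0, y0, sigma, beta = 1, baseline = 0, r2 = NA_real_) {
  if (!is.na(sigma) && sigma <= 0) stopf("sigma must be > 0")
  if (!is.na(r2) && r2 > 1 + 1e-12) stopf("r2 cannot exceed 1")
  structure(list(x0 = x0, y0 = y0, sigma = sigma, beta = beta,
                 baseline = baseline, r2 = r2), class = "prf_params")
}

#' @export
print.prf_params <- function(x, ...) {
  cat(sprintf(
    "<prf_params: x0=%.3f y0=%.3f sigma=%.3f beta=%.3g baseline=%.3g r2=%.3f>\n",
    x$x0, x$y0, x$sigma, x$beta, x$baseline, x$r2))
  invisible(x)
}

#' Double-gamma hemodynamic response function
#'
#' The canonical double-gamma impulse response (response peak 6 s,
#' undershoot peak 16 s, undershoot ratio 1/6), sampled at the design frame
#' interval and normalized to peak 1. Any kernel sampled at the same `tr`
#' can be substituted via [hrf_model()].
#'
#' @param tr seconds per sample.
#' @param duration kernel length in seconds.
#' @export
hrf_double_gamma <- function(tr, duration = 32) {
  t <- seq(0, duration, by = tr)
  a1 <- 6; a2 <- 16; b <- 1; ratio <- 1 / 6
  k <- stats::dgamma(t, shape = a1, rate = b) -
    ratio * stats::dgamma(t, shape = a2, rate = b)
  hrf_model(k / max(k), tr, definition = "double-gamma(6,16,1/6)")
}

#' Construct an HRF model from a sampled kernel
#' @param kernel numeric impulse response sampled at `tr`.
#' @param tr seconds per sample.
#' @param definition free-text description of the parameterization.
#' @export
hrf_model <- function(kernel, tr, definition = "custom") {
  if (!all(is.finite(kernel))) stopf("HRF kernel must be finite")
  structure(list(kernel = as.numeric(kernel), tr = tr,
                 definition = definition), class = "hrf_model")
}

#' Build a moving-bar stimulus design
#'
#' Constructs the binary aperture stack of a bar-mapping experiment: one bar
#' traversal per (orientation x direction x width) combination, with
#' mean-luminance blank blocks inserted after every two passes, all frames
#' clipped to a circular aperture.
#'
#' @param orientations bar long-axis angles (degrees); motion is
#'   perpendicular to the bar.
#' @param directions motion directions per orientation, `+1` (forward) and/or
#'   `-1` (reversed traversal).
#' @param bar_widths bar widths (degrees).
#' @param grid_extent full width of the square visual-field grid (degrees).
#' @param step bar-center displacement per frame (degrees).
#' @param tr seconds per frame.
#' @param blank_s blank-block duration (seconds) inserted after every two
#'   passes (15 s in the experiments this emulates).
#' @param circular_mask_radius aperture radius (degrees); defaults to
#'   `grid_extent / 2`.
#' @param n_pix pixels per axis of the aperture grid.
#' @return a `stimulus_design`: list with `apertures` (T x H x W binary
#'   array), `grid_extent`, `tr`, `blank_frames` (0-based), pixel-center
#'   coordinates `xs`, `ys`, and `n_configurations`.
#' @export
build_bar_design <- function(orientations, directions = c(1, -1),
                             bar_widths = 1.25, grid_extent = 10,
                             step = 0.25, tr = 1.5, blank_s = 15,
                             circular_mask_radius = grid_extent / 2,
                             n_pix = 41) {
  if (!length(orientations)) stopf("orientations must be nonempty")
  if (any(bar_widths <= 0)) stopf("bar widths must be > 0")
  if (any(bar_widths > grid_extent)) stopf("bar wider than the grid")
  xs <- seq(-grid_extent / 2, grid_extent / 2, length.out = n_pix)
  ys <- xs
  px <- matrix(xs, n_pix, n_pix)          # x varies along rows
  py <- matrix(ys, n_pix, n_pix, byrow = TRUE)
  in_ap <- (px^2 + py^2) <= circular_mask_radius^2

  offsets <- seq(-grid_extent / 2, grid_extent / 2, by = step)
  n_blank <- max(1L, round(blank_s / tr))
  frames <- list()
  blank <- integer(0)
  t0 <- 0L
  pass <- 0L
  configs <- expand.grid(width = bar_widths, direction = directions,
                         orientation = orientations)
  for (i in seq_len(nrow(configs))) {
    o <- configs$orientation[i] * pi / 180
    dir <- configs$direction[i]
    w <- configs$width[i]
    # motion axis perpendicular to the bar's long axis
    u <- px * cos(o + pi / 2) + py * sin(o + pi / 2)
    offs <- if (dir > 0) offsets else rev(offsets)
    for (off in offs) {
      frames[[length(frames) + 1L]] <- (abs(u - off) <= w / 2) & in_ap
    }
    t0 <- t0 + length(offs)
    pass <- pass + 1L
    if (pass %% 2L == 0L) {
      for (k in seq_len(n_blank))
        frames[[length(frames) + 1L]] <- matrix(FALSE, n_pix, n_pix)
      blank <- c(blank, t0 + seq_len(n_blank) - 1L)
      t0 <- t0 + n_blank
    }
  }
  Tn <- length(frames)
  ap <- array(0, dim = c(Tn, n_pix, n_pix))
  for (t in seq_len(Tn)) ap[t, , ] <- frames[[t]] * 1
  structure(list(apertures = ap, grid_extent = grid_extent, tr = tr,
                 blank_frames = as.integer(blank), xs = xs, ys = ys,
                 n_configurations = nrow(configs)),
            class = "stimulus_design")
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat(sprintf(
    "<stimulus_design: %d frames (%.2f s/frame), %d configurations, %d blank frames>\n",
    dim(x$apertures)[1], x$tr, x$n_configurations, length(x$blank_frames)))
  invisible(x)
}

# flatten T x H x W apertures into T x npix; pixel coordinate vectors
design_matrix <- function(design) {
  d <- dim(design$apertures)
  matrix(design$apertures, d[1], d[2] * d[3])
}

design_pixel_coords <- function(design) {
  n <- length(design$xs)
  list(x = rep(design$xs, times = n), y = rep(design$ys, each = n))
}

gaussian_field <- function(x0, y0, sigma, px, py) {
  exp(-((px - x0)^2 + (py - y0)^2) / (2 * sigma^2))
}

# causal zero-padded convolution truncated at series end
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
}

#' Predicted pRF time series
#'
#' The neural drive at each frame is the dot product between the Gaussian
#' pRF and the stimulus aperture; the prediction is
#' `baseline + beta * (HRF (*) drive)` with causal zero-padded convolution
#' truncated at the series end.
#'
#' @param params a [prf_params].
#' @param design a `stimulus_design`.
#' @param hrf an `hrf_model` sampled at the design `tr`.
#' @return numeric time series (%BOLD).
#' @export
prf_prediction <- function(params, design, hrf) {
  if (params$sigma <= 0) stopf("sigma must be > 0")
  pc <- design_pixel_coords(design)
  g <- gaussian_field(params$x0, params$y0, params$sigma, pc$x, pc$y)
  drive <- as.numeric(design_matrix(design) %*% g)
  params$baseline + params$beta * convolve_hrf(drive, hrf$kernel)
}

#' Spatially non-selective block prediction
#'
#' The null model for functional validation: an indicator of "any stimulus
#' on screen" convolved with the HRF. Amplitude and offset are left to the
#' GLM in [crossval_r2()].
#'
#' @inheritParams prf_prediction
#' @return numeric regressor time series.
#' @export
block_null_prediction <- function(design, hrf) {
  on <- as.numeric(apply(design$apertures, 1, max) > 0)
  convolve_hrf(on, hrf$kernel)
}

default_grid_spec <- function(design) {
  e <- design$grid_extent / 2
  list(x0 = seq(-e, e, length.out = 13),
       y0 = seq(-e, e, length.out = 13),
       sigma = exp(seq(log(0.1), log(max(e, 0.2)), length.out = 6)))
}

# closed-form (beta, baseline) for a fixed-shape prediction; returns SS_res
glm_amplitude <- function(ts, pred) {
  X <- cbind(1, pred)
  cf <- tryCatch(qr.coef(qr(X), ts), error = function(e) c(mean(ts), 0))
  cf[is.na(cf)] <- 0
  res <- ts - X %*% cf
  list(baseline = cf[1], beta = cf[2], ss_res = sum(res^2))
}

#' Fit a Gaussian pRF to a time series
#'
#' Two stages: (1) an exhaustive coarse grid over `(x0, y0, sigma)` with the
#' amplitude and baseline solved in closed form per candidate by least
#' squares; (2) bounded quasi-Newton (L-BFGS-B) refinement of the three
#' spatial parameters from the grid optimum, minimizing the residual sum of
#' squares. Grid ties are broken by lowest residual, then smallest sigma,
#' then lexicographic `(x0, y0)`.
#'
#' @param ts numeric time series, same length as the design.
#' @param design a `stimulus_design`.
#' @param hrf an `hrf_model`.
#' @param grid_spec list with `x0`, `y0`, `sigma` candidate vectors; default
#'   covers `[-extent/2, extent/2]` and log-spaced sigmas.
#' @param bounds list with `lower`/`upper` length-3 vectors for
#'   `(x0, y0, sigma)` in the refinement stage.
#' @param refine logical; skip stage 2 when `FALSE`.
#' @return a [prf_params] with in-sample `r2`; all-constant input returns
#'   `r2 = 0` with `reliable = FALSE` attribute.
#' @export
fit_prf <- function(ts, design, hrf, grid_spec = NULL, bounds = NULL,
                    refine = TRUE) {
  Tn <- dim(design$apertures)[1]
  if (length(ts) != Tn)
    stopf("time series length %d does not match design length %d",
          length(ts), Tn)
  if (!all(is.finite(ts))) stopf("time series must be finite")
  if (stats::var(ts) == 0) {
    p <- prf_params(NA_real_, NA_real_, NA_real_, beta = 0,
                    baseline = ts[1], r2 = 0)
    attr(p, "reliable") <- FALSE
    return(p)
  }
  if (is.null(grid_spec)) grid_spec <- default_grid_spec(design)
  e <- design$grid_extent / 2
  if (is.null(bounds))
    bounds <- list(lower = c(-1.5 * e, -1.5 * e, 0.05),
                   upper = c(1.5 * e, 1.5 * e, 2 * e))

  pc <- design_pixel_coords(design)
  D <- design_matrix(design)
  # convolve the design once: prediction shape = (D %*% g) then HRF, and
  # convolution is linear, so convolve each pixel column up front
  Dh <- apply(D, 2, convolve_hrf, kernel = hrf$kernel)

  cand <- expand.grid(x0 = grid_spec$x0, y0 = grid_spec$y0,
                      sigma = grid_spec$sigma)
  G <- mapply(function(x0, y0, s) gaussian_field(x0, y0, s, pc$x, pc$y),
              cand$x0, cand$y0, cand$sigma)
  P <- Dh %*% G                                  # T x ncand predictions
  ss_tot <- sum((ts - mean(ts))^2)
  ss <- vapply(seq_len(ncol(P)), function(j) glm_amplitude(ts, P[, j])$ss_res,
               numeric(1))
  ord <- order(ss, cand$sigma, cand$x0, cand$y0)
  best <- ord[1]
  theta <- c(cand$x0[best], cand$y0[best], cand$sigma[best])

  objective <- function(th) {
    g <- gaussian_field(th[1], th[2], th[3], pc$x, pc$y)
    glm_amplitude(ts, as.numeric(Dh %*% g))$ss_res
  }
  if (refine) {
    opt <- stats::optim(theta, objective, method = "L-BFGS-B",
                        lower = bounds$lower, upper = bounds$upper,
                        control = list(maxit = 200))
    if (opt$value <= ss[best]) theta <- opt$par
  }
  g <- gaussian_field(theta[1], theta[2], theta[3], pc$x, pc$y)
  pred <- as.numeric(Dh %*% g)
  fit <- glm_amplitude(ts, pred)
  prf_params(theta[1], theta[2], theta[3], beta = fit$beta,
             baseline = fit$baseline, r2 = 1 - fit$ss_res / ss_tot)
}

#' Cross-validated variance explained of a fixed-shape prediction
#'
#' Refits only amplitude and intercept of a fixed prediction shape to the
#' data by ordinary least squares and reports `1 - SS_res/SS_tot`. Because
#' the amplitude sign is free, this equals the squared Pearson correlation
#' between prediction and data and is non-negative.
#'
#' @param reference a [prf_params] (its prediction is computed for `design`)
#'   or a numeric regressor of the right length.
#' @param ts observed time series.
#' @param design,hrf needed when `reference` is a [prf_params].
#' @return cvR² in `[0, 1]`; `NaN` with a warning for zero-variance data; 0
#'   for a zero-variance prediction.
#' @export
crossval_r2 <- function(reference, ts, design = NULL, hrf = NULL) {
  pred <- if (inherits(reference, "prf_params")) {
    if (is.null(design) || is.null(hrf))
      stopf("design and hrf required for a prf_params reference")
    prf_prediction(reference, design, hrf)
  } else as.numeric(reference)
  if (length(pred) != length(ts))
    stopf("prediction and data lengths differ")
  if (stats::var(ts) == 0) {
    warnf("zero-variance time series: cvR2 undefined")
    return(NaN)
  }
  if (stats::var(pred) == 0) return(0)
  stats::cor(pred, ts)^2
}

#' Eccentricity and polar angle of a pRF center
#'
#' @param params a [prf_params], or a data.frame/list with `x0`, `y0`
#'   columns (vectorized).
#' @return list with `ecc` (degrees) and `polar` (radians in `(-pi, pi]`;
#'   0 at the origin by convention).
#' @export
ecc_polar <- function(params) {
  x0 <- params$x0; y0 <- params$y0
  list(ecc = sqrt(x0^2 + y0^2), polar = atan2(y0, x0))
}

#' Order per-depth pRF fits into a depth profile table
#'
#' Each depth voxel is modelled independently; this collects fits into a
#' table ordered from superficial (depth 0) to deep (depth 1), with no
#' smoothing across depth.
#'
#' @param fits list of [prf_params], one per depth position.
#' @param depths numeric depth fractions in `[0, 1]` (0 = superficial).
#' @return data.frame with columns `depth`, `beta`, `r2`, `x0`, `y0`,
#'   `sigma`, sorted by depth.
#' @export
depth_profile <- function(fits, depths) {
  if (length(fits) != length(depths))
    stopf("fits and depths lengths differ")
  if (length(depths) < 2) stopf("need at least 2 depths")
  df <- data.frame(depth = depths,
                   beta = vapply(fits, function(f) f$beta, numeric(1)),
                   r2 = vapply(fits, function(f) f$r2, numeric(1)),
                   x0 = vapply(fits, function(f) f$x0, numeric(1)),
                   y0 = vapply(fits, function(f) f$y0, numeric(1)),
                   sigma = vapply(fits, function(f) f$sigma, numeric(1)))
  df[order(df$depth), , drop = FALSE]
}
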