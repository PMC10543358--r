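#' Multi-coil multi-echo line-scanning series
#'
#' @param data complex or real array with dimensions
#'   (coil C, echo E, position P, time T).
#' @param dt seconds per sample (the sequence TR, 0.105 s in the
#'   acquisitions this emulates).
#' @param echo_times echo times in seconds, length E.
#' @param position_res mm per position along the line.
#' @export
multicoil_line_series <- function(data, dt, echo_times, position_res = 0.25) {
  data <- as.array(data)
  if (length(dim(data)) != 4)
    stopf("data must be a 4-D (coil, echo, position, time) array")
  if (dim(data)[2] != length(echo_times))
    stopf("echo dimension (%d) does not match echo_times (%d)",
          dim(data)[2], length(echo_times))
  if (dt <= 0) stopf("dt must be positive")
  if (anyNA(data)) stopf("line data contains NA")
  structure(list(data = data, dt = dt, echo_times = as.numeric(echo_times),
                 position_res = position_res),
            class = "multicoil_line_series")
}

#' @export
print.multicoil_line_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<multicoil_line_series: %d coils, %d echoes, %d positions, %d samples (dt=%g s)>\n",
    d[1], d[2], d[3], d[4], x$dt))
  invisible(x)
}

#' Scree-plot elbow of a non-increasing spectrum
#'
#' The elbow is the index of maximal perpendicular distance from the
#' `(index, value)` curve to the chord joining the first and last points;
#' components strictly before the elbow are retained. Ties are broken
#' toward the larger index (retaining more components); a spectrum with no
#' interior deviation from the chord (e.g. strictly linear decay) retains
#' everything, with a warning when the spectrum is constant.
#'
#' @param singular_values non-increasing numeric vector (length >= 2).
#' @return the 1-based elbow index; `length + 1` means "retain all".
#' @export
detect_elbow <- function(singular_values) {
  s <- as.numeric(singular_values)
  n <- length(s)
  if (n < 2) stopf("need at least 2 values")
  if (any(diff(s) > 1e-9 * max(abs(s), 1)))
    stopf("singular values must be non-increasing")
  if (n == 2) return(2L)  # degenerate rule: retain the first component
  p1 <- c(1, s[1]); p2 <- c(n, s[n])
  chord <- p2 - p1
  # perpendicular distance of (i, s_i) to the chord (up to a constant factor)
  i <- seq_len(n)
  d <- abs((i - p1[1]) * chord[2] - (s - p1[2]) * chord[1])
  tol <- 1e-12 * max(d, 1)
  if (max(d) <= tol) {
    if (max(s) - min(s) <= 1e-12 * max(abs(s), 1))
      warnf("constant spectrum: elbow undefined, retaining all components")
    return(n + 1L)
  }
  max(which(d >= max(d) - tol))
}

#' SVD thermal-noise suppression of a space-by-time matrix
#'
#' Decomposes the position x time Casorati matrix of one coil/echo with a
#' singular value decomposition, zeroes the singular values from the scree
#' elbow ([detect_elbow()]) onward, and reconstructs. Complex input is
#' processed as-is (k-space data); magnitude data works identically.
#'
#' @param mat P x T numeric or complex matrix.
#' @return list with `data` (denoised matrix) and `rank` (number of
#'   components retained).
#' @export
svd_denoise <- function(mat) {
  mat <- as.matrix(mat)
  if (all(Mod(mat) == 0))
    return(list(data = mat, rank = 0L))
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stopf("need at least a 2 x 2 matrix")
  s <- svd(mat)
  elbow <- suppressWarnings(detect_elbow(s$d))
  keep <- min(elbow - 1L, length(s$d))
  d <- s$d
  if (keep < length(d)) d[(keep + 1L):length(d)] <- 0
  rec <- s$u %*% (d * Conj(t(s$v)))
  list(data = if (is.complex(mat)) rec else Re(rec), rank = keep)
}

#' @rdname svd_denoise
#' @param series a [multicoil_line_series]; each coil/echo plane is denoised
#'   separately.
#' @return for `svd_denoise_series`: the series with denoised data plus a
#'   `ranks` attribute (C x E retained ranks).
#' @export
svd_denoise_series <- function(series) {
  d <- dim(series$data)
  ranks <- matrix(NA_integer_, d[1], d[2])
  for (ci in seq_len(d[1])) for (ei in seq_len(d[2])) {
    mat <- series$data[ci, ei, , ]
    if (all(Mod(mat) == 0)) { ranks[ci, ei] <- 0L; next }
    s <- svd(mat)
    elbow <- suppressWarnings(detect_elbow(s$d))
    keep <- min(elbow - 1L, length(s$d))
    ranks[ci, ei] <- keep
    dd <- s$d
    if (keep < length(dd)) dd[(keep + 1L):length(dd)] <- 0
    rec <- s$u %*% (dd * Conj(t(s$v)))
    series$data[ci, ei, , ] <- if (is.complex(series$data)) rec else Re(rec)
  }
  attr(series, "ranks") <- ranks
  series
}

#' tSNR- and sensitivity-weighted sum-of-squares coil combination
#'
#' Per echo and position, `combined(t) = sqrt(sum_c w_c |x_c(t)|^2)` with
#' weights `w_c = (tsnr_c |s_c|)^2 / sum_c (tsnr_c |s_c|)^2`. The weights
#' are normalized so that equal sensitivities and tSNR reduce to the
#' root-mean-square over coils; set `normalize = FALSE` for the plain
#' weighted sum of squares. Positions where every weight is zero fall back
#' to the unweighted root sum of squares with a warning.
#'
#' @param series a [multicoil_line_series].
#' @param sensitivities C x P coil sensitivity magnitudes.
#' @param tsnr C x P temporal signal-to-noise ratios.
#' @param normalize normalize weights to sum 1 per position.
#' @return E x P x T real array.
#' @export
combine_coils <- function(series, sensitivities, tsnr, normalize = TRUE) {
  d <- dim(series$data)
  C <- d[1]; E <- d[2]; P <- d[3]; Tn <- d[4]
  sensitivities <- abs(as.matrix(sensitivities))
  tsnr <- as.matrix(tsnr)
  if (!all(dim(sensitivities) == c(C, P)) || !all(dim(tsnr) == c(C, P)))
    stopf("sensitivities and tsnr must be C x P")
  if (any(tsnr < 0) || any(sensitivities < 0))
    stopf("weights must be non-negative")
  w <- (tsnr * sensitivities)^2                  # C x P
  wsum <- colSums(w)
  zero <- wsum == 0
  if (any(zero)) {
    warnf("all-zero coil weights at %d position(s); using unweighted RSS",
          sum(zero))
    w[, zero] <- 1
    wsum[zero] <- if (normalize) C else 1
  }
  if (normalize) w <- sweep(w, 2, wsum, "/")
  out <- array(0, dim = c(E, P, Tn))
  for (ei in seq_len(E)) {
    acc <- matrix(0, P, Tn)
    for (ci in seq_len(C))
      acc <- acc + w[ci, ] * Mod(series$data[ci, ei, , , drop = FALSE][1, 1, , ])^2
    out[ei, , ] <- sqrt(acc)
  }
  out
}

#' Sum-of-squares echo combination
#'
#' `out(p, t) = sqrt(sum_e x_e(p, t)^2)`.
#' @param per_echo E x P x T real array.
#' @return P x T matrix.
#' @export
combine_echoes <- function(per_echo) {
  d <- dim(per_echo)
  if (length(d) != 3) stopf("expected an E x P x T array")
  out <- matrix(0, d[2], d[3])
  for (ei in seq_len(d[1])) out <- out + per_echo[ei, , ]^2
  sqrt(out)
}

# DCT-II basis columns with frequency < cutoff_hz (excluding the constant);
# frequency of component k over T samples at dt is k / (2 T dt)
dct_basis <- function(Tn, dt, cutoff_hz, above = FALSE) {
  kmax <- Tn - 1L
  f <- (1:kmax) / (2 * Tn * dt)
  ks <- if (above) which(f >= cutoff_hz) else which(f < cutoff_hz)
  if (!length(ks)) return(NULL)
  t_idx <- seq_len(Tn) - 0.5
  b <- sapply(ks, function(k) cos(pi * k * t_idx / Tn))
  b <- as.matrix(b)
  sweep(b, 2, colMeans(b))   # zero-mean columns
}

regress_out <- function(ts_mat, regressors) {
  # residualize rows of P x T matrix against T x K regressors (+ intercept
  # preserved: regressors are zero-mean so the temporal mean is untouched)
  X <- cbind(1, regressors)
  q <- qr(X)
  resid <- t(ts_mat) - X %*% qr.coef(q, t(ts_mat))
  means <- rowMeans(ts_mat)
  t(resid) + means - rowMeans(t(resid))
}

#' Remove slow drifts with a discrete cosine transform filter
#'
#' Regresses out zero-mean DCT-II basis functions with frequency below
#' `cutoff_hz` (the constant term is excluded, so each position's temporal
#' mean is preserved).
#'
#' @param ts P x T matrix (or length-T vector).
#' @param dt seconds per sample.
#' @param cutoff_hz drift cutoff (default 0.01 Hz).
#' @return list with `data` (filtered P x T matrix) and `nuisance`
#'   (`nuisance_set` of the removed regressors; `NULL` columns when the
#'   cutoff yields no regressors, in which case the data pass through with a
#'   warning).
#' @export
dct_highpass <- function(ts, dt, cutoff_hz = 0.01) {
  ts <- if (is.null(dim(ts))) matrix(ts, 1) else as.matrix(ts)
  Tn <- ncol(ts)
  B <- dct_basis(Tn, dt, cutoff_hz)
  if (is.null(B)) {
    warnf("cutoff %g Hz yields no DCT regressors for %d samples; unchanged",
          cutoff_hz, Tn)
    return(list(data = ts, nuisance = nuisance_set(NULL, "dct", cutoff_hz)))
  }
  list(data = regress_out(ts, B),
       nuisance = nuisance_set(B, "dct", cutoff_hz))
}

#' Nuisance regressor set
#' @param regressors T x K matrix with zero-mean columns (or `NULL`).
#' @param source `"dct"` or `"acompcor"`.
#' @param cutoff_hz the filter cutoff the regressors encode.
#' @export
nuisance_set <- function(regressors, source = c("dct", "acompcor"),
                         cutoff_hz = NA_real_) {
  source <- match.arg(source)
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    if (any(abs(colMeans(regressors)) > 1e-8))
      stopf("nuisance regressor columns must be zero-mean")
  }
  structure(list(regressors = regressors, source = source,
                 cutoff_hz = cutoff_hz), class = "nuisance_set")
}

#' Line-tailored anatomical component correction (aCompCor)
#'
#' Physiological noise regression adapted to 1-D line data: (1) select the
#' white-matter and CSF positions inside the nominal line mask; (2) run PCA
#' on their standardized time courses; (3) keep the first `n_components`
#' scores; (4) high-pass each score above `resp_cutoff_hz` (slightly below
#' the respiratory frequency, so task-band frequencies are not regressed
#' out); (5) regress the filtered scores out of every position's time
#' course.
#'
#' @param ts P x T matrix.
#' @param seg length-P tissue labels (`"GM"`, `"WM"`, `"CSF"`, ...).
#' @param line_mask length-P logical (or 0/1) inclusion mask; defaults to
#'   all positions.
#' @param n_components number of PCA components (default 5; 0 is the
#'   identity transform).
#' @param resp_cutoff_hz high-pass cutoff for the component scores
#'   (default 0.18 Hz).
#' @param dt seconds per sample.
#' @return list with `data` (cleaned P x T) and `nuisance`
#'   (`nuisance_set`).
#' @export
line_acompcor <- function(ts, seg, line_mask = NULL, n_components = 5,
                          resp_cutoff_hz = 0.18, dt) {
  ts <- as.matrix(ts)
  P <- nrow(ts); Tn <- ncol(ts)
  if (length(seg) != P) stopf("seg length must match positions")
  if (is.null(line_mask)) line_mask <- rep(TRUE, P)
  line_mask <- as.logical(line_mask)
  if (1 / dt <= 2 * resp_cutoff_hz)
    warnf("sampling rate %.3g Hz cannot resolve the %.2g Hz cutoff",
          1 / dt, resp_cutoff_hz)
  if (n_components == 0)
    return(list(data = ts,
                nuisance = nuisance_set(NULL, "acompcor", resp_cutoff_hz)))
  sel <- which(line_mask & seg %in% c("WM", "CSF"))
  if (!length(sel))
    stopf("no WM/CSF positions inside the line mask (labels present: %s)",
          paste(unique(seg), collapse = ", "))
  X <- t(ts[sel, , drop = FALSE])                 # T x V
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    warnf("all candidate nuisance time courses are constant; nothing to remove")
    return(list(data = ts,
                nuisance = nuisance_set(NULL, "acompcor", resp_cutoff_hz)))
  }
  X <- scale(X[, keep, drop = FALSE])
  k <- min(n_components, ncol(X), Tn - 1L)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # high-pass each score: remove the DCT components below the cutoff
  B <- dct_basis(Tn, dt, resp_cutoff_hz)
  if (!is.null(B)) {
    q <- qr(cbind(1, B))
    scores <- scores - cbind(1, B) %*% qr.coef(q, scores)
  }
  scores <- sweep(scores, 2, colMeans(scores))
  list(data = regress_out(ts, scores),
       nuisance = nuisance_set(scores, "acompcor", resp_cutoff_hz))
}

#' Savitzky-Golay low-pass smoothing
#'
#' Least-squares local polynomial smoothing (default window 11 samples,
#' order 3). Edges are handled by polynomial fits of the terminal windows,
#' matching the filter's interior behavior.
#'
#' @param ts P x T matrix or length-T vector.
#' @param window odd window length in samples.
#' @param polyorder polynomial order (< window).
#' @return smoothed data, same shape as input.
#' @export
savgol_smooth <- function(ts, window = 11, polyorder = 3) {
  if (window %% 2 == 0 || window <= polyorder)
    stopf("window must be odd and larger than polyorder")
  vec_in <- is.null(dim(ts))
  m <- if (vec_in) matrix(ts, 1) else as.matrix(ts)
  if (ncol(m) < window)
    stopf("series length %d is shorter than the window %d", ncol(m), window)
  out <- t(apply(m, 1, function(x)
    signal::sgolayfilt(x, p = polyorder, n = window)))
  if (vec_in) as.numeric(out) else out
}

#' Convert to percent signal change
#'
#' `100 * (x - mu) / mu` per position, where `mu` is the mean over the
#' baseline frames (the empty-screen periods when a stimulus design is
#' available; the full series otherwise).
#'
#' @param ts P x T matrix or length-T vector.
#' @param baseline_frames 0-based time indices defining the baseline;
#'   `NULL` uses every frame.
#' @return percent-signal-change data, same shape.
#' @export
percent_signal_change <- function(ts, baseline_frames = NULL) {
  vec_in <- is.null(dim(ts))
  m <- if (vec_in) matrix(ts, 1) else as.matrix(ts)
  cols <- if (is.null(baseline_frames)) seq_len(ncol(m))
          else as.integer(baseline_frames) + 1L
  mu <- rowMeans(m[, cols, drop = FALSE])
  if (any(mu == 0)) stopf("zero baseline mean at position(s) %s",
                          paste(which(mu == 0), collapse = ", "))
  out <- 100 * (m - mu) / mu
  if (vec_in) as.numeric(out) else out
}

#' Average repeated iterations of the stimulus sequence
#'
#' Element-wise mean across equal-length segments of the time axis (the two
#' within-run iterations of the experimental sequence; also usable for
#' run and voxel averaging).
#'
#' @param ts P x T matrix or length-T vector.
#' @param iteration_boundaries 0-based start indices of each iteration; the
#'   segments must tile the series in equal lengths.
#' @return averaged data with the length of one iteration.
#' @export
average_iterations <- function(ts, iteration_boundaries) {
  vec_in <- is.null(dim(ts))
  m <- if (vec_in) matrix(ts, 1) else as.matrix(ts)
  Tn <- ncol(m)
  starts <- sort(as.integer(iteration_boundaries)) + 1L
  ends <- c(starts[-1] - 1L, Tn)
  lens <- ends - starts + 1L
  if (length(unique(lens)) != 1)
    stopf("iterations have unequal lengths: %s", paste(lens, collapse = ", "))
  L <- lens[1]
  acc <- matrix(0, nrow(m), L)
  for (i in seq_along(starts)) acc <- acc + m[, starts[i]:ends[i], drop = FALSE]
  out <- acc / length(starts)
  if (vec_in) as.numeric(out) else out
}

#' The fixed line-scanning preprocessing chain
#'
#' Runs the full signal chain in its fixed order: SVD denoise (per
#' coil/echo) -> coil combination -> echo combination -> DCT drift removal
#' -> line aCompCor -> percent signal change -> Savitzky-Golay smoothing ->
#' iteration averaging. The executed steps and parameters are recorded in
#' the result's `chain` descriptor; the order is structural and not
#' configurable.
#'
#' @param series a [multicoil_line_series].
#' @param seg length-P tissue labels.
#' @param line_mask length-P logical inclusion mask.
#' @param sensitivities,tsnr C x P coil weights; both default to uniform
#'   (tSNR is computed from the denoised data when `tsnr = NULL`).
#' @param baseline_frames 0-based empty-screen frames for percent signal
#'   change (`NULL`: full-series mean).
#' @param iteration_boundaries 0-based iteration starts for averaging
#'   (`NULL`: no averaging).
#' @param dct_cutoff_hz,acompcor_cutoff_hz,n_components,savgol_window,savgol_order
#'   chain parameters (defaults 0.01 Hz, 0.18 Hz, 5, 11, 3).
#' @param denoise run the SVD step (default TRUE).
#' @return a `line_series`: list with `data` (P x T %change matrix), `dt`,
#'   `position_res`, `seg`, `chain` (ordered step descriptor), `nuisance`
#'   (list of `nuisance_set`s).
#' @export
preprocess_line_series <- function(series, seg, line_mask = NULL,
                                   sensitivities = NULL, tsnr = NULL,
                                   baseline_frames = NULL,
                                   iteration_boundaries = NULL,
                                   dct_cutoff_hz = 0.01,
                                   acompcor_cutoff_hz = 0.18,
                                   n_components = 5,
                                   savgol_window = 11, savgol_order = 3,
                                   denoise = TRUE) {
  d <- dim(series$data)
  C <- d[1]; P <- d[3]
  chain <- character(0)
  if (denoise) {
    series <- svd_denoise_series(series)
    chain <- c(chain, "svd_denoise")
  }
  if (is.null(sensitivities)) sensitivities <- matrix(1, C, P)
  if (is.null(tsnr)) {
    # tSNR from the (denoised) magnitude data, first echo
    tsnr <- matrix(0, C, P)
    for (ci in seq_len(C)) {
      x <- Mod(series$data[ci, 1, , ])
      mu <- rowMeans(x); sdv <- apply(x, 1, stats::sd)
      tsnr[ci, ] <- ifelse(sdv > 0, mu / sdv, 0)
    }
  }
  per_echo <- combine_coils(series, sensitivities, tsnr)
  chain <- c(chain, "combine_coils")
  ts <- combine_echoes(per_echo)
  chain <- c(chain, "combine_echoes")
  nuis <- list()
  hp <- dct_highpass(ts, series$dt, dct_cutoff_hz)
  ts <- hp$data
  nuis$dct <- hp$nuisance
  chain <- c(chain, "dct_highpass")
  ac <- line_acompcor(ts, seg, line_mask, n_components,
                      acompcor_cutoff_hz, dt = series$dt)
  ts <- ac$data
  nuis$acompcor <- ac$nuisance
  chain <- c(chain, "line_acompcor")
  ts <- percent_signal_change(ts, baseline_frames)
  chain <- c(chain, "percent_signal_change")
  ts <- savgol_smooth(ts, savgol_window, savgol_order)
  chain <- c(chain, "savgol_smooth")
  if (!is.null(iteration_boundaries)) {
    ts <- average_iterations(ts, iteration_boundaries)
    chain <- c(chain, "average_iterations")
  }
  structure(list(data = ts, dt = series$dt,
                 position_res = series$position_res, seg = seg,
                 chain = chain, nuisance = nuis),
            class = "line_series")
}

#' @export
print.line_series <- function(x, ...) {
  cat(sprintf("<line_series: %d positions x %d samples (dt=%g s)>\n",
              nrow(x$data), ncol(x$data), x$dt))
  cat("  chain:", paste(x$chain, collapse = " -> "), "\n")
  invisible(x)
}

#' The canonical chain order
#'
#' The fixed step order of [preprocess_line_series()], exposed so tests and
#' reports can assert against it.
#' @export
line_chain_order <- function() {
  c("svd_denoise", "combine_coils", "combine_echoes", "dct_highpass",
    "line_acompcor", "percent_signal_change", "savgol_smooth",
    "average_iterations")
}
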