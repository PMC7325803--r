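# Phase-encoded retinotopy: phase-lag recovery, visual field sign, and the
# six-segment V1/V2 parcellation.

#' Discard the first quarter of the stimulus cycle from a run
#'
#' Removes the initial `round(0.25 * cycle_period_s / tr_s)` samples (the
#' transient before the response settles) and reduces the cycle count by 0.25,
#' so a standard 8.25-cycle run becomes an integer 8 cycles, as the Fourier
#' analysis requires.
#'
#' @param run a `bold_run`.
#' @return the shortened `bold_run`.
#' @export
discard_initial_quarter_cycle <- function(run) {
  n_drop <- round(0.25 * run$cycle_period_s / run$tr_s)
  if (run$n_cycles - 0.25 < 1)
    stopf("run too short: less than one full cycle would remain after discard")
  if (n_drop >= ncol(run$series))
    stopf("run shorter than a quarter stimulus cycle")
  run$series <- run$series[, -seq_len(n_drop), drop = FALSE]
  run$n_cycles <- run$n_cycles - 0.25
  # keep the absolute time origin so phases stay referenced to stimulus onset
  run$t0_s <- (if (is.null(run$t0_s)) 0 else run$t0_s) + n_drop * run$tr_s
  run
}

#' Default high-pass cutoff for a mapping dimension
#'
#' 1/120 Hz for polar-angle runs and 1/72 Hz for eccentricity runs, matching
#' the slower rotating-ray versus faster expanding-ring cycle periods.
#'
#' @param dimension `"eccentricity"` or `"polar"`.
#' @return cutoff frequency in Hz.
#' @export
default_highpass_cutoff <- function(dimension = c("eccentricity", "polar")) {
  switch(match.arg(dimension), eccentricity = 1 / 72, polar = 1 / 120)
}

#' High-pass filter a run by discrete-cosine drift regression
#'
#' Removes baseline drift below `cutoff_hz` by regressing each vertex's time
#' series on a discrete cosine basis (all DCT components with frequency below
#' the cutoff, plus an intercept) and subtracting the fitted drift. The
#' stimulus-frequency sine and cosine are included in the fit as protected
#' regressors, so the component of interest keeps its amplitude and phase
#' exactly while drift is estimated from what is orthogonal to it.
#'
#' @param run a `bold_run`.
#' @param cutoff_hz drift cutoff; must lie below the stimulus frequency
#'   `1/cycle_period_s`. Defaults per dimension via
#'   [default_highpass_cutoff()].
#' @return the filtered `bold_run` (zero-mean series).
#' @export
highpass_filter <- function(run, cutoff_hz = default_highpass_cutoff(run$dimension)) {
  f_stim <- 1 / run$cycle_period_s
  if (cutoff_hz < 0) stopf("cutoff_hz must be nonnegative")
  if (cutoff_hz >= f_stim)
    stopf("cutoff (%.4g Hz) at or above the stimulus frequency (%.4g Hz) would destroy the signal",
          cutoff_hz, f_stim)
  n_t <- ncol(run$series)
  t_idx <- 0:(n_t - 1)
  k_max <- floor(2 * n_t * run$tr_s * cutoff_hz)
  dct <- if (k_max >= 1)
    sapply(seq_len(k_max), function(k) cos(pi * (2 * t_idx + 1) * k / (2 * n_t)))
  else NULL
  wt <- 2 * pi * f_stim * t_idx * run$tr_s
  x <- cbind(1, dct, cos(wt), sin(wt))
  drift_cols <- seq_len(1L + k_max)
  beta <- solve(crossprod(x), crossprod(x, t(run$series)))
  drift <- t(x[, drift_cols, drop = FALSE] %*% beta[drift_cols, , drop = FALSE])
  run$series <- run$series - drift
  run
}

#' Fourier coefficient at the stimulus frequency
#'
#' Computes, per vertex, the DFT coefficient at the stimulus frequency
#' (`n_cycles` cycles per run). The run should cover an integer number of
#' cycles (apply [discard_initial_quarter_cycle()] first); a non-integer count
#' is still computed but triggers a spectral-leakage warning. Phase
#' convention: a signal `cos(2*pi*f*t - phi)` yields a coefficient with
#' argument `+phi` and modulus equal to the signal amplitude. Phases are
#' referenced to absolute stimulus onset: a run whose initial samples were
#' discarded carries its time origin in `t0_s`, and the coefficient is
#' rotated back so the discard introduces no phase offset.
#'
#' @param run a `bold_run`.
#' @return complex vector, one coefficient per vertex.
#' @export
fourier_phase <- function(run) {
  k <- round(run$n_cycles)
  if (abs(run$n_cycles - k) > 1e-8)
    warning(sprintf("non-integer cycle count (%.3f): spectral leakage expected", run$n_cycles))
  n_t <- ncol(run$series)
  w <- exp(2i * pi * k * (0:(n_t - 1)) / n_t)
  coeff <- drop(run$series %*% w) * (2 / n_t)
  t0 <- if (is.null(run$t0_s)) 0 else run$t0_s
  f <- k / (n_t * run$tr_s)
  coeff * exp(2i * pi * f * t0)
}

#' Combine opposite-direction runs into a phase map
#'
#' The hemodynamic delay shifts both runs by the same `+delta`, while the true
#' retinotopic phase enters with opposite sign (forward `phi + delta`,
#' reversed `-phi + delta`). Conjugating the reversed-run coefficient and
#' averaging the complex values cancels the delay, and the complex average
#' weights each run by its response amplitude. The combined amplitude scales
#' with `cos(delta)`, so the method requires the hemodynamic delay to stay
#' below a quarter stimulus cycle (|delta| < pi/2) -- amply satisfied by
#' hemodynamic delays of a few seconds at cycle periods of 36-60 s.
#'
#' @param fwd_coeff,rev_coeff complex coefficient vectors from
#'   [fourier_phase()] on runs of equal length and frequency.
#' @param dimension stored on the result for bookkeeping.
#' @return object of class `phase_map`: `phase` in [0, 2*pi), `amplitude`
#'   (>= 0), `dimension`, `flagged` (vertices with zero amplitude in both
#'   runs, whose phase is undefined and set NA).
#' @export
combine_opposite_runs <- function(fwd_coeff, rev_coeff,
                                  dimension = c("eccentricity", "polar")) {
  dimension <- match.arg(dimension)
  if (length(fwd_coeff) != length(rev_coeff))
    stopf("coefficient vectors must have equal length")
  avg <- (fwd_coeff + Conj(rev_coeff)) / 2
  flagged <- Mod(fwd_coeff) == 0 & Mod(rev_coeff) == 0
  phase <- wrap_2pi(Arg(avg))
  phase[flagged] <- NA_real_
  structure(list(phase = phase, amplitude = Mod(avg), dimension = dimension,
                 flagged = flagged),
            class = "phase_map")
}

#' Estimate a phase map from a forward/reversed run pair
#'
#' Convenience wrapper chaining [discard_initial_quarter_cycle()],
#' [highpass_filter()], [fourier_phase()] and [combine_opposite_runs()].
#'
#' @param fwd,rev `bold_run`s of opposite direction, same dimension.
#' @param cutoff_hz high-pass cutoff (defaults per dimension).
#' @return a `phase_map`.
#' @export
estimate_phase_map <- function(fwd, rev,
                               cutoff_hz = default_highpass_cutoff(fwd$dimension)) {
  stopifnot(fwd$direction == 1, rev$direction == -1,
            identical(fwd$dimension, rev$dimension))
  cf <- fourier_phase(highpass_filter(discard_initial_quarter_cycle(fwd), cutoff_hz))
  cr <- fourier_phase(highpass_filter(discard_initial_quarter_cycle(rev), cutoff_hz))
  combine_opposite_runs(cf, cr, fwd$dimension)
}

#' Visual field sign map
#'
#' Per vertex, the sign of the oriented area of the (eccentricity, polar
#' angle) mapping: the z-component of the cross product of the two phase
#' gradients in the patch tangent plane. Gradients are computed per triangle
#' by linear interpolation and averaged (area-weighted) onto vertices, using
#' only triangles whose three vertices lie in the same visual area so the
#' V1/V2 border does not blur the sign. Mirror-image representations (V1) and
#' non-mirror representations (V2) get opposite signs.
#'
#' @param patch a `retino_patch`.
#' @param ecc_map,pol_map `phase_map`s on the patch vertices.
#' @param amplitude_threshold vertices whose amplitude (in either map) falls
#'   below this get sign 0 (default 0: keep all).
#' @return integer vector in {-1, 0, +1}, one entry per vertex.
#' @export
field_sign <- function(patch, ecc_map, pol_map, amplitude_threshold = 0) {
  coords <- patch$vertex_coords
  faces <- patch$faces
  n_v <- nrow(coords)
  acc <- numeric(n_v)
  n_degenerate <- 0L

  for (f in seq_len(nrow(faces))) {
    tri <- faces[f, ]
    area_lab <- patch$area_label[tri]
    if (area_lab[1] == "none" || length(unique(area_lab)) != 1L) next
    a <- coords[tri[1], ]; b <- coords[tri[2], ]; c3 <- coords[tri[3], ]
    e1 <- b - a; e2 <- c3 - a
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    area2 <- sqrt(sum(nrm^2))
    if (area2 < 1e-12) { n_degenerate <- n_degenerate + 1L; next }
    # local orthonormal tangent basis (u, v) with (u, v, normal) right-handed
    u <- e1 / sqrt(sum(e1^2))
    nh <- nrm / area2
    v <- c(nh[2] * u[3] - nh[3] * u[2],
           nh[3] * u[1] - nh[1] * u[3],
           nh[1] * u[2] - nh[2] * u[1])
    p2 <- rbind(c(0, 0),
                c(sum(e1 * u), sum(e1 * v)),
                c(sum(e2 * u), sum(e2 * v)))
    m <- cbind(p2[2, ] - p2[1, ], p2[3, ] - p2[1, ])  # 2x2, columns = edges
    ge <- solve(t(m), ecc_map$phase[tri[2:3]] - ecc_map$phase[tri[1]])
    gp <- solve(t(m), pol_map$phase[tri[2:3]] - pol_map$phase[tri[1]])
    jac <- ge[1] * gp[2] - ge[2] * gp[1]
    acc[tri] <- acc[tri] + jac * (area2 / 2)
  }
  if (n_degenerate > 0)
    message(sprintf("field_sign: skipped %d degenerate triangle(s)", n_degenerate))

  s <- sign(acc)
  low <- ecc_map$amplitude < amplitude_threshold | pol_map$amplitude < amplitude_threshold
  s[low] <- 0L
  s[patch$area_label == "none"] <- 0L
  as.integer(s)
}

#' Segment V1 and V2 into six retinotopic subdivisions each
#'
#' Per area the eccentricity and polar-angle phases are min-max scaled to
#' (0,1); the polar angle is thresholded into two equal parts (upper/lower
#' field) and the eccentricity into three (foveal/middle/peripheral), giving
#' six subdivisions of the visual hemifield. Bins are half-open `[a, b)`, a
#' deterministic stand-in for manually refined borders. Segment ids are
#' `1 + polar_bin*3 + ecc_bin` in V1 and the same plus 6 in V2.
#'
#' @param ecc_map,pol_map `phase_map`s.
#' @param area_label per-vertex area ("V1", "V2", "none").
#' @return integer vector of segment ids (1-6 V1, 7-12 V2, 0 unassigned).
#' @export
segment_v1_v2 <- function(ecc_map, pol_map, area_label) {
  n <- length(area_label)
  if (length(ecc_map$phase) != n || length(pol_map$phase) != n)
    stopf("phase maps and area labels must agree in length")
  seg <- integer(n)
  for (area in c("V1", "V2")) {
    idx <- area_label == area
    if (!any(idx)) next
    seg[idx] <- bin_segments(ecc_map$phase[idx], pol_map$phase[idx],
                             offset = if (area == "V1") 0L else 6L,
                             circular = TRUE)
  }
  seg
}
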