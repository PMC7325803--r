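# Synthetic-data generator: retinotopic patch, phase-encoded BOLD runs,
# segment label volumes, U-shaped streamline sets and b=0 image series,
# all with known ground truth.

#' Generator configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults encode
#' the study conditions the downstream pipeline is calibrated against:
#' retinotopic (diagonal) streamlines of 16 +/- 4 mm, non-retinotopic ones of
#' 32 +/- 13 mm, lengths clipped to the 3-100 mm tracking range at a 0.2 mm
#' step, and a retinotopic share of total connectivity of about 72.7%.
#'
#' @param seed integer RNG seed; fixes all stochastic output bit-reproducibly.
#' @param n_streamlines total streamlines per simulated hemisphere.
#' @param n_streamlines_per_cell optional explicit 6x6 nonnegative integer
#'   matrix of per-cell streamline counts (rows = V1 segments, cols = V2
#'   segments); overrides `retino_bias` when given.
#' @param retino_bias fraction of streamline mass placed on the diagonal
#'   (retinotopically corresponding) cells of the 6x6 cell distribution. The
#'   six diagonal cells share `retino_bias` uniformly; the 30 off-diagonal
#'   cells share `1 - retino_bias` uniformly, so `retino_bias = 1/6` is the
#'   uniform (chance) matrix and the expected retinotopic percentage equals
#'   `100 * retino_bias`.
#' @param length_mean_retino,length_sd_retino mm; truncated-normal length
#'   distribution of diagonal-cell streamlines.
#' @param length_mean_nonretino,length_sd_nonretino mm; same for off-diagonal.
#' @param length_range_mm tracking range; generated lengths are confined to it.
#' @param step_mm polyline sampling step.
#' @param csf_contaminant_fraction fraction of streamlines routed through the
#'   CSF slab of the label volume (and tagged as such).
#' @param noise_sd Gaussian noise SD added to BOLD time series (signal units).
#' @param hemodynamic_delay_s common hemodynamic phase delay applied to both
#'   stimulus directions (seconds).
#' @param drift_amplitude scale of the low-frequency drift added to BOLD runs.
#' @param bold_amplitude,bold_baseline response amplitude and baseline of the
#'   simulated stimulus-locked BOLD signal (signal units).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_streamlines = 1000L,
                             n_streamlines_per_cell = NULL,
                             retino_bias = 0.727,
                             length_mean_retino = 16, length_sd_retino = 4,
                             length_mean_nonretino = 32, length_sd_nonretino = 13,
                             length_range_mm = c(3, 100),
                             step_mm = 0.2,
                             csf_contaminant_fraction = 0,
                             noise_sd = 1,
                             hemodynamic_delay_s = 5,
                             drift_amplitude = 0,
                             bold_amplitude = 1,
                             bold_baseline = 100) {
  if (!is_count(seed)) stopf("seed must be a nonnegative integer")
  if (!is_count(n_streamlines)) stopf("n_streamlines must be a nonnegative integer")
  if (!is.null(n_streamlines_per_cell)) {
    m <- as.matrix(n_streamlines_per_cell)
    if (!all(dim(m) == c(6L, 6L)) || any(m < 0) || any(m != round(m)))
      stopf("n_streamlines_per_cell must be a 6x6 matrix of nonnegative integers")
    n_streamlines_per_cell <- m
  }
  if (retino_bias < 0 || retino_bias > 1) stopf("retino_bias must lie in [0, 1]")
  if (csf_contaminant_fraction < 0 || csf_contaminant_fraction > 1)
    stopf("csf_contaminant_fraction must lie in [0, 1]")
  if (length_sd_retino < 0 || length_sd_nonretino < 0 || noise_sd < 0)
    stopf("standard deviations must be nonnegative")
  if (length(length_range_mm) != 2L || length_range_mm[1] <= 0 ||
      length_range_mm[2] <= length_range_mm[1])
    stopf("length_range_mm must be an increasing positive pair")
  if (step_mm <= 0) stopf("step_mm must be positive")
  structure(list(
    seed = as.integer(seed),
    n_streamlines = as.integer(n_streamlines),
    n_streamlines_per_cell = n_streamlines_per_cell,
    retino_bias = retino_bias,
    length_mean_retino = length_mean_retino,
    length_sd_retino = length_sd_retino,
    length_mean_nonretino = length_mean_nonretino,
    length_sd_nonretino = length_sd_nonretino,
    length_range_mm = length_range_mm,
    step_mm = step_mm,
    csf_contaminant_fraction = csf_contaminant_fraction,
    noise_sd = noise_sd,
    hemodynamic_delay_s = hemodynamic_delay_s,
    drift_amplitude = drift_amplitude,
    bold_amplitude = bold_amplitude,
    bold_baseline = bold_baseline
  ), class = "generator_config")
}

#' Build a flat retinotopic cortical patch with ground truth
#'
#' The patch is a triangulated square grid embedded in 3D at z = 0, split into
#' two adjacent bands labelled V1 and V2. Eccentricity increases along the
#' band axis (x) in both areas; polar angle increases along the orthogonal
#' axis (y) within V1 and decreases within V2, so the two areas carry opposite
#' visual field signs (mirror vs non-mirror representation), as across the
#' real V1/V2 border.
#'
#' @param n_vertices_per_axis grid size per axis (>= 4); the patch has
#'   `n_vertices_per_axis^2` vertices.
#' @param layout list with `spacing_mm` (vertex spacing, default 1) and
#'   `ecc_max_deg` (eccentricity at the far edge, default 8).
#' @return object of class `retino_patch` with fields `vertex_coords` (N x 3,
#'   mm), `faces` (M x 3 vertex indices, counter-clockwise in the plane),
#'   `ecc_true` (deg), `pol_true` (radians in [0, 2*pi)), `area_label`
#'   (character: "V1", "V2" or "none").
#' @export
make_retino_patch <- function(n_vertices_per_axis = 12L,
                              layout = list(spacing_mm = 1, ecc_max_deg = 8)) {
  n <- n_vertices_per_axis
  if (!is_count(n) || n < 4) stopf("n_vertices_per_axis must be an integer >= 4")
  spacing <- if (is.null(layout$spacing_mm)) 1 else layout$spacing_mm
  ecc_max <- if (is.null(layout$ecc_max_deg)) 8 else layout$ecc_max_deg
  if (spacing <= 0 || ecc_max <= 0) stopf("layout spacing and eccentricity range must be positive")

  col <- rep(seq_len(n), times = n)     # x / eccentricity axis
  row <- rep(seq_len(n), each = n)      # y / polar axis
  coords <- cbind(x = (col - 1) * spacing, y = (row - 1) * spacing, z = 0)

  m1 <- floor(n / 2)                    # V1 rows 1..m1, V2 rows m1+1..n
  m2 <- n - m1
  if (m1 < 2 || m2 < 2) stopf("layout produces a degenerate V1 or V2 band")
  area <- ifelse(row <= m1, "V1", "V2")

  ecc <- (col - 1) / (n - 1) * ecc_max
  pol <- numeric(n * n)
  in1 <- area == "V1"
  # polar phases leave an empty guard arc at least 1.2 rad wider than the
  # between-row phase step (step = (2*pi - 1.2)/m for m rows), centered away
  # from the phase origin: noisy estimates then neither straddle the wrap
  # point nor make an in-data gap overtake the guard arc as the widest gap
  pol_layout <- function(m) {
    step <- (2 * pi - 1.2) / m
    span <- (m - 1) * step
    list(step = step, offset = (2 * pi - span) / 2)
  }
  l1 <- pol_layout(m1); l2 <- pol_layout(m2)
  pol[in1] <- l1$offset + l1$step * (row[in1] - 1)
  r2 <- row[!in1] - m1 - 1
  pol[!in1] <- l2$offset + l2$step * (m2 - 1 - r2)  # mirrored gradient in V2

  # two triangles per grid square, counter-clockwise in the xy plane
  i0 <- rep(seq_len(n - 1), times = n - 1)
  j0 <- rep(seq_len(n - 1), each = n - 1)
  v00 <- (j0 - 1) * n + i0
  v10 <- v00 + 1
  v01 <- v00 + n
  v11 <- v01 + 1
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  structure(list(
    vertex_coords = coords,
    faces = faces,
    ecc_true = ecc,
    pol_true = pol,
    area_label = area,
    n_per_axis = as.integer(n)
  ), class = "retino_patch")
}

#' Ground-truth segment identifiers of a synthetic patch
#'
#' Applies the same rule used by [segment_v1_v2()] to the noiseless ground
#' truth: per area, eccentricity and polar angle are min-max scaled to (0,1),
#' polar angle split in two and eccentricity in three equal half-open bins,
#' giving segment ids 1-6 in V1 and 7-12 in V2.
#'
#' @param patch a `retino_patch`.
#' @return integer vector of per-vertex segment ids (0 outside V1/V2).
#' @export
ground_truth_segments <- function(patch) {
  seg <- integer(length(patch$ecc_true))
  for (area in c("V1", "V2")) {
    idx <- patch$area_label == area
    seg[idx] <- bin_segments(patch$ecc_true[idx], patch$pol_true[idx],
                             offset = if (area == "V1") 0L else 6L)
  }
  seg
}

# Shared binning rule: min-max scale to (0,1), half-open bins [a, b).
# With `circular = TRUE` (phase-domain inputs) the empty part of the circle is
# first rotated away from the phase origin (via the circular mean); otherwise
# vertices whose true phase sits near 0 wrap to ~2*pi under noise and wreck
# the scaling. Ground-truth maps are plain linear quantities and skip this.
bin_segments <- function(ecc, pol, offset = 0L, circular = FALSE) {
  if (circular) {
    ecc <- rotate_gap(ecc)
    pol <- rotate_gap(pol)
  }
  se <- minmax_scale(ecc)
  sp <- minmax_scale(pol)
  ecc_bin <- pmin(floor(se * 3), 2)
  pol_bin <- pmin(floor(sp * 2), 1)
  as.integer(1 + pol_bin * 3 + ecc_bin + offset)
}

# Rotate circular data so the midpoint of its largest empty arc lands at the
# phase origin: a rigid shift that leaves min-max-scaled values unchanged when
# the data already sit clear of the origin, and unwraps them when noise has
# pushed some values across it. Requires the coding's guard band to be wider
# than any in-data step (see encode_phase), which makes the largest gap
# identifiable.
rotate_gap <- function(phase) {
  u <- sort(unique(wrap_2pi(phase)))
  if (length(u) < 2) return(wrap_2pi(phase))
  gaps <- c(diff(u), u[1] + 2 * pi - u[length(u)])
  k <- which.max(gaps)
  center <- wrap_2pi(u[k] + gaps[k] / 2)
  wrap_2pi(phase - center)
}

minmax_scale <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) stopf("cannot scale a constant map (zero range)")
  (x - r[1]) / (r[2] - r[1])
}

#' Simulate a pair of opposite-direction phase-encoded BOLD runs
#'
#' Per vertex the signal is
#' `baseline + A * cos(2*pi*f*t - direction*phi_true - delta) + drift + noise`
#' with stimulus frequency `f = 1/cycle_period_s`, `phi_true` the vertex's
#' true phase (eccentricity or polar angle coded half-open into [0, 2*pi)) and
#' `delta = 2*pi*f*hemodynamic_delay_s` the common hemodynamic phase delay.
#' Forward and reversed runs share the configuration seed but carry
#' independent noise, as two separately acquired runs would.
#'
#' @param patch a `retino_patch`.
#' @param cfg a `generator_config`.
#' @param dimension `"eccentricity"` or `"polar"`.
#' @param tr_s repetition time (s).
#' @param cycle_period_s stimulus cycle period (s); 36 s (eccentricity) and
#'   60 s (polar angle) are the usual phase-encoded paradigm values.
#' @param n_cycles number of stimulus cycles presented (may be fractional;
#'   default 8.25). The run holds `ceiling(n_cycles*cycle_period_s/tr_s)`
#'   samples.
#' @return list with elements `forward` and `reversed`, each a `bold_run`
#'   (fields: `series` N x T, `tr_s`, `cycle_period_s`, `n_cycles`,
#'   `direction` +1/-1, `dimension`), plus `phi_true` and `delta`.
#' @export
simulate_phase_encoded_runs <- function(patch, cfg,
                                        dimension = c("eccentricity", "polar"),
                                        tr_s = 3,
                                        cycle_period_s = if (match.arg(dimension) == "eccentricity") 36 else 60,
                                        n_cycles = 8.25) {
  dimension <- match.arg(dimension)
  if (tr_s <= 0 || cycle_period_s <= 0) stopf("tr_s and cycle_period_s must be positive")
  if (cycle_period_s <= 2 * tr_s) stopf("cycle_period_s must exceed 2*tr_s (Nyquist)")
  if (n_cycles <= 0) stopf("n_cycles must be positive")

  phi <- if (dimension == "eccentricity") encode_phase(patch$ecc_true) else patch$pol_true
  n_t <- ceiling(n_cycles * cycle_period_s / tr_s)
  t_s <- (seq_len(n_t) - 1) * tr_s
  f <- 1 / cycle_period_s
  delta <- 2 * pi * f * cfg$hemodynamic_delay_s
  n_v <- length(phi)

  make_run <- function(direction, noise, drift) {
    arg <- outer(direction * phi + delta, 2 * pi * f * t_s, function(p, wt) wt - p)
    series <- cfg$bold_baseline + cfg$bold_amplitude * cos(arg) + drift + noise
    structure(list(series = series, tr_s = tr_s, cycle_period_s = cycle_period_s,
                   n_cycles = n_cycles, direction = direction, dimension = dimension,
                   t0_s = 0), class = "bold_run")
  }

  seed_off <- if (dimension == "eccentricity") 11L else 13L
  out <- with_seed(cfg$seed + seed_off, {
    drift_of <- function() {
      if (cfg$drift_amplitude == 0) return(0)
      # slow cosine (period = twice the run) plus a linear trend, per vertex
      ph <- runif(n_v, 0, 2 * pi)
      a1 <- rnorm(n_v, 0, cfg$drift_amplitude)
      a2 <- rnorm(n_v, 0, cfg$drift_amplitude)
      dur <- n_t * tr_s
      outer(seq_len(n_v), t_s, function(v, tt) {
        a1[v] * cos(2 * pi * tt / (2 * dur) + ph[v]) + a2[v] * (tt / dur - 0.5)
      })
    }
    noise_of <- function() {
      if (cfg$noise_sd == 0) return(0)
      matrix(rnorm(n_v * n_t, 0, cfg$noise_sd), n_v, n_t)
    }
    fwd <- make_run(+1, noise_of(), drift_of())
    rev <- make_run(-1, noise_of(), drift_of())
    list(forward = fwd, reversed = rev)
  })
  out$phi_true <- phi
  out$delta <- delta
  out
}

# Linear phase coding of a map into [0, 2*pi): the value range maps onto
# [guard, 2*pi - guard] (radians). The symmetric guard band keeps noisy
# estimates clear of the wrap point and leaves the empty arc of the circle
# wider than in-data phase steps, so the gap-rotation step of the
# segmentation stays unambiguous.
encode_phase <- function(v, guard = 0.9) {
  u <- range(v)
  if (u[2] - u[1] <= 0) return(rep(pi, length(v)))
  guard + (2 * pi - 2 * guard) * (v - u[1]) / (u[2] - u[1])
}

#' Rasterize a labelled patch into a segment label volume
#'
#' Each labelled vertex is written into the voxel containing it; a CSF slab is
#' added below the patch plane. Label codes: 0 background, 1-6 V1 segments,
#' 7-12 V2 segments, 13 CSF. The affine maps 0-based voxel indices to the mm
#' coordinates of voxel centers.
#'
#' @param patch a `retino_patch`.
#' @param segments per-vertex segment ids (1-6 on V1, 7-12 on V2, 0 elsewhere),
#'   e.g. from [ground_truth_segments()] or [segment_v1_v2()].
#' @param voxel_size_mm isotropic voxel edge (> 0).
#' @param csf_layout list with `z_mm`, the mm z-range of the CSF slab
#'   (default c(-9, -5), i.e. below the patch plane at z = 0).
#' @param pad_mm spatial margin around the patch.
#' @return object of class `segment_label_volume`: `grid` (3D integer array),
#'   `affine` (4x4 voxel-to-mm), `voxel_size_mm`, `csf_label` (13).
#' @export
make_label_volume <- function(patch, segments, voxel_size_mm = 1,
                              csf_layout = list(z_mm = c(-9, -5)),
                              pad_mm = 2) {
  if (voxel_size_mm <= 0) stopf("voxel_size_mm must be positive")
  if (length(segments) != nrow(patch$vertex_coords))
    stopf("segments must have one id per patch vertex")
  on_v1 <- patch$area_label == "V1" & segments != 0
  on_v2 <- patch$area_label == "V2" & segments != 0
  if (any(!segments[on_v1] %in% 1:6) || any(!segments[on_v2] %in% 7:12))
    stopf("segment ids must be 1-6 within V1 and 7-12 within V2")

  lo <- apply(patch$vertex_coords, 2, min) - pad_mm
  hi <- apply(patch$vertex_coords, 2, max) + pad_mm
  lo[3] <- min(lo[3], csf_layout$z_mm[1] - pad_mm)
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size_mm)) + 1L)
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- lo

  grid <- array(0L, dim = dims)
  idx <- world_to_voxel(patch$vertex_coords, affine)
  keep <- segments != 0
  grid[idx[keep, , drop = FALSE] + 1L] <- as.integer(segments[keep])

  zc <- lo[3] + (seq_len(dims[3]) - 1) * voxel_size_mm
  csf_z <- which(zc >= csf_layout$z_mm[1] & zc <= csf_layout$z_mm[2])
  if (length(csf_z)) {
    slab <- grid[, , csf_z, drop = FALSE]
    slab[slab == 0L] <- 13L
    grid[, , csf_z] <- slab
  }

  structure(list(grid = grid, affine = affine, voxel_size_mm = voxel_size_mm,
                 csf_label = 13L),
            class = "segment_label_volume")
}

# 0-based voxel index of mm points (n x 3): voxel (i,j,k) spans
# [i-0.5, i+0.5) in continuous voxel coordinates.
world_to_voxel <- function(points_mm, affine) {
  pts <- rbind(t(points_mm), 1)
  v <- solve(affine) %*% pts
  t(floor(v[1:3, , drop = FALSE] + 0.5))
}

voxel_to_world <- function(idx0, affine) {
  pts <- rbind(t(idx0), 1)
  t((affine %*% pts)[1:3, , drop = FALSE])
}

#' Cell probabilities of the streamline generator
#'
#' Diagonal (retinotopically corresponding) cells share `retino_bias`
#' uniformly; off-diagonal cells share the remainder uniformly. With
#' `retino_bias = 1/6` every cell has probability 1/36 (chance).
#'
#' @param retino_bias diagonal mass fraction in [0, 1].
#' @return 6x6 matrix of probabilities summing to 1.
#' @export
cell_probs <- function(retino_bias) {
  p <- matrix((1 - retino_bias) / 30, 6, 6)
  diag(p) <- retino_bias / 6
  p
}

#' Draw a 6x6 table of streamline counts from the generator's cell distribution
#'
#' This is the exact multinomial step [simulate_streamlines()] performs before
#' building geometry; it is exposed so distribution-level studies (power,
#' type-I calibration) can run without polyline construction.
#'
#' @param cfg a `generator_config`.
#' @param n total count (default `cfg$n_streamlines`).
#' @return 6x6 integer matrix.
#' @export
simulate_cell_counts <- function(cfg, n = cfg$n_streamlines) {
  with_seed(cfg$seed + 29L, draw_cell_counts(cfg, n))
}

draw_cell_counts <- function(cfg, n = cfg$n_streamlines) {
  if (!is.null(cfg$n_streamlines_per_cell)) return(cfg$n_streamlines_per_cell)
  matrix(stats::rmultinom(1, n, as.vector(cell_probs(cfg$retino_bias))), 6, 6)
}

#' Simulate a U-shaped streamline set between V1 and V2 segments
#'
#' For each streamline a cell (i, j) is drawn from the generator's 6x6 cell
#' distribution (or taken from the explicit per-cell table), endpoints are
#' placed uniformly inside a random voxel of V1 segment i and V2 segment j
#' (jittered strictly inside the voxel so endpoint assignment round-trips
#' exactly), and a smooth circular arc bulging out of the patch plane is
#' sampled at `cfg$step_mm` steps. Arc lengths are drawn from the
#' cell-appropriate truncated normal (16 +/- 4 mm for diagonal, 32 +/- 13 mm
#' for off-diagonal cells by default), confined to the tracking range and to
#' lengths achievable for the endpoint chord. A `csf_contaminant_fraction` of
#' streamlines is instead routed through the CSF slab and tagged.
#'
#' @param labels a `segment_label_volume` containing all 12 segments.
#' @param cfg a `generator_config`.
#' @return object of class `streamline_set`: `streamlines` (list of n x 3 mm
#'   matrices), `lengths` (polyline arc lengths, mm), `true_cell` (n x 2
#'   matrix of ground-truth V1/V2 segment indices 1-6), `csf_tag` (logical).
#' @export
simulate_streamlines <- function(labels, cfg) {
  seg_voxels <- lapply(1:12, function(s) which(labels$grid == s, arr.ind = TRUE) - 1L)
  if (any(vapply(seg_voxels, nrow, 0L) == 0L))
    stopf("label volume must contain all 12 V1/V2 segments")
  vs <- labels$voxel_size_mm
  lo <- cfg$length_range_mm[1]; hi <- cfg$length_range_mm[2]
  csf_mid <- csf_slab_mid_z(labels)

  with_seed(cfg$seed + 37L, {
    counts <- draw_cell_counts(cfg)
    n <- sum(counts)
    cells <- which(counts > 0, arr.ind = TRUE)
    ii <- unlist(mapply(function(r, k) rep(r, k), cells[, 1], counts[cells], SIMPLIFY = FALSE))
    jj <- unlist(mapply(function(r, k) rep(r, k), cells[, 2], counts[cells], SIMPLIFY = FALSE))
    if (n == 0L) {
      return(new_streamline_set(list(), numeric(0), cbind(integer(0), integer(0)),
                                logical(0), cfg$step_mm))
    }
    is_csf <- stats::runif(n) < cfg$csf_contaminant_fraction

    streamlines <- vector("list", n)
    lengths <- numeric(n)
    for (s in seq_len(n)) {
      i <- ii[s]; j <- jj[s]
      mu <- if (i == j) cfg$length_mean_retino else cfg$length_mean_nonretino
      sdv <- if (i == j) cfg$length_sd_retino else cfg$length_sd_nonretino
      poly <- NULL
      for (try in 1:50) {
        p <- sample_in_voxel(seg_voxels[[i]], labels$affine, vs)
        q <- sample_in_voxel(seg_voxels[[j + 6L]], labels$affine, vs)
        chord <- sqrt(sum((q - p)^2))
        if (is_csf[s]) {
          depth <- (p[3] + q[3]) / 2 - csf_mid + stats::runif(1, -0.2, 0.2)
          poly <- arc_through_depth(p, q, depth, cfg$step_mm)
          break
        }
        lmin <- max(lo, chord * 1.02)
        if (lmin >= hi) next  # infeasible endpoints; resample
        len <- rtruncnorm1(mu, sdv, lmin, hi)
        poly <- arc_of_length(p, q, len, cfg$step_mm)
        break
      }
      if (is.null(poly))
        stopf("could not place endpoints with a feasible length for cell (%d,%d)", i, j)
      streamlines[[s]] <- poly
      lengths[s] <- polyline_length(poly)
    }
    new_streamline_set(streamlines, lengths, cbind(ii, jj), is_csf, cfg$step_mm)
  })
}

new_streamline_set <- function(streamlines, lengths, true_cell, csf_tag, step_mm) {
  colnames(true_cell) <- c("v1", "v2")
  structure(list(streamlines = streamlines, lengths = lengths,
                 true_cell = true_cell, csf_tag = csf_tag, step_mm = step_mm),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("streamline_set: %d streamlines, lengths %.1f-%.1f mm (%d CSF-tagged)\n",
              length(x$streamlines),
              if (length(x$lengths)) min(x$lengths) else NA,
              if (length(x$lengths)) max(x$lengths) else NA,
              sum(x$csf_tag)))
  invisible(x)
}

csf_slab_mid_z <- function(labels) {
  kz <- which(apply(labels$grid == labels$csf_label, 3, any))
  if (!length(kz)) stopf("label volume has no CSF slab")
  mid_k <- mean(range(kz)) - 1  # 0-based
  voxel_to_world(cbind(0, 0, mid_k), labels$affine)[3]
}

# uniform point strictly inside a random voxel of the given 0-based index list
sample_in_voxel <- function(vox, affine, voxel_size) {
  v <- vox[sample.int(nrow(vox), 1L), ]
  center <- voxel_to_world(matrix(v, 1), affine)[1, ]
  center + stats::runif(3, -0.45, 0.45) * voxel_size
}

# exact truncated normal via inverse CDF
rtruncnorm1 <- function(mu, sd, lo, hi) {
  if (sd <= 0) return(min(max(mu, lo), hi))
  plo <- stats::pnorm(lo, mu, sd); phi <- stats::pnorm(hi, mu, sd)
  if (phi - plo < 1e-12) return(min(max(lo, mu), hi))
  stats::qnorm(stats::runif(1, plo, phi), mu, sd)
}

# Circular arc from p to q with arc length `len`, bulging toward +z.
arc_of_length <- function(p, q, len, step) {
  d <- q - p
  chord <- sqrt(sum(d^2))
  if (len <= chord * (1 + 1e-9)) {  # straight segment
    npts <- max(2L, ceiling(chord / step) + 1L)
    return(cbind(seq(p[1], q[1], length.out = npts),
                 seq(p[2], q[2], length.out = npts),
                 seq(p[3], q[3], length.out = npts)))
  }
  ratio <- chord / len
  theta <- stats::uniroot(function(th) sin(th) / th - ratio,
                          c(1e-9, pi), tol = 1e-12)$root
  radius <- len / (2 * theta)
  sample_arc(p, q, radius, theta, bulge_sign = +1, step = step)
}

# Circular arc whose apex lies `depth` mm below the chord midpoint (-z bulge).
arc_through_depth <- function(p, q, depth, step) {
  chord <- sqrt(sum((q - p)^2))
  depth <- max(depth, 0.5)
  radius <- (chord^2 / 4 + depth^2) / (2 * depth)
  theta <- atan2(chord / 2, radius - depth)
  sample_arc(p, q, radius, theta, bulge_sign = -1, step = step)
}

sample_arc <- function(p, q, radius, theta, bulge_sign, step) {
  d <- q - p
  chord <- sqrt(sum(d^2))
  u <- d / chord                       # along-chord unit vector
  w <- c(0, 0, bulge_sign)             # bulge direction
  # orthonormalize w against u (u is never parallel to z for patch endpoints,
  # but guard against it)
  w <- w - sum(w * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-9) {
    w <- c(1, 0, 0) - u[1] * u
    nw <- sqrt(sum(w^2))
  }
  w <- w / nw
  m <- (p + q) / 2
  center <- m - (radius * cos(theta)) * w
  len <- 2 * radius * theta
  npts <- max(2L, ceiling(len / step) + 1L)
  alpha <- seq(-theta, theta, length.out = npts)
  sweep(outer(sin(alpha), radius * u, "*") + outer(cos(alpha), radius * w, "*"),
        2, center, "+")
}

polyline_length <- function(poly) {
  if (nrow(poly) < 2) return(0)
  sum(sqrt(rowSums(diff(poly)^2)))
}

#' Simulate a b = 0 image time series with a coil-dependent tSNR profile
#'
#' Voxel temporal means are fixed; temporal noise SD is set so the target tSNR
#' follows the requested coil profile. The `"surface"` profile emulates a
#' flexible surface receive coil: tSNR is `near_deep_ratio` times higher in a
#' band near one face of the volume than in the deep band, with a linear ramp
#' between (the two flat bands are the natural near/deep ROI presets, see
#' [b0_roi_presets()]).
#'
#' @param shape integer triple of spatial dimensions.
#' @param n_volumes number of time points (>= 3).
#' @param coil_profile `"uniform"` or `"surface"`.
#' @param cfg a `generator_config` (seed source).
#' @param target_tsnr tSNR of the uniform profile / of the deep band.
#' @param near_deep_ratio near-face over deep tSNR ratio (default 1.7).
#' @param mean_signal fixed voxel temporal mean.
#' @return object of class `b0_series`: `data` (4D array), `tsnr_target`
#'   (3D array), `shape`, `n_volumes`.
#' @export
simulate_b0_series <- function(shape, n_volumes,
                               coil_profile = c("uniform", "surface"),
                               cfg = generator_config(),
                               target_tsnr = 20, near_deep_ratio = 1.7,
                               mean_signal = 100) {
  coil_profile <- match.arg(coil_profile)
  if (!is_count(n_volumes) || n_volumes < 3) stopf("n_volumes must be an integer >= 3")
  if (length(shape) != 3L || any(shape < 1)) stopf("shape must be a positive integer triple")
  if (!is.finite(target_tsnr) || target_tsnr <= 0)
    stopf("target_tsnr must be finite and positive (zero-noise series are not simulated)")
  if (near_deep_ratio <= 0) stopf("near_deep_ratio must be positive")

  nz <- shape[3]
  prof <- rep(target_tsnr, nz)
  if (coil_profile == "surface") {
    b <- band_bounds(nz)
    ramp <- rep(0, nz)
    ramp[seq_len(b$near_end)] <- 1
    if (b$deep_start - b$near_end > 1) {
      k <- (b$near_end + 1):(b$deep_start - 1)
      ramp[k] <- 1 - (k - b$near_end) / (b$deep_start - b$near_end)
    }
    prof <- target_tsnr * (1 + (near_deep_ratio - 1) * ramp)
  }
  tsnr_target <- array(rep(prof, each = shape[1] * shape[2]), dim = shape)

  data <- with_seed(cfg$seed + 53L, {
    sd_vox <- mean_signal / tsnr_target
    noise <- array(stats::rnorm(prod(shape) * n_volumes), dim = c(shape, n_volumes))
    mean_signal + noise * array(rep(sd_vox, n_volumes), dim = c(shape, n_volumes))
  })
  structure(list(data = data, tsnr_target = tsnr_target,
                 shape = as.integer(shape), n_volumes = as.integer(n_volumes)),
            class = "b0_series")
}

band_bounds <- function(nz) {
  list(near_end = max(1L, floor(nz / 4)), deep_start = min(nz, ceiling(3 * nz / 4)))
}

#' Near/deep ROI presets matching the surface-coil tSNR profile
#'
#' Labels the flat near-face band 1 and the flat deep band 2 (the ramp between
#' them is unlabelled), mirroring a proximal (~2-3 cm) and a distal (> 5 cm)
#' ROI relative to the coil surface.
#'
#' @param shape integer triple of spatial dimensions.
#' @return 3D integer array of ROI labels.
#' @export
b0_roi_presets <- function(shape) {
  nz <- shape[3]
  b <- band_bounds(nz)
  lab <- array(0L, dim = shape)
  lab[, , seq_len(b$near_end)] <- 1L
  lab[, , b$deep_start:nz] <- 2L
  lab
}
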