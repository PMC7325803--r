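# Phase recovery, run combination, field sign and segmentation.

make_run <- function(series, tr_s = 3, cycle_period_s = 36, n_cycles = 8,
                     direction = 1, dimension = "eccentricity") {
  structure(list(series = series, tr_s = tr_s, cycle_period_s = cycle_period_s,
                 n_cycles = n_cycles, direction = direction, dimension = dimension),
            class = "bold_run")
}

sinusoid_series <- function(phi, n_t = 96, tr_s = 3, period = 36, amp = 1) {
  t_s <- (seq_len(n_t) - 1) * tr_s
  outer(phi, t_s, function(p, tt) amp * cos(2 * pi * tt / period - p))
}

test_that("quarter-cycle discard removes the right samples and guards short runs", {
  run <- make_run(matrix(rnorm(2 * 99), 2, 99), n_cycles = 8.25)
  out <- discard_initial_quarter_cycle(run)
  expect_equal(ncol(out$series), 96)  # 0.25*36/3 = 3 samples dropped
  expect_equal(out$n_cycles, 8)
  expect_identical(out$series, run$series[, -(1:3)])

  short <- make_run(matrix(rnorm(2 * 12), 2, 12), n_cycles = 1)
  expect_error(discard_initial_quarter_cycle(short), "full cycle")
})

test_that("high-pass filter preserves the stimulus component and removes drift", {
  phi <- c(0.4, 1.7, 3.3, 5.1)
  clean <- sinusoid_series(phi)
  run <- make_run(clean)

  # passband identity for a pure stimulus sinusoid
  filt <- highpass_filter(run, cutoff_hz = 1 / 72)
  expect_lt(max(abs(Arg(fourier_phase(filt)) %% (2 * pi) - phi)), 0.01)

  # DC removal
  run_dc <- make_run(clean + 50)
  expect_lt(max(abs(rowMeans(highpass_filter(run_dc)$series))), 1e-8)

  # sinusoid + linear drift: recovered phase matches the drift-free phase
  t_s <- (0:95) * 3
  drift <- outer(c(2, -3, 1, 4), t_s / max(t_s))
  run_dr <- make_run(clean + drift + 30)
  ph <- Arg(fourier_phase(highpass_filter(run_dr, 1 / 72))) %% (2 * pi)
  expect_lt(max(abs(ph - phi)), 0.02)

  expect_error(highpass_filter(run, cutoff_hz = 1 / 30), "destroy")
})

test_that("Fourier phase follows the cos(2*pi*f*t - phi) convention and DFT orthogonality", {
  phi <- 1.0
  run <- make_run(sinusoid_series(phi))
  coeff <- fourier_phase(run)
  expect_equal(Arg(coeff), rep(phi, nrow(run$series)), tolerance = 1e-10)
  expect_equal(Mod(coeff), rep(1, nrow(run$series)), tolerance = 1e-10)

  # stimulus sinusoid + off-frequency sinusoid over integer cycles: the
  # coefficient picks out the stimulus component only (checked against a
  # brute-force inner product at the stimulus frequency)
  n_t <- 96; t_s <- (0:(n_t - 1)) * 3
  stim <- cos(2 * pi * t_s / 36 - 2.2)
  other <- 0.8 * cos(2 * pi * 5 * t_s / (n_t * 3) - 0.7)  # 5 cycles/run (stim = 8)
  series <- matrix(stim + other, 1)
  coeff2 <- fourier_phase(make_run(series))
  brute <- sum(series[1, ] * exp(2i * pi * 8 * (0:(n_t - 1)) / n_t)) * 2 / n_t
  expect_equal(coeff2, brute, tolerance = 1e-12)
  expect_equal(Arg(coeff2), 2.2, tolerance = 1e-10)

  expect_warning(fourier_phase(make_run(matrix(rnorm(99), 1, 99), n_cycles = 8.25)),
                 "leakage")
})

test_that("opposite-run combination cancels the hemodynamic delay", {
  phi <- seq(0.3, 5.5, length.out = 40)
  for (delta in c(0, 0.4, 1.2)) {
    fwd <- complex(modulus = 1, argument = phi + delta)
    rev <- complex(modulus = 1, argument = -phi + delta)
    pm <- combine_opposite_runs(fwd, rev)
    expect_lt(max(abs(atan2(sin(pm$phase - phi), cos(pm$phase - phi)))), 1e-10)
  }
  # delta = 0, rev = conj(fwd): combined equals the forward phase
  fwd <- complex(modulus = 2, argument = phi)
  pm0 <- combine_opposite_runs(fwd, Conj(fwd))
  expect_equal(pm0$phase, phi %% (2 * pi), tolerance = 1e-12)
  expect_equal(pm0$amplitude, rep(2, length(phi)))

  # zero amplitude in both runs: flagged, phase NA
  pmz <- combine_opposite_runs(complex(real = c(0, 1)), complex(real = c(0, 1)))
  expect_true(pmz$flagged[1]); expect_true(is.na(pmz$phase[1]))
  expect_false(pmz$flagged[2])
})

test_that("noisy phase estimation reaches the expected accuracy at amplitude SNR 10", {
  set.seed(31)
  n_v <- 200; n_t <- 96
  phi <- runif(n_v, 0.3, 5.8)
  # complex coefficient noise SD per component is sd*sqrt(2/T); SNR 10
  sd_noise <- sqrt(n_t / 2) / 10
  # fwd: phase phi + 0.9; rev: phase -phi + 0.9 (delta = 0.9)
  fwd <- make_run(sinusoid_series(phi + 0.9) + matrix(rnorm(n_v * n_t, 0, sd_noise), n_v))
  rev <- make_run(sinusoid_series(-phi + 0.9) + matrix(rnorm(n_v * n_t, 0, sd_noise), n_v))
  pm <- combine_opposite_runs(fourier_phase(fwd), fourier_phase(rev))
  err <- abs(atan2(sin(pm$phase - phi), cos(pm$phase - phi)))
  expect_lt(mean(err), 0.1)
})

test_that("phase estimates are rotation-equivariant", {
  phi <- seq(0.5, 4.5, length.out = 10)
  shift <- 0.8
  c1 <- fourier_phase(make_run(sinusoid_series(phi)))
  c2 <- fourier_phase(make_run(sinusoid_series(phi + shift)))
  dphi <- (Arg(c2) - Arg(c1)) %% (2 * pi)
  expect_equal(dphi, rep(shift, 10), tolerance = 1e-10)
})

test_that("field sign is +1 for right-handed maps, -1 mirrored, opposite across V1/V2", {
  patch <- make_retino_patch(8)
  # synthetic maps: ecc along +x, pol along +y -> sign +1 everywhere
  mk_map <- function(vals, dim) structure(list(phase = vals, amplitude = rep(1, length(vals)),
                                               dimension = dim, flagged = rep(FALSE, length(vals))),
                                          class = "phase_map")
  ex <- mk_map(patch$vertex_coords[, 1] * 0.3, "eccentricity")
  py <- mk_map(patch$vertex_coords[, 2] * 0.3, "polar")
  fs <- field_sign(patch, ex, py)
  expect_true(all(fs == 1))
  # pol along -y -> mirrored, sign -1
  py_m <- mk_map(-patch$vertex_coords[, 2] * 0.3, "polar")
  expect_true(all(field_sign(patch, ex, py_m) == -1))

  # generator's own maps: opposite uniform signs in V1 and V2
  cfg <- generator_config(seed = 12, noise_sd = 0)
  re <- simulate_phase_encoded_runs(patch, cfg, "eccentricity", tr_s = 3)
  rp <- simulate_phase_encoded_runs(patch, cfg, "polar", tr_s = 3)
  em <- estimate_phase_map(re$forward, re$reversed)
  pm <- estimate_phase_map(rp$forward, rp$reversed)
  fs2 <- field_sign(patch, em, pm)
  expect_true(all(fs2[patch$area_label == "V1"] == 1))
  expect_true(all(fs2[patch$area_label == "V2"] == -1))

  # amplitude threshold zeroes out weak vertices
  ex_weak <- ex; ex_weak$amplitude[1] <- 0
  expect_equal(field_sign(patch, ex_weak, py, amplitude_threshold = 0.5)[1], 0L)
})

test_that("segment binning follows the half-open 2x3 rule and partitions V1 u V2", {
  # direct binning checks via scaled coordinates: (pol, ecc) = (0.2, 0.5) -> 2
  area <- rep(c("V1", "V2"), each = 4)
  mk_map <- function(vals) structure(list(phase = vals, amplitude = rep(1, 8),
                                          flagged = rep(FALSE, 8)), class = "phase_map")
  # V1 block: ecc values scale to {0, .5, .75, 1}, pol to {0, .2, .9, 1}
  ecc <- mk_map(c(0, 0.5, 0.75, 1, 0, 0.3, 0.9, 1))
  pol <- mk_map(c(0, 0.2, 0.9, 1, 0, 0.4, 0.9, 1))
  seg <- segment_v1_v2(ecc, pol, area)
  expect_equal(seg[2], 2L)   # V1, pol 0.2 lower band, ecc 0.5 middle third
  expect_equal(seg[7], 12L)  # V2, pol 0.9 upper band, ecc 0.9 top third
  expect_true(all(seg[area == "V1"] %in% 1:6))
  expect_true(all(seg[area == "V2"] %in% 7:12))

  # constant map over an area: zero range is an error
  expect_error(segment_v1_v2(ecc, mk_map(rep(0.5, 8)), area), "constant")
})

test_that("segments recover ground truth on generated data (noiseless and SNR 10)", {
  patch <- make_retino_patch(12)
  segt <- ground_truth_segments(patch)
  # noiseless, any delay: exact recovery, phases to < 0.01 rad
  for (delay in c(0, 4, 8)) {
    cfg <- generator_config(seed = 13, noise_sd = 0, hemodynamic_delay_s = delay)
    re <- simulate_phase_encoded_runs(patch, cfg, "eccentricity", tr_s = 3)
    em <- estimate_phase_map(re$forward, re$reversed)
    expect_lt(max(abs(atan2(sin(em$phase - re$phi_true), cos(em$phase - re$phi_true)))), 0.01)
    rp <- simulate_phase_encoded_runs(patch, cfg, "polar", tr_s = 3)
    pm <- estimate_phase_map(rp$forward, rp$reversed)
    seg <- segment_v1_v2(em, pm, patch$area_label)
    expect_equal(seg[segt > 0], segt[segt > 0])
  }
  # amplitude SNR 10 (unit amplitude, 96 samples): >= 95% agreement
  acc <- vapply(1:5, function(s) {
    cfg <- generator_config(seed = 20 + s, noise_sd = sqrt(48) / 10)
    re <- simulate_phase_encoded_runs(patch, cfg, "eccentricity", tr_s = 3)
    rp <- simulate_phase_encoded_runs(patch, cfg, "polar", tr_s = 3)
    seg <- segment_v1_v2(estimate_phase_map(re$forward, re$reversed),
                         estimate_phase_map(rp$forward, rp$reversed),
                         patch$area_label)
    mean(seg[segt > 0] == segt[segt > 0])
  }, 0)
  expect_true(all(acc >= 0.95))
})
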