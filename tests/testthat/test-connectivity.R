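# Endpoint assignment, retention rules, connectivity/proximity matrices,
# U-shape filtering.

test_that("streamline length matches simple geometry and a brute-force sum", {
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(streamline_length(rbind(c(1, 1, 1), c(1, 1, 1))), 0)
  set.seed(41)
  arc <- matrix(cumsum(rnorm(300, 0, 0.1)), ncol = 3)
  brute <- sum(vapply(2:100, function(r) sqrt(sum((arc[r, ] - arc[r - 1, ])^2)), 0))
  expect_equal(streamline_length(arc), brute)
  expect_error(streamline_length(matrix(0, 1, 3)), "two points")
})

test_that("endpoint assignment uses the containing-voxel convention with 0 out of bounds", {
  labs <- fixture_identity_labels()
  # voxel (2,3,2) under identity affine contains (2.2, 3.0, 1.9); it is
  # background here, but the index convention is what matters
  expect_equal(assign_endpoint(c(2.2, 3.0, 1.9), labs),
               labs$grid[3, 4, 3])
  expect_equal(assign_endpoint(c(0, 0, 0), labs), labs$grid[1, 1, 1])
  expect_equal(assign_endpoint(c(2, 0, 0), labs), 3L)     # V1 segment 3
  expect_equal(assign_endpoint(c(2, 2, 0), labs), 9L)     # V2 segment 3
  expect_equal(assign_endpoint(c(-5, 0, 0), labs), 0L)
  expect_equal(assign_endpoint(c(100, 0, 0), labs), 0L)
  # half-open bins: 0.5 rounds into voxel 1, 0.49 stays in voxel 0
  expect_equal(assign_endpoint(c(0.5, 0, 0), labs), labs$grid[2, 1, 1])
  expect_equal(assign_endpoint(c(0.49, 0, 0), labs), labs$grid[1, 1, 1])
})

test_that("generated endpoints round-trip to their ground-truth segments", {
  labs <- fixture_labels(10)
  cfg <- generator_config(seed = 21, n_streamlines = 1000)
  tr <- simulate_streamlines(labs, cfg)
  firsts <- t(vapply(tr$streamlines, function(p) p[1, ], numeric(3)))
  lasts <- t(vapply(tr$streamlines, function(p) p[nrow(p), ], numeric(3)))
  expect_equal(assign_endpoint(firsts, labs), as.integer(tr$true_cell[, 1]))
  expect_equal(assign_endpoint(lasts, labs), as.integer(tr$true_cell[, 2] + 6L))
})

test_that("CSF traversal is detected at native sampling", {
  labs <- fixture_identity_labels()
  through <- straight_line(c(2, 0, 0), c(2, 2, 5.2), n = 40)  # crosses z=5 slab
  clear <- straight_line(c(2, 0, 0), c(2, 2, 0), n = 20)
  expect_true(traverses_csf(through, labs))
  expect_false(traverses_csf(clear, labs))

  # generator contaminants are flagged at the configured rate
  labs2 <- fixture_labels(10)
  cfg <- generator_config(seed = 22, n_streamlines = 800, csf_contaminant_fraction = 0.2)
  tr <- simulate_streamlines(labs2, cfg)
  flagged <- vapply(tr$streamlines, traverses_csf, TRUE, labels = labs2)
  expect_identical(flagged, tr$csf_tag)
  expect_lt(abs(mean(flagged) - 0.2), 3 * sqrt(0.2 * 0.8 / 800))
})

test_that("connectivity matrix applies the dual-termination and CSF rules", {
  labs <- fixture_identity_labels()
  five <- replicate(5, straight_line(c(0, 0, 0), c(0, 2, 0), n = 8), simplify = FALSE)
  tract <- fixture_streamlines(five)
  m <- build_connectivity(tract, labs)
  expect_equal(m$counts[1, 1], 5L)
  expect_equal(sum(m$counts), 5L)
  expect_equal(m$percent[1, 1], 100)

  # V1<->V1 streamline contributes nowhere
  tract2 <- fixture_streamlines(list(straight_line(c(0, 0, 0), c(3, 0, 0), n = 8)))
  m2 <- build_connectivity(tract2, labs)
  expect_equal(sum(m2$counts), 0L)
  expect_false(m2$percent_defined)
  expect_error(partition_connectivity(m2), "empty")

  # CSF-crossing V1<->V2 streamline is discarded
  tract3 <- fixture_streamlines(list(
    straight_line(c(0, 0, 0), c(0, 2, 0), n = 8),
    rbind(straight_line(c(1, 0, 0), c(1, 0, 5), n = 20),
          straight_line(c(1, 0, 5), c(1, 2, 0), n = 20))))
  m3 <- build_connectivity(tract3, labs)
  expect_equal(sum(m3$counts), 1L)
  expect_equal(m3$n_csf_discarded, 1L)
})

test_that("percent normalization, endpoint-order symmetry and count conservation hold", {
  labs <- fixture_labels(10)
  cfg <- generator_config(seed = 23, n_streamlines = 500, csf_contaminant_fraction = 0.1)
  tr <- simulate_streamlines(labs, cfg)
  m <- build_connectivity(tr, labs)
  expect_lt(abs(sum(m$percent) - 100), 1e-9)
  expect_equal(sum(m$counts) + m$n_discarded, length(tr$streamlines))

  # reversing every polyline leaves the matrix unchanged
  tr_rev <- tr
  tr_rev$streamlines <- lapply(tr$streamlines, function(p) p[nrow(p):1, , drop = FALSE])
  expect_equal(build_connectivity(tr_rev, labs)$counts, m$counts)

  # explicit table round-trip: counts equal the table exactly (no contaminants)
  tbl <- matrix(0L, 6, 6); tbl[cbind(1:6, 1:6)] <- 10L; tbl[2, 5] <- 4L
  cfg_t <- generator_config(seed = 24, n_streamlines_per_cell = tbl)
  m_t <- build_connectivity(simulate_streamlines(labs, cfg_t), labs)
  expect_equal(unname(m_t$counts), unname(tbl))
})

test_that("partition splits diagonal and off-diagonal mass correctly", {
  uni <- matrix(10L, 6, 6)
  p <- partition_connectivity(uni)
  expect_equal(p$retinotopic_pct, 100 * 6 / 36)
  expect_equal(p$retinotopic_pct + p$nonretinotopic_pct, 100)
  expect_equal(p$retinotopic_mean, p$nonretinotopic_mean)  # uniform: equal per-cell means

  dg <- diag(6) * 7
  pd <- partition_connectivity(dg)
  expect_equal(pd$retinotopic_pct, 100)
  expect_equal(pd$nonretinotopic_pct, 0)

  # generator round-trip: recovered share approx 100*b within binomial error
  labs <- fixture_labels(10)
  b <- 0.7; n <- 2000
  tr <- simulate_streamlines(labs, generator_config(seed = 25, n_streamlines = n, retino_bias = b))
  share <- partition_connectivity(build_connectivity(tr, labs))$retinotopic_pct
  expect_lt(abs(share - 100 * b), 3 * 100 * sqrt(b * (1 - b) / n))
})

test_that("proximity matrix averages reciprocal lengths with undefined cells flagged", {
  labs <- fixture_identity_labels()
  # two streamlines in cell (1,1) of lengths 10 and 20 mm (straight, in-plane)
  poly10 <- straight_line(c(0, 0, 0), c(0, 2, 0), n = 5)
  tract <- fixture_streamlines(list(poly10, poly10))
  tract$lengths <- c(10, 20)  # lengths enter the statistic directly
  pm <- proximity_matrix(tract, labs)
  expect_equal(pm$mean_recip_len[1, 1], (0.1 + 0.05) / 2)
  expect_true(is.na(pm$mean_recip_len[2, 2]))
  expect_false(pm$defined_mask[2, 2])

  single <- fixture_streamlines(list(poly10)); single$lengths <- 16
  expect_equal(proximity_matrix(single, labs)$mean_recip_len[1, 1], 0.0625)

  # generator defaults: diagonal (short) cells show higher proximity
  labs2 <- fixture_labels(10)
  tr <- simulate_streamlines(labs2, generator_config(seed = 26, n_streamlines = 2000, retino_bias = 0.5))
  pmx <- proximity_matrix(tr, labs2)$mean_recip_len
  expect_gt(mean(diag(pmx), na.rm = TRUE), mean(pmx[row(pmx) != col(pmx)], na.rm = TRUE))
})

test_that("group averaging is element-wise with pairwise exclusion of undefined cells", {
  a <- matrix(10, 6, 6); b <- matrix(20, 6, 6)
  expect_equal(group_average(list(a))$mean, a)
  expect_equal(group_average(list(a, b))$mean, matrix(15, 6, 6))
  # order invariance
  set.seed(42)
  ms <- replicate(4, matrix(runif(36), 6, 6), simplify = FALSE)
  expect_equal(group_average(ms)$mean, group_average(rev(ms))$mean)
  # undefined cells excluded pairwise
  a[1, 1] <- NA
  g <- group_average(list(a, b))
  expect_equal(g$mean[1, 1], 20)
  expect_equal(g$n_defined[1, 1], 1)
  expect_error(group_average(list()), "empty")
})

test_that("U-shape filter retains curved short streamlines only", {
  straight <- straight_line(c(0, 0, 0), c(10, 0, 0), n = 30)
  expect_equal(turning_angle(straight), 0)
  # semicircle of radius 5: turning -> 180 degrees (discrete polyline turns
  # 180*(n-2)/(n-1), so use a fine sampling)
  th <- seq(0, pi, length.out = 400)
  semi <- cbind(5 * cos(th), 5 * sin(th), 0)
  expect_equal(turning_angle(semi), 180, tolerance = 0.005)
  expect_gt(turning_angle(semi), 90)

  # brute-force angle-sum oracle on a random smooth polyline
  set.seed(43)
  poly <- apply(matrix(rnorm(60, 0, 0.3), ncol = 3), 2, cumsum)
  d <- diff(poly)
  brute <- 0
  for (r in 2:nrow(d)) {
    ct <- sum(d[r - 1, ] * d[r, ]) / sqrt(sum(d[r - 1, ]^2) * sum(d[r, ]^2))
    brute <- brute + acos(max(-1, min(1, ct))) * 180 / pi
  }
  expect_equal(turning_angle(poly), brute)

  tract <- fixture_streamlines(list(straight, semi))
  kept <- filter_u_shaped(tract, max_length_mm = 25, turning_threshold_deg = 90)
  expect_length(kept$streamlines, 1)
  expect_equal(kept$lengths, tract$lengths[2])
  # a long curved streamline fails the length threshold
  big <- cbind(50 * cos(th), 50 * sin(th), 0)
  tract2 <- fixture_streamlines(list(big))
  expect_length(filter_u_shaped(tract2, 25, 90)$streamlines, 0)
  expect_error(filter_u_shaped(tract, -1, 90), "positive")
})

test_that("vectorized connectivity equals the naive brute-force reference", {
  labs <- fixture_labels(10)
  for (s in 1:3) {
    cfg <- generator_config(seed = 100 + s, n_streamlines = 200,
                            retino_bias = 0.6, csf_contaminant_fraction = 0.15)
    tr <- simulate_streamlines(labs, cfg)
    fast <- build_connectivity(tr, labs)$counts
    brute <- brute_force_connectivity(tr, labs)
    expect_equal(unname(fast), brute)
  }
})
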