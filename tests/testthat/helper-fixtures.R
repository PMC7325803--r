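# Shared fixtures, all built in code.

# Small patch + ground-truth label volume used across connectivity tests.
fixture_labels <- function(n = 8L, seed = 1L) {
  patch <- make_retino_patch(n)
  make_label_volume(patch, ground_truth_segments(patch))
}

# Label volume with identity affine built by hand: a 6x6x6 grid with one
# voxel per segment along a diagonal-ish layout plus a CSF wall at z = 4..5.
fixture_identity_labels <- function() {
  grid <- array(0L, dim = c(8L, 8L, 8L))
  for (s in 1:6) grid[s, 1, 1] <- s          # V1 segments at y=0,z=0
  for (s in 1:6) grid[s, 3, 1] <- s + 6L     # V2 segments at y=2,z=0
  grid[, , 6] <- 13L                         # CSF slab at z = 5
  structure(list(grid = grid, affine = diag(4), voxel_size_mm = 1,
                 csf_label = 13L),
            class = "segment_label_volume")
}

# Streamline set assembled from explicit polylines.
fixture_streamlines <- function(polylines, csf = rep(FALSE, length(polylines))) {
  structure(list(streamlines = polylines,
                 lengths = vapply(polylines, function(p) sum(sqrt(rowSums(diff(p)^2))), 0),
                 true_cell = matrix(NA_integer_, length(polylines), 2),
                 csf_tag = csf, step_mm = NA_real_),
            class = "streamline_set")
}

# Straight polyline between two points with n points.
straight_line <- function(p, q, n = 10) {
  cbind(seq(p[1], q[1], length.out = n),
        seq(p[2], q[2], length.out = n),
        seq(p[3], q[3], length.out = n))
}

# Independent brute-force connectivity reference: loops over streamlines and
# points naively, computing voxel indices one point at a time.
brute_force_connectivity <- function(tractogram, labels) {
  inv <- solve(labels$affine)
  dims <- dim(labels$grid)
  label_at <- function(pt) {
    v <- inv %*% c(pt, 1)
    ijk <- floor(v[1:3] + 0.5)
    if (any(ijk < 0) || any(ijk >= dims)) return(0L)
    labels$grid[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1]
  }
  counts <- matrix(0L, 6, 6)
  for (poly in tractogram$streamlines) {
    hit_csf <- FALSE
    for (r in seq_len(nrow(poly))) {
      if (label_at(poly[r, ]) == labels$csf_label) { hit_csf <- TRUE; break }
    }
    if (hit_csf) next
    a <- label_at(poly[1, ])
    b <- label_at(poly[nrow(poly), ])
    if (a >= 1 && a <= 6 && b >= 7 && b <= 12) {
      counts[a, b - 6] <- counts[a, b - 6] + 1L
    } else if (b >= 1 && b <= 6 && a >= 7 && a <= 12) {
      counts[b, a - 6] <- counts[b, a - 6] + 1L
    }
  }
  counts
}

# Independent ICC(2,1) oracle via aov mean squares.
icc21_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
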