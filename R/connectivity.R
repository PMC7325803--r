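# Streamline filtering and 6x6 V1-V2 connectivity / proximity matrices.

#' Arc length of a streamline polyline
#'
#' @param polyline n x 3 matrix of mm points (n >= 2).
#' @return length in mm (sum of Euclidean segment lengths).
#' @export
streamline_length <- function(polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) stopf("a polyline needs at least two points")
  polyline_length(polyline)
}

#' Label of the voxel containing a point
#'
#' Applies the inverse affine and the containing-voxel convention: voxel
#' (i,j,k) spans `[i-0.5, i+0.5)` along each continuous voxel coordinate.
#' Points outside the volume get background code 0. This is also the
#' convention external tractograms must satisfy: no dilation or nearest-label
#' search is performed around endpoints.
#'
#' @param point_mm length-3 mm coordinate, or an n x 3 matrix of points.
#' @param labels a `segment_label_volume`.
#' @return integer label code(s).
#' @export
assign_endpoint <- function(point_mm, labels) {
  pts <- if (is.matrix(point_mm)) point_mm else matrix(point_mm, nrow = 1)
  idx <- world_to_voxel(pts, labels$affine)
  dims <- dim(labels$grid)
  ok <- idx[, 1] >= 0 & idx[, 1] < dims[1] &
        idx[, 2] >= 0 & idx[, 2] < dims[2] &
        idx[, 3] >= 0 & idx[, 3] < dims[3]
  out <- integer(nrow(pts))
  if (any(ok)) out[ok] <- labels$grid[idx[ok, , drop = FALSE] + 1L]
  out
}

#' Does a streamline traverse CSF?
#'
#' TRUE iff any polyline point (at its native sampling; no interpolation
#' between points) falls in a CSF-labelled voxel. A streamline whose endpoint
#' voxel is CSF counts as traversing CSF.
#'
#' @param polyline n x 3 matrix of mm points.
#' @param labels a `segment_label_volume`.
#' @return logical scalar.
#' @export
traverses_csf <- function(polyline, labels) {
  any(assign_endpoint(as.matrix(polyline), labels) == labels$csf_label)
}

# Internal: vectorized retention bookkeeping shared by build_connectivity()
# and proximity_matrix(). Returns per-streamline cell assignment (i, j) with
# NA where the streamline is discarded, plus discard reasons.
streamline_cells <- function(tractogram, labels) {
  sl <- tractogram$streamlines
  n <- length(sl)
  if (n == 0L)
    return(list(i = integer(0), j = integer(0), retained = logical(0),
                csf = logical(0), n = 0L))
  firsts <- t(vapply(sl, function(p) p[1, ], numeric(3)))
  lasts <- t(vapply(sl, function(p) p[nrow(p), ], numeric(3)))
  la <- assign_endpoint(firsts, labels)
  lb <- assign_endpoint(lasts, labels)

  npts <- vapply(sl, nrow, 0L)
  all_pts <- do.call(rbind, sl)
  pt_lab <- assign_endpoint(all_pts, labels)
  sid <- rep.int(seq_len(n), npts)
  csf_hits <- tabulate(sid[pt_lab == labels$csf_label], nbins = n) > 0L

  in_v1_a <- la >= 1L & la <= 6L
  in_v2_a <- la >= 7L & la <= 12L
  in_v1_b <- lb >= 1L & lb <= 6L
  in_v2_b <- lb >= 7L & lb <= 12L
  # endpoint order ignored: one end V1, the other V2
  spans <- (in_v1_a & in_v2_b) | (in_v2_a & in_v1_b)
  retained <- spans & !csf_hits
  i <- ifelse(in_v1_a, la, lb)
  j <- ifelse(in_v2_a, la - 6L, lb - 6L)
  i[!retained] <- NA_integer_
  j[!retained] <- NA_integer_
  list(i = i, j = j, retained = retained, csf = csf_hits & spans, n = n)
}

v1v2_dimnames <- function() list(paste0("V1_", 1:6), paste0("V2_", 1:6))

#' Build the 6x6 streamline-count connectivity matrix
#'
#' A streamline contributes to cell (i, j) iff one endpoint lies in V1
#' segment i and the other in V2 segment j (order ignored) and it does not
#' traverse CSF; streamlines terminating twice in the same area, in
#' background, or crossing CSF are discarded. Percent connectivity normalizes
#' counts to the total retained count in the hemisphere, so percentages sum
#' to 100.
#'
#' @param tractogram a `streamline_set`.
#' @param labels a `segment_label_volume` containing all 12 segments.
#' @param hemisphere_id,acquisition_id metadata strings carried on the result.
#' @return object of class `connectivity_matrix`: `counts`, `percent` (both
#'   6x6, rows V1 segments, cols V2 segments; `percent` all-NA and
#'   `percent_defined = FALSE` when nothing is retained), `total`,
#'   `n_csf_discarded`, `n_discarded`, metadata ids.
#' @export
build_connectivity <- function(tractogram, labels,
                               hemisphere_id = NA_character_,
                               acquisition_id = NA_character_) {
  if (!all(1:12 %in% labels$grid)) stopf("label volume must contain all 12 segments")
  cells <- streamline_cells(tractogram, labels)
  counts <- matrix(0L, 6, 6, dimnames = v1v2_dimnames())
  if (any(cells$retained)) {
    tb <- table(factor(cells$i[cells$retained], levels = 1:6),
                factor(cells$j[cells$retained], levels = 1:6))
    counts[] <- as.integer(tb)
  }
  total <- sum(counts)
  percent_defined <- total > 0L
  percent <- if (percent_defined) 100 * counts / total
             else matrix(NA_real_, 6, 6, dimnames = v1v2_dimnames())
  structure(list(counts = counts, percent = percent, total = total,
                 percent_defined = percent_defined,
                 n_csf_discarded = sum(cells$csf),
                 n_discarded = cells$n - total,
                 hemisphere_id = hemisphere_id, acquisition_id = acquisition_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix (%s / %s): %d retained, %d discarded (%d via CSF)\n",
              x$hemisphere_id, x$acquisition_id, x$total, x$n_discarded,
              x$n_csf_discarded))
  if (x$percent_defined) {
    p <- partition_connectivity(x)
    cat(sprintf("  retinotopic %.1f%% / non-retinotopic %.1f%%\n",
                p$retinotopic_pct, p$nonretinotopic_pct))
  }
  invisible(x)
}

#' Partition connectivity into retinotopic and non-retinotopic totals
#'
#' Diagonal cells (matching V1/V2 segment indices) are retinotopic,
#' off-diagonal cells non-retinotopic. Besides the percentage shares and
#' absolute totals, the per-cell mean strengths (mean over the 6 diagonal and
#' the 30 off-diagonal cells) are returned: these are the per-hemisphere
#' summary statistics the permutation test compares, and under a uniform cell
#' distribution they are equal.
#'
#' @param m a `connectivity_matrix`, or a plain 6x6 matrix of counts or
#'   percentages.
#' @return list with `retinotopic_pct`, `nonretinotopic_pct`,
#'   `retinotopic_counts`, `nonretinotopic_counts`, `retinotopic_mean`,
#'   `nonretinotopic_mean`.
#' @export
partition_connectivity <- function(m) {
  counts <- if (inherits(m, "connectivity_matrix")) m$counts else as.matrix(m)
  if (!all(dim(counts) == c(6, 6))) stopf("expected a 6x6 matrix")
  total <- sum(counts)
  if (total <= 0) stopf("cannot partition an empty connectivity matrix")
  d <- sum(diag(counts))
  o <- total - d
  pct <- if (inherits(m, "connectivity_matrix")) m$percent else 100 * counts / total
  list(retinotopic_pct = 100 * d / total,
       nonretinotopic_pct = 100 * o / total,
       retinotopic_counts = d,
       nonretinotopic_counts = o,
       retinotopic_mean = mean(diag(pct)),
       nonretinotopic_mean = mean(pct[row(pct) != col(pct)]))
}

#' Mean reciprocal streamline length (proximity) matrix
#'
#' Applies the same retention rules as [build_connectivity()]; cell (i, j) is
#' the arithmetic mean of 1/L over retained streamlines of that cell (mm^-1),
#' undefined where no streamline lands. Larger values mean shorter connecting
#' fibers, a first-order handle on the short-streamline bias of tractography.
#'
#' @inheritParams build_connectivity
#' @return object of class `proximity_matrix`: `mean_recip_len` (6x6, NA
#'   where undefined), `defined_mask`, `n_per_cell`.
#' @export
proximity_matrix <- function(tractogram, labels,
                             hemisphere_id = NA_character_,
                             acquisition_id = NA_character_) {
  if (!all(1:12 %in% labels$grid)) stopf("label volume must contain all 12 segments")
  cells <- streamline_cells(tractogram, labels)
  keep <- cells$retained
  len <- tractogram$lengths
  zero_len <- keep & len <= 0
  if (any(zero_len)) {
    message(sprintf("proximity_matrix: excluded %d zero-length streamline(s)", sum(zero_len)))
    keep <- keep & len > 0
  }
  mrl <- matrix(NA_real_, 6, 6, dimnames = v1v2_dimnames())
  npc <- matrix(0L, 6, 6, dimnames = v1v2_dimnames())
  if (any(keep)) {
    fi <- factor(cells$i[keep], levels = 1:6)
    fj <- factor(cells$j[keep], levels = 1:6)
    s <- tapply(1 / len[keep], list(fi, fj), mean)
    ncell <- table(fi, fj)
    mrl[] <- s
    npc[] <- as.integer(ncell)
  }
  structure(list(mean_recip_len = mrl, defined_mask = npc > 0L, n_per_cell = npc,
                 hemisphere_id = hemisphere_id, acquisition_id = acquisition_id),
            class = "proximity_matrix")
}

#' Element-wise group average of 6x6 matrices
#'
#' For connectivity percentages a plain element-wise mean; for proximity
#' matrices, undefined cells are excluded pairwise and the per-cell count of
#' defined inputs is reported.
#'
#' @param matrices nonempty list of 6x6 numeric matrices (NA = undefined), or
#'   of `connectivity_matrix` / `proximity_matrix` objects (their `percent` /
#'   `mean_recip_len` fields are averaged).
#' @return list with `mean` (6x6) and `n_defined` (6x6 count of non-NA
#'   inputs per cell).
#' @export
group_average <- function(matrices) {
  if (length(matrices) == 0L) stopf("cannot average an empty list of matrices")
  as_mat <- function(m) {
    if (inherits(m, "connectivity_matrix")) m$percent
    else if (inherits(m, "proximity_matrix")) m$mean_recip_len
    else as.matrix(m)
  }
  ms <- lapply(matrices, as_mat)
  d <- dim(ms[[1]])
  if (any(!vapply(ms, function(m) all(dim(m) == d), TRUE)))
    stopf("matrices must share a common shape")
  arr <- simplify2array(ms)
  n_def <- apply(!is.na(arr), c(1, 2), sum)
  avg <- apply(arr, c(1, 2), function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  dimnames(avg) <- dimnames(ms[[1]])
  list(mean = avg, n_defined = n_def)
}

#' Total turning angle of a polyline
#'
#' Sum of the angles between successive segment direction vectors, in
#' degrees. A straight line turns 0 degrees; a semicircle 180.
#'
#' @param polyline n x 3 matrix of points.
#' @return turning angle in degrees.
#' @export
turning_angle <- function(polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 3) return(0)
  d <- diff(polyline)
  nr <- sqrt(rowSums(d^2))
  ok <- nr > 0
  d <- d[ok, , drop = FALSE]
  nr <- nr[ok]
  if (nrow(d) < 2) return(0)
  dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE]) /
    (nr[-length(nr)] * nr[-1])
  sum(acos(pmin(1, pmax(-1, dots)))) * 180 / pi
}

#' Select short, strongly curved (U-shaped) streamlines
#'
#' Retains streamlines no longer than `max_length_mm` whose total turning
#' angle is at least `turning_threshold_deg`: the straight or gently bending
#' long-range fibers drop out, leaving the U-shaped short association fibers.
#' The defaults (25 mm, 90 degrees) target fibers at the U-fiber scale; both
#' are fully configurable.
#'
#' @param tractogram a `streamline_set`.
#' @param max_length_mm maximum retained length.
#' @param turning_threshold_deg minimum total turning angle.
#' @return the filtered `streamline_set`.
#' @export
filter_u_shaped <- function(tractogram, max_length_mm = 25, turning_threshold_deg = 90) {
  if (max_length_mm <= 0 || turning_threshold_deg <= 0)
    stopf("thresholds must be positive")
  turn <- vapply(tractogram$streamlines, turning_angle, 0)
  keep <- tractogram$lengths <= max_length_mm & turn >= turning_threshold_deg
  subset_streamlines(tractogram, keep)
}

subset_streamlines <- function(set, keep) {
  new_streamline_set(set$streamlines[keep], set$lengths[keep],
                     set$true_cell[keep, , drop = FALSE],
                     set$csf_tag[keep], set$step_mm)
}
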