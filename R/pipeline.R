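# End-to-end orchestration: synthetic study generation -> retinotopy ->
# connectivity -> group statistics, or the same over externally supplied
# tractograms/labels listed in a run manifest.

#' Pipeline configuration for a synthetic study
#'
#' Describes a simulated multi-hemisphere, multi-acquisition study with the
#' design of a proof-of-concept experiment: six hemispheres, two head-coil
#' acquisitions (scan-rescan) plus one flexible-surface-coil acquisition
#' each, 1000 streamlines per hemisphere and acquisition, and phase-encoded
#' runs of 8.25 cycles with periods of 36 s (eccentricity) / 60 s (polar
#' angle) at TR 3 s.
#'
#' @param seed master seed; every stochastic stage derives from it.
#' @param n_hemispheres hemispheres simulated (6 = 3 participants x 2).
#' @param acquisitions data.frame with columns `id` and `coil`
#'   ("headcoil"/"surface").
#' @param retino_bias diagonal mass of the streamline cell distribution
#'   (group mean).
#' @param retino_bias_sd between-hemisphere SD of the diagonal mass: each
#'   hemisphere's bias is drawn from a truncated normal around
#'   `retino_bias`, emulating biological variability so that reliability
#'   statistics (ICC) have hemisphere-level trait variance to detect. Set to
#'   0 for identically distributed hemispheres.
#' @param n_streamlines streamlines per hemisphere and acquisition.
#' @param csf_contaminant_fraction fraction routed through CSF.
#' @param noise_sd BOLD noise SD (the default gives an amplitude SNR of ~10
#'   for unit response amplitude over an 8-cycle run).
#' @param n_vertices_per_axis patch grid size.
#' @param tr_s,n_cycles fMRI timing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_hemispheres = 6L,
                            acquisitions = data.frame(
                              id = c("headcoil_1", "headcoil_2", "surface_1"),
                              coil = c("headcoil", "headcoil", "surface"),
                              stringsAsFactors = FALSE),
                            retino_bias = 0.727,
                            retino_bias_sd = 0.05,
                            n_streamlines = 1000L,
                            csf_contaminant_fraction = 0.05,
                            noise_sd = sqrt(48) / 10,
                            n_vertices_per_axis = 12L,
                            tr_s = 3, n_cycles = 8.25) {
  structure(list(seed = as.integer(seed), n_hemispheres = as.integer(n_hemispheres),
                 acquisitions = acquisitions, retino_bias = retino_bias,
                 retino_bias_sd = retino_bias_sd,
                 n_streamlines = as.integer(n_streamlines),
                 csf_contaminant_fraction = csf_contaminant_fraction,
                 noise_sd = noise_sd,
                 n_vertices_per_axis = as.integer(n_vertices_per_axis),
                 tr_s = tr_s, n_cycles = n_cycles),
            class = "pipeline_config")
}

#' Validate a run manifest of external inputs
#'
#' A manifest is a data.frame with columns `hemisphere_id`, `acquisition_id`,
#' `coil`, `tck` (tractogram path) and `labels` (NIfTI label volume path).
#' Hemisphere/acquisition pairs must be unique and every referenced path must
#' resolve.
#'
#' @param manifest data.frame as above.
#' @return the manifest, invisibly, or an error naming the offending entry.
#' @export
validate_manifest <- function(manifest) {
  need <- c("hemisphere_id", "acquisition_id", "coil", "tck", "labels")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stopf("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  key <- paste(manifest$hemisphere_id, manifest$acquisition_id)
  if (anyDuplicated(key)) stopf("duplicate hemisphere/acquisition entry: %s", key[duplicated(key)][1])
  for (r in seq_len(nrow(manifest))) {
    for (col in c("tck", "labels")) {
      if (!file.exists(manifest[[col]][r]))
        stopf("manifest entry %s/%s: missing file '%s'",
              manifest$hemisphere_id[r], manifest$acquisition_id[r], manifest[[col]][r])
    }
  }
  invisible(manifest)
}

simulate_hemisphere <- function(config, h) {
  base_seed <- config$seed + 1000L * h
  bias_sd <- if (is.null(config$retino_bias_sd)) 0 else config$retino_bias_sd
  bias_h <- if (bias_sd > 0)
    with_seed(base_seed + 7L, rtruncnorm1(config$retino_bias, bias_sd, 0, 1))
  else config$retino_bias
  cfg <- generator_config(seed = base_seed,
                          n_streamlines = config$n_streamlines,
                          retino_bias = bias_h,
                          csf_contaminant_fraction = config$csf_contaminant_fraction,
                          noise_sd = config$noise_sd)
  patch <- make_retino_patch(config$n_vertices_per_axis)
  runs_ecc <- simulate_phase_encoded_runs(patch, cfg, "eccentricity",
                                          tr_s = config$tr_s, n_cycles = config$n_cycles)
  runs_pol <- simulate_phase_encoded_runs(patch, cfg, "polar",
                                          tr_s = config$tr_s, n_cycles = config$n_cycles)
  ecc_map <- estimate_phase_map(runs_ecc$forward, runs_ecc$reversed)
  pol_map <- estimate_phase_map(runs_pol$forward, runs_pol$reversed)
  seg_rec <- segment_v1_v2(ecc_map, pol_map, patch$area_label)
  seg_true <- ground_truth_segments(patch)
  fsign <- field_sign(patch, ecc_map, pol_map)
  list(patch = patch, cfg = cfg,
       ecc_map = ecc_map, pol_map = pol_map,
       segments = seg_rec, segments_true = seg_true, field_sign = fsign,
       segment_accuracy = mean(seg_rec[seg_true > 0] == seg_true[seg_true > 0]),
       labels_true = make_label_volume(patch, seg_true),
       labels_recovered = make_label_volume(patch, seg_rec))
}

#' Run the full synthetic or manifest-driven pipeline
#'
#' Synthetic mode (default): per hemisphere, simulates phase-encoded runs,
#' recovers the retinotopic segmentation, rasterizes it, simulates
#' streamlines from the ground-truth label volume per acquisition, and maps
#' connectivity against the recovered labels; then computes group-average
#' matrices, the restricted permutation test per acquisition, ICC/CoV between
#' the head-coil mean and the surface-coil acquisition, and the 2x2
#' repeated-measures ANOVA on absolute counts. Manifest mode
#' (`manifest` supplied): reads tractograms and label volumes from disk and
#' runs the connectivity and statistics stages only.
#'
#' Everything is deterministic given `config$seed`; when `out_dir` is given,
#' all matrices, statistics, the configuration echo and a stage log are
#' written there.
#'
#' @param config a `pipeline_config`.
#' @param manifest optional run manifest (see [validate_manifest()]).
#' @param out_dir optional output directory.
#' @return results bundle (list), invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = pipeline_config(), manifest = NULL, out_dir = NULL) {
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (is.null(manifest)) {
    hemis <- lapply(seq_len(config$n_hemispheres), function(h) {
      hs <- simulate_hemisphere(config, h)
      say("hemisphere %d: segment accuracy %.3f", h, hs$segment_accuracy)
      hs
    })
    entries <- expand.grid(h = seq_len(config$n_hemispheres),
                           a = seq_len(nrow(config$acquisitions)))
    conn <- vector("list", nrow(entries))
    prox <- vector("list", nrow(entries))
    diag_lengths <- offdiag_lengths <- numeric(0)
    for (r in seq_len(nrow(entries))) {
      h <- entries$h[r]; a <- entries$a[r]
      hs <- hemis[[h]]
      cfg_a <- hs$cfg
      cfg_a$seed <- cfg_a$seed + 10L * a
      tract <- simulate_streamlines(hs$labels_true, cfg_a)
      hid <- sprintf("hemi_%d", h); aid <- config$acquisitions$id[a]
      conn[[r]] <- build_connectivity(tract, hs$labels_recovered, hid, aid)
      prox[[r]] <- proximity_matrix(tract, hs$labels_recovered, hid, aid)
      cells <- streamline_cells(tract, hs$labels_recovered)
      keep <- cells$retained
      dg <- keep & cells$i == cells$j
      diag_lengths <- c(diag_lengths, tract$lengths[which(dg)])
      offdiag_lengths <- c(offdiag_lengths, tract$lengths[which(keep & !dg)])
      say("%s/%s: %d retained, %d discarded (%d CSF)", hid, aid,
          conn[[r]]$total, conn[[r]]$n_discarded, conn[[r]]$n_csf_discarded)
    }
    meta <- data.frame(hemisphere_id = sprintf("hemi_%d", entries$h),
                       acquisition_id = config$acquisitions$id[entries$a],
                       coil = config$acquisitions$coil[entries$a],
                       stringsAsFactors = FALSE)
    seg_acc <- vapply(hemis, `[[`, 0, "segment_accuracy")
    fs_summary <- vapply(hemis, function(hs) {
      v1 <- hs$field_sign[hs$patch$area_label == "V1"]
      v2 <- hs$field_sign[hs$patch$area_label == "V2"]
      mean(sign(mean(v1)) != sign(mean(v2)) & mean(v1) != 0)
    }, 0)
    length_stats <- list(
      retinotopic = c(mean = mean(diag_lengths), sd = stats::sd(diag_lengths)),
      nonretinotopic = c(mean = mean(offdiag_lengths), sd = stats::sd(offdiag_lengths)))
  } else {
    validate_manifest(manifest)
    conn <- vector("list", nrow(manifest))
    prox <- vector("list", nrow(manifest))
    for (r in seq_len(nrow(manifest))) {
      tract <- read_tck(manifest$tck[r])
      labels <- read_label_volume(manifest$labels[r])
      conn[[r]] <- build_connectivity(tract, labels,
                                      manifest$hemisphere_id[r], manifest$acquisition_id[r])
      prox[[r]] <- proximity_matrix(tract, labels,
                                    manifest$hemisphere_id[r], manifest$acquisition_id[r])
      say("%s/%s: %d retained", manifest$hemisphere_id[r],
          manifest$acquisition_id[r], conn[[r]]$total)
    }
    meta <- manifest[, c("hemisphere_id", "acquisition_id", "coil")]
    seg_acc <- NULL; fs_summary <- NULL; length_stats <- NULL
  }

  acq_ids <- unique(meta$acquisition_id)
  perm_tests <- list()
  group_percent <- list()
  for (aid in acq_ids) {
    sel <- which(meta$acquisition_id == aid)
    parts <- lapply(conn[sel], partition_connectivity)
    perm_tests[[aid]] <- restricted_permutation_test(
      vapply(parts, `[[`, 0, "retinotopic_mean"),
      vapply(parts, `[[`, 0, "nonretinotopic_mean"))
    group_percent[[aid]] <- group_average(conn[sel])$mean
    say("acquisition %s: t = %.3f, p = %.4f", aid,
        perm_tests[[aid]]$t_obs, perm_tests[[aid]]$p)
  }
  group_overall <- group_average(conn)$mean
  partition_overall <- partition_connectivity(
    matrix(group_overall * 1, 6, 6))  # percent matrix; partition on shares
  group_proximity <- group_average(prox)

  # reliability and ANOVA across coils, when both coil types are present
  icc <- cov_res <- anova_res <- NULL
  coils <- split(acq_ids, vapply(acq_ids, function(a) meta$coil[match(a, meta$acquisition_id)], ""))
  if (all(c("headcoil", "surface") %in% names(coils))) {
    hemi_ids <- unique(meta$hemisphere_id)
    stack_of <- function(aids) {
      per_hemi <- lapply(hemi_ids, function(hid) {
        sel <- which(meta$hemisphere_id == hid & meta$acquisition_id %in% aids)
        group_average(conn[sel])$mean
      })
      simplify2array(per_hemi)
    }
    head_stack <- stack_of(coils$headcoil)
    surf_stack <- stack_of(coils$surface)
    icc <- icc_matrix(head_stack, surf_stack)
    cov_res <- cov_matrix(head_stack, surf_stack)

    counts_of <- function(aid) {
      t(vapply(hemi_ids, function(hid) {
        sel <- which(meta$hemisphere_id == hid & meta$acquisition_id == aid)
        p <- partition_connectivity(conn[[sel[1]]])
        c(p$retinotopic_counts, p$nonretinotopic_counts)
      }, numeric(2)))
    }
    arr <- array(NA_real_, c(length(hemi_ids), 2, 2),
                 dimnames = list(hemi_ids, c("retinotopic", "nonretinotopic"),
                                 c("headcoil", "surface")))
    arr[, , 1] <- counts_of(coils$headcoil[1])
    arr[, , 2] <- counts_of(coils$surface[1])
    anova_res <- rm_anova_2x2(arr)
    say("ANOVA: F_type = %.3g (p = %.3g), F_coil = %.3g, F_interaction = %.3g",
        anova_res$F["type"], anova_res$p["type"], anova_res$F["coil"],
        anova_res$F["interaction"])
  }

  bundle <- list(config = config,
                 meta = meta,
                 connectivity = conn, proximity = prox,
                 group_percent = group_percent,
                 group_overall = group_overall,
                 partition_overall = partition_overall,
                 group_proximity = group_proximity,
                 perm_tests = perm_tests,
                 icc = icc, cov = cov_res, anova = anova_res,
                 segment_accuracy = seg_acc,
                 field_sign_opposite = fs_summary,
                 length_stats = length_stats,
                 log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_along(conn))
      write_connectivity_csv(conn[[r]], file.path(out_dir, sprintf(
        "connectivity_%s_%s", conn[[r]]$hemisphere_id, conn[[r]]$acquisition_id)))
    utils::write.csv(group_overall, file.path(out_dir, "group_percent.csv"))
    stats_out <- list(
      partition = partition_overall,
      perm_tests = lapply(perm_tests, function(pt) pt[c("t_obs", "p", "H")]),
      icc = if (!is.null(icc)) list(matrix = icc$icc, summary = icc$summary),
      cov = if (!is.null(cov_res)) list(matrix = cov_res$cov, summary = cov_res$summary),
      anova = if (!is.null(anova_res)) anova_res[c("F", "p")],
      length_stats = length_stats, segment_accuracy = seg_acc)
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    return(invisible(bundle))
  }
  bundle
}
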