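#!/usr/bin/env Rscript
# Simulate one hemisphere's complete input set -- retinotopic patch,
# phase-encoded BOLD run pairs, segment label volume, U-fiber tractogram and
# b = 0 series -- and write everything in standard formats under
# results/data/. Downstream scripts (02, 03, 05) consume these files.

library(retinoconn)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed, n_streamlines = 1000,
                        csf_contaminant_fraction = 0.05,
                        noise_sd = sqrt(48) / 10)   # amplitude SNR ~10
patch <- make_retino_patch(12)
message(sprintf("patch: %d vertices, %d V1 / %d V2",
                nrow(patch$vertex_coords),
                sum(patch$area_label == "V1"), sum(patch$area_label == "V2")))

# phase-encoded runs: expanding ring (36 s cycle) and rotating ray (60 s
# cycle), 8.25 cycles at TR 3 s, forward + reversed directions
for (dimension in c("eccentricity", "polar")) {
  runs <- simulate_phase_encoded_runs(patch, cfg, dimension, tr_s = 3)
  write_bold_run(runs$forward, file.path(out, paste0(dimension, "_fwd")))
  write_bold_run(runs$reversed, file.path(out, paste0(dimension, "_rev")))
  message(sprintf("%s runs: %d vertices x %d samples", dimension,
                  nrow(runs$forward$series), ncol(runs$forward$series)))
}

# ground-truth labels -> NIfTI; tractogram -> TCK
seg_true <- ground_truth_segments(patch)
labels <- make_label_volume(patch, seg_true)
write_label_volume(labels, file.path(out, "labels_true.nii.gz"))
tract <- simulate_streamlines(labels, cfg)
write_tck(tract, file.path(out, "tractogram.tck"))
message(sprintf("tractogram: %d streamlines, %d CSF contaminants, lengths %.1f-%.1f mm",
                length(tract$streamlines), sum(tract$csf_tag),
                min(tract$lengths), max(tract$lengths)))

# patch geometry + ground truth for the retinotopy script
write.table(data.frame(x = patch$vertex_coords[, 1], y = patch$vertex_coords[, 2],
                       z = patch$vertex_coords[, 3], area = patch$area_label,
                       segment_true = seg_true),
            file.path(out, "patch_vertices.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

message("inputs written to ", out)
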