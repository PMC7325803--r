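#!/usr/bin/env Rscript
# Filter the tractogram with the recovered V1/V2 segment labels into the 6x6
# connectivity (percent streamline count) and proximity (mean reciprocal
# length) matrices, and split connectivity into retinotopic (diagonal) vs
# non-retinotopic (off-diagonal) shares.

library(retinoconn)

out <- "results/connectivity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tract <- read_tck("results/data/tractogram.tck")
labels <- read_label_volume("results/retinotopy/labels_recovered.nii.gz")

conn <- build_connectivity(tract, labels, hemisphere_id = "hemi_1",
                           acquisition_id = "headcoil_1")
prox <- proximity_matrix(tract, labels, hemisphere_id = "hemi_1",
                         acquisition_id = "headcoil_1")
print(conn)

part <- partition_connectivity(conn)
message(sprintf("retinotopic %.1f%% vs non-retinotopic %.1f%% of total V1-V2 connectivity",
                part$retinotopic_pct, part$nonretinotopic_pct))
message(sprintf("mean proximity: diagonal %.4f mm^-1, off-diagonal %.4f mm^-1",
                mean(diag(prox$mean_recip_len), na.rm = TRUE),
                mean(prox$mean_recip_len[row(prox$mean_recip_len) !=
                                         col(prox$mean_recip_len)], na.rm = TRUE)))

write_connectivity_csv(conn, file.path(out, "hemi_1_headcoil_1"))
write.csv(prox$mean_recip_len, file.path(out, "hemi_1_headcoil_1_proximity.csv"))

# U-shape selection as a configurable track filter
kept <- filter_u_shaped(tract, max_length_mm = 25, turning_threshold_deg = 90)
message(sprintf("U-shape filter (<= 25 mm, >= 90 deg turning): %d of %d streamlines kept",
                length(kept$streamlines), length(tract$streamlines)))
message("matrices written to ", out)
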