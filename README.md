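# retinoconn

Quantification of short association (U-) fiber connectivity between
retinotopically defined V1 and V2, for researchers combining phase-encoded
fMRI retinotopy with diffusion-MRI tractography.

U-fibers connect adjacent cortical areas directly beneath the gray–white
boundary. Between V1 and V2 their organization is predicted by retinotopy:
cortical patches representing the same visual-field location should be
preferentially connected. `retinoconn` turns that prediction into a testable
pipeline:

1. **Retinotopy** — recover eccentricity and polar-angle phase maps from
   phase-encoded BOLD runs (Fourier phase at the stimulus frequency,
   opposite-direction runs combined by conjugate averaging to cancel the
   hemodynamic delay), compute visual field sign maps, and split each area
   into six retinotopic segments (2 polar × 3 eccentricity bins).
2. **Connectivity** — filter a tractogram (TCK) with the segment label
   volume (NIfTI): a streamline counts toward cell *(i, j)* of a 6×6 matrix
   iff it terminates in V1 segment *i* and V2 segment *j* and avoids CSF.
   Report percent connectivity, the proximity matrix (mean reciprocal
   streamline length per cell), and the retinotopic (diagonal) vs
   non-retinotopic (off-diagonal) split.
3. **Inference** — one-tailed paired *t* on per-hemisphere mean strengths
   with an exhaustive restricted sign-flip null (all 2^H within-hemisphere
   swaps; 64 assignments for six hemispheres, identity included, and
   p = #(t\* ≥ t)/2^H), ICC(2,1) and CoV reliability matrices across
   acquisitions, a 2×2 repeated-measures ANOVA (connection type × coil) on
   absolute counts, and paired *t*-tests on motion-parameter SDs.
4. **QC** — voxel-wise temporal SNR (mean/SD over time) with ROI
   aggregation, and the analytic echo-time model
   gain = exp(ΔTE/T2) − 1, extra time = (1 + gain)² − 1.

A synthetic-data generator (`generator_config()`, `make_retino_patch()`,
`simulate_phase_encoded_runs()`, `make_label_volume()`,
`simulate_streamlines()`, `simulate_b0_series()`) produces every input with
known ground truth — retinotopic patches, BOLD run pairs, label volumes,
U-shaped streamline sets with configured length distributions (16 ± 4 mm
retinotopic, 32 ± 13 mm non-retinotopic, clipped to the 3–100 mm tracking
range), and b = 0 series with surface-coil tSNR profiles — so the whole
chain runs and is tested without any scanner data.

## Worked example

The numbered scripts under `analysis/` run the study end to end on synthetic
data (`01` simulate inputs → `02` retinotopy → `03` connectivity →
`04` group statistics → `05` QC), writing tables under `results/`. The group
study (`analysis/04_group_stats.R`: six hemispheres, two head-coil
acquisitions plus one surface-coil acquisition each, 1000 streamlines per
hemisphere and acquisition) prints:

```
group-average split: retinotopic 70.7% / non-retinotopic 29.3%
headcoil_1: t = 43.39, permutation p = 0.0156 (64 assignments)
headcoil_2: t = 36.82, permutation p = 0.0156 (64 assignments)
surface_1: t = 41.51, permutation p = 0.0156 (64 assignments)
streamline lengths: retinotopic 16.3 +/- 4.0 mm, non-retinotopic 31.3 +/- 12.6 mm
reliability: ICC 0.37 +/- 0.41, CoV 0.20 +/- 0.09
```

Reading: although only 6 of 36 segment pairings are retinotopic, they carry
~71% of all retained V1–V2 streamlines; the permutation p of 0.0156 is the
smallest value achievable from 64 assignments, i.e. the observed pairing
beats every alternative swap; retinotopic fibers are about half as long as
non-retinotopic ones, consistent with their higher proximity. The per-cell
ICC/CoV quantify scan–rescan and across-coil agreement of the matrices (on
synthetic data the ICC reflects the configured hemisphere-to-hemisphere
variability, not an in-vivo prediction). A single-hemisphere pass
(`analysis/03_connectivity.R`) prints the same quantities for one
tractogram, e.g. `retinotopic 72.5% vs non-retinotopic 27.5%` with
`953 retained, 47 discarded (47 via CSF)`.

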