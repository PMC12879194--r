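#!/usr/bin/env Rscript
# Step 1 — generate every synthetic input the downstream analyses consume:
# a rotated/warped section with known template-frame ground truth, a
# litter-level EdU co-labeling count table from three Gaussian birth
# waves, quarter-day cell-type composition series, and dorsoventral
# signal profiles with a genotype shift. All tables land in results/.

suppressPackageStartupMessages(library(chronotopy))
dir.create("results", showWarnings = FALSE)
seed <- 20260101L

# --- section with 10 anchors, 30 degrees off-axis, mild warp ---
sec_cfg <- section_sim_config(
  n_cells = 2000L, rotation_deg = 30, jitter_sd = 0, seed = seed,
  warp_y_scale = c(1.3, 1.1, 1, 0.9, 1.2, 1.4),
  warp_x_scale_dh = 0.7, warp_x_scale_vh = 1.3, offset = c(500, -300))
sec <- make_section(sec_cfg)
write.csv(sec$raw, "results/section_raw_cells.csv", row.names = FALSE)
write.csv(sec$anchors, "results/section_anchors.csv", row.names = FALSE)
write.csv(sec$template_truth, "results/section_template_truth.csv",
          row.names = FALSE)
cat("section: ", nrow(sec$raw), "cells,", nrow(sec$anchors), "anchors\n")

# --- EdU birthdating design: 7 half-day pulses E10.5-E13.5 ---
birth_cfg <- birth_sim_config(
  families = data.frame(family = c("F1", "F2", "F3"),
                        mu_birth = c(11.5, 12.0, 12.5), sigma_birth = 0.4),
  timepoints = seq(10.5, 13.5, by = 0.5),
  n_litters = 4L, n_embryos_per_litter = 3L, n_cells_per_embryo = 100L,
  seed = seed)
counts <- make_birth_counts(birth_cfg)
write.csv(counts, "results/birth_counts.csv", row.names = FALSE)
cat("birth counts:", nrow(counts), "rows;",
    "waves at E11.5 / E12.0 / E12.5\n")

# --- composition over quarter-day timepoints ---
comp_cfg <- composition_sim_config(
  types = data.frame(type = paste0("T", 1:4),
                     mu_peak = c(11.0, 11.5, 12.0, 12.5),
                     sigma = 0.5, weight = 1),
  timepoints = seq(10.5, 13.5, by = 0.25),
  n_cells_per_timepoint = 2000L, seed = seed)
series <- make_composition_series(comp_cfg)
long <- do.call(rbind, lapply(series, function(s)
  data.frame(label = s$label, x = s$x, value = s$v)))
write.csv(long, "results/composition_series.csv", row.names = FALSE)
cat("composition:", length(series), "types x", length(series[[1]]$x),
    "timepoints\n")

# --- depth profiles: mutant peak shifted ventrally by 40 raw bins ---
prof_cfg <- profile_sim_config(
  n_bins_raw = 160L,
  peaks = data.frame(genotype = c("ctl", "mut"), marker = "markerA",
                     center_bin = c(40, 80), width = 12, amplitude = 5),
  noise_sd = 0.05, n_replicates = 3L, seed = seed)
profiles <- make_depth_profiles(prof_cfg)
write.csv(profiles, "results/depth_profiles_raw.csv", row.names = FALSE)
cat("profiles:", length(unique(profiles$genotype)), "genotypes x",
    max(profiles$replicate), "replicates x", max(profiles$bin), "bins\n")
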