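#!/usr/bin/env Rscript
# Step 5 — spatial quantification on the normalized coordinates and the
# simulated depth profiles: 2D KDE with highest-density contour levels,
# the 200-bin dorsoventral histogram, 80-bin compressed profiles with
# the 56-bin dorsal view, and the quintile ANOVA genotype comparison.

suppressPackageStartupMessages(library(chronotopy))

cells <- read.csv("results/section_normalized.csv")

# KDE + HDR contour levels per family (densest 50/25/15/5/2.5% of points)
hdr_rows <- do.call(rbind, lapply(split(cells, cells$family_label),
  function(d) {
    dens <- kde2d_at_points(d$x, d$y)
    hs <- hdr_levels(dens)
    data.frame(family = d$family_label[1], alpha = hs$alpha,
               threshold = hs$threshold, n_members = hs$n_members,
               pct_inside = 100 * hs$n_members / nrow(d))
  }))
write.csv(hdr_rows, "results/hdr_levels_by_family.csv", row.names = FALSE)
cat("HDR membership at alpha = 0.5, per family (%):\n")
print(round(hdr_rows$pct_inside[hdr_rows$alpha == 0.5], 1))

grid <- kde2d_grid(cells$x, cells$y, resolution = 100)
cat(sprintf("density grid %dx%d, Riemann mass %.4f\n", nrow(grid$z),
            ncol(grid$z), sum(grid$z) * diff(grid$x[1:2]) * diff(grid$y[1:2])))

# 200-bin depth histogram of all cells
dp <- depth_histogram(cells$y, smooth = TRUE)
write.csv(data.frame(bin = seq_len(dp$n_bins), count = dp$counts,
                     smoothed = dp$smoothed),
          "results/depth_histogram_200.csv", row.names = FALSE)
cat(sprintf("depth histogram: %d bins, %d cells, modal bin %d\n",
            dp$n_bins, sum(dp$counts), which.max(dp$counts)))

# compress simulated genotype profiles and run the quintile ANOVA
profiles <- read.csv("results/depth_profiles_raw.csv")
comp <- do.call(rbind, lapply(
  split(profiles, list(profiles$genotype, profiles$replicate)),
  function(d) {
    cp <- compress_profile(d$value[order(d$bin)])
    data.frame(genotype = d$genotype[1], cell_type = d$marker[1],
               replicate = d$replicate[1], bin = seq_along(cp$weights),
               weight = cp$weights)
  }))
write.csv(comp, "results/depth_profiles_compressed80.csv", row.names = FALSE)

qs <- quintile_stats(comp)
write.csv(qs$anova, "results/quintile_anova.csv", row.names = FALSE)
write.csv(qs$posthoc, "results/quintile_posthoc.csv", row.names = FALSE)
cat("quintile ANOVA:\n"); print(qs$anova, digits = 3)
sigq <- qs$posthoc[qs$posthoc$p_adj < 0.05, "quintile"]
cat("quintiles with significant genotype differences:",
    paste(sort(unique(sigq)), collapse = ", "), "\n")
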