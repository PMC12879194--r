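#!/usr/bin/env Rscript
# Step 2 — normalize the simulated section onto the idealized template
# and verify the registration against the known ground truth; then build
# a mirrored, ratio-downsampled genotype overlay from the normalized
# cells.

suppressPackageStartupMessages(library(chronotopy))

raw <- read.csv("results/section_raw_cells.csv")
anc <- read.csv("results/section_anchors.csv")
truth <- read.csv("results/section_template_truth.csv")

cells <- cell_table(raw$section_id, raw$x, raw$y,
                    family_label = raw$family_label, frame = "raw")
anchors <- section_landmarks(anc$section_id[1], anc$role, anc$x, anc$y)

norm <- normalize_section(cells, anchors)
err <- max(abs(norm$cells$x - truth$x), abs(norm$cells$y - truth$y))
ta <- norm$anchors
cat(sprintf("round-trip max error: %.2e template units\n", err))
cat(sprintf("dorsal anchor y: %+.1f   lateral-left anchor x: %+.1f\n",
            ta$y[ta$role == "DH_dorsal_R"], ta$x[ta$role == "DH_lateral_L"]))
write.csv(norm$cells, "results/section_normalized.csv", row.names = FALSE)

# mirrored overlay of two family groups standing in for genotypes; the
# larger group is the reference and is downsampled to the other's total
g1 <- norm$cells[norm$cells$family_label %in% c("F1", "F2", "F3"), ]
g2 <- norm$cells[norm$cells$family_label %in% c("F4", "F5", "F6"), ]
if (nrow(g1) >= nrow(g2)) { ref <- g1; alt <- g2 } else { ref <- g2; alt <- g1 }
ref <- chronotopy:::set_frame(ref, "template")
alt <- chronotopy:::set_frame(alt, "template")
ref_ds <- downsample_matched(ref, alt_total = nrow(alt), seed = 2,
                             type_col = "family_label")
ov <- mirror_overlay(ref_ds, alt, "ref", "alt")
cat(sprintf("overlay: %d ref (downsampled from %d) + %d alt cells\n",
            nrow(ref_ds), nrow(ref), nrow(alt)))
write.csv(ov, "results/overlay_mirrored.csv", row.names = FALSE)
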