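#!/usr/bin/env Rscript
# Gating descriptors and state classification on one well-sampled
# replicate: the kink hydrogen bonds, bending angle, and the 2-D histogram
# separating the kinked and bent states, written as tidy CSV.

suppressPackageStartupMessages(library(kinkgate))
dir.create("results", showWarnings = FALSE)

spec <- preset_conduction_group("high_current", n_frames = 3000L)
gen <- generate_trajectory(spec, seed = 1L)
fr <- gen$frames; top <- gen$topology

d_vg <- hbond_distance(fr, top)
ang <- bending_angle(fr, top)
states <- classify_state(d_vg)

tidy <- do.call(rbind, lapply(colnames(d_vg), function(s) data.frame(
  frame = seq_len(nrow(d_vg)), time_ns = fr$times, subunit = s,
  d_vg_nm = d_vg[, s], angle_deg = ang[, s], state = states$labels[, s])))
write.csv(tidy, "results/02_descriptors.csv", row.names = FALSE)

h <- histogram2d(as.vector(ang), as.vector(d_vg),
                 seq(20.5, 50.5, 1), seq(0.125, 0.725, 0.02),
                 normalize = TRUE)
grid <- expand.grid(angle_deg = h$x_mid, d_vg_nm = h$y_mid)
grid$p <- as.vector(h$z)
write.csv(grid, "results/02_histogram2d.csv", row.names = FALSE)

cat(sprintf("bent-state fraction %.3f; per-state angle means %.1f / %.1f deg\n",
            states$f_bent,
            mean(ang[states$labels == "kinked"]),
            mean(ang[states$labels == "bent"])))
cat(sprintf("label accuracy vs planted states: %.4f\n",
            mean(states$labels == gen$truth$states)))
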