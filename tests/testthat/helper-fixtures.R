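# Shared fixtures, all generated in code.

# A landmark set at the template's own anchor positions, with DC_base and
# DV_junction overridable for rotation tests.
toy_landmarks <- function(frame = "raw", spec = template_spec()) {
  ta <- chronotopy:::template_anchor_positions(spec)
  section_landmarks("toy", ta$role, ta$x, ta$y, frame = frame)
}

# Standard simulated-section configuration used across registration tests.
toy_section_cfg <- function(seed = 42L, rotation_deg = 30, jitter_sd = 0, ...) {
  section_sim_config(n_cells = 150, rotation_deg = rotation_deg,
                     jitter_sd = jitter_sd, seed = seed,
                     warp_y_scale = c(1.3, 1.1, 1, 0.9, 1.2, 1.4),
                     warp_x_scale_dh = 0.7, warp_x_scale_vh = 1.3,
                     offset = c(500, -300), ...)
}

# Emulated EdU study design: 7 half-day pulses E10.5-E13.5, 4 litters of 3
# embryos, 100 marker cells per embryo.
edu_design_birth_cfg <- function(seed = 1L,
                                  mu = c(11.5, 12.0, 12.5), sigma = 0.4) {
  birth_sim_config(
    families = data.frame(family = paste0("F", seq_along(mu)),
                          mu_birth = mu, sigma_birth = sigma),
    timepoints = seq(10.5, 13.5, by = 0.5),
    n_litters = 4L, n_embryos_per_litter = 3L, n_cells_per_embryo = 100L,
    seed = seed)
}
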