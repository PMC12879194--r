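#' Configuration for a simulated section
#'
#' Describes one bilaterally symmetric section: cells are placed in the
#' idealized template frame from a per-family laminar layout, then carried
#' into a "raw" frame by an invertible piecewise-linear inverse warp, a
#' rigid rotation and translation, and optional coordinate jitter. The
#' anchors are transported by the same transform (without jitter), so the
#' registration round trip is exact when `jitter_sd = 0`.
#'
#' @param n_cells Number of cells (> 0).
#' @param rotation_deg Rigid rotation applied when producing raw
#'   coordinates, degrees.
#' @param jitter_sd SD of Gaussian coordinate noise added to raw cell
#'   coordinates (raw units, >= 0). Anchors are never jittered.
#' @param family_layout data.frame with columns
#'   `family, prop, mean_y, sd_y, mean_abs_x, sd_x`: template-frame
#'   laminar placement per family. Proportions must sum to 1 and SDs be
#'   positive.
#' @param seed Integer RNG seed.
#' @param warp_y_scale Scalar (or length-6, one per y control level,
#'   ventral to dorsal) multiplier taking template control y positions to
#'   their raw-frame positions; 1 = identity warp.
#' @param warp_x_scale_dh,warp_x_scale_vh Multipliers taking the template
#'   lateral dorsal-horn / ventral-horn anchor |x| to raw-frame |x|.
#' @param offset Length-2 raw-frame translation.
#' @param spec A [template_spec()].
#' @return A `section_sim_config` list.
#' @export
section_sim_config <- function(n_cells, rotation_deg = 0, jitter_sd = 0,
                               family_layout = default_family_layout(),
                               seed = 1L, warp_y_scale = 1,
                               warp_x_scale_dh = 1, warp_x_scale_vh = 1,
                               offset = c(0, 0), spec = template_spec()) {
  stopifnot(n_cells > 0, jitter_sd >= 0, length(offset) == 2)
  req <- c("family", "prop", "mean_y", "sd_y", "mean_abs_x", "sd_x")
  if (!all(req %in% names(family_layout)))
    stop("family_layout needs columns: ", paste(req, collapse = ", "))
  if (any(family_layout$sd_y <= 0) || any(family_layout$sd_x <= 0))
    stop("invalid layout: sd_y and sd_x must be positive")
  if (abs(sum(family_layout$prop) - 1) > 1e-8)
    stop("family proportions must sum to 1")
  if (!length(warp_y_scale) %in% c(1L, 6L))
    stop("warp_y_scale must have length 1 or 6")
  if (any(warp_y_scale <= 0) || warp_x_scale_dh <= 0 || warp_x_scale_vh <= 0)
    stop("warp scales must be positive")
  structure(list(n_cells = as.integer(n_cells), rotation_deg = rotation_deg,
                 jitter_sd = jitter_sd, family_layout = family_layout,
                 seed = as.integer(seed), warp_y_scale = warp_y_scale,
                 warp_x_scale_dh = warp_x_scale_dh,
                 warp_x_scale_vh = warp_x_scale_vh,
                 offset = as.numeric(offset), spec = spec),
            class = "section_sim_config")
}

#' Default laminar layout of six dorsal interneuron families
#'
#' Template-frame placement emulating temporal cohorts settling at
#' successively deeper dorsoventral positions.
#'
#' @return data.frame usable as `family_layout`.
#' @export
default_family_layout <- function() {
  data.frame(
    family = paste0("F", 1:6),
    prop = rep(1 / 6, 6),
    mean_y = seq(1700, 200, length.out = 6),
    sd_y = 150,
    mean_abs_x = seq(900, 600, length.out = 6),
    sd_x = 250,
    stringsAsFactors = FALSE)
}

# Template-frame anchor positions implied by a template spec. Anchors with
# no pinned template x get conventional symmetric positions.
template_anchor_positions <- function(spec) {
  data.frame(
    role = anchor_roles(),
    x = c(-1000, 1000, spec$X_L, spec$X_R, 0, -spec$X_VLAT, spec$X_VLAT,
          -800, 800, 0),
    y = c(spec$Y_D, spec$Y_D, spec$Y_LAT, spec$Y_LAT, spec$Y_DC,
          spec$Y_VLAT, spec$Y_VLAT, spec$Y_V, spec$Y_V, 0),
    stringsAsFactors = FALSE)
}

# Inverse of the template warp: template (x, y) -> "rotated"-frame (x, y)
# under section-specific warp scales.
inverse_warp <- function(x_t, y_t, cfg) {
  spec <- cfg$spec
  dst <- c(spec$Y_V, spec$Y_VLAT, 0, spec$Y_LAT, spec$Y_DC, spec$Y_D)
  src <- dst * cfg$warp_y_scale
  if (any(diff(src) <= 0)) stop("warp_y_scale breaks control monotonicity")
  y_r <- pw_linear(y_t, dst, src)
  # raw lateral anchor levels implied by the y scales
  y_dh <- src[4]
  y_vh <- src[2]
  s_dh <- 1 / cfg$warp_x_scale_dh  # forward x scale at dorsal-horn lateral level
  s_vh <- 1 / cfg$warp_x_scale_vh
  w <- (y_r - y_vh) / (y_dh - y_vh)
  w <- pmin(pmax(w, 0), 1)
  s <- s_vh + w * (s_dh - s_vh)
  list(x = x_t / s, y = y_r)
}

rigid_forward <- function(x, y, rotation_deg, offset) {
  th <- rotation_deg * pi / 180
  list(x = cos(th) * x - sin(th) * y + offset[1],
       y = sin(th) * x + cos(th) * y + offset[2])
}

#' Simulate one annotated section
#'
#' Generates template-frame ground-truth cell coordinates from the family
#' layout, transports cells and the 10 anchors into a raw frame by the
#' inverse template warp plus a rigid motion, and adds jitter to the raw
#' cell coordinates.
#'
#' @param cfg A [section_sim_config()].
#' @param section_id Section identifier.
#' @return List with `raw` (raw-frame `cell_table`), `anchors` (raw-frame
#'   `section_landmarks`) and `template_truth` (template-frame
#'   `cell_table`).
#' @export
make_section <- function(cfg, section_id = "S1") {
  stopifnot(inherits(cfg, "section_sim_config"))
  set.seed(cfg$seed)
  lay <- cfg$family_layout
  fam_idx <- sample.int(nrow(lay), cfg$n_cells, replace = TRUE, prob = lay$prop)
  y_t <- stats::rnorm(cfg$n_cells, lay$mean_y[fam_idx], lay$sd_y[fam_idx])
  ax <- abs(stats::rnorm(cfg$n_cells, lay$mean_abs_x[fam_idx], lay$sd_x[fam_idx]))
  side <- sample(c(-1, 1), cfg$n_cells, replace = TRUE)
  x_t <- side * ax
  truth <- cell_table(section_id, x_t, y_t, family_label = lay$family[fam_idx],
                      frame = "template")

  inv_c <- inverse_warp(x_t, y_t, cfg)
  raw_c <- rigid_forward(inv_c$x, inv_c$y, cfg$rotation_deg, cfg$offset)
  jx <- stats::rnorm(cfg$n_cells, 0, cfg$jitter_sd)
  jy <- stats::rnorm(cfg$n_cells, 0, cfg$jitter_sd)
  raw <- cell_table(section_id, raw_c$x + jx, raw_c$y + jy,
                    family_label = lay$family[fam_idx], frame = "raw")

  ta <- template_anchor_positions(cfg$spec)
  inv_a <- inverse_warp(ta$x, ta$y, cfg)
  raw_a <- rigid_forward(inv_a$x, inv_a$y, cfg$rotation_deg, cfg$offset)
  anchors <- section_landmarks(section_id, ta$role, raw_a$x, raw_a$y,
                               frame = "raw")
  list(raw = raw, anchors = anchors, template_truth = truth)
}

#' Configuration for simulated EdU birthdating counts
#'
#' Each family's neurons are born along a Gaussian wave in embryonic time;
#' an EdU pulse at time t co-labels a neuron iff its birthdate falls in
#' the half-open window `[t, t + edu_window)`.
#'
#' @param families data.frame with columns `family, mu_birth, sigma_birth`
#'   (embryonic days).
#' @param timepoints Strictly increasing pulse times, embryonic days.
#' @param n_litters,n_embryos_per_litter,n_cells_per_embryo Design sizes.
#' @param edu_window Pulse labeling window, days (default 0.5, the
#'   half-day pulse spacing).
#' @param litter_jitter_sd SD (days) of an optional litter-level shift in
#'   effective conception time; 0 (off) by default.
#' @param seed Integer RNG seed.
#' @return A `birth_sim_config` list.
#' @export
birth_sim_config <- function(families, timepoints, n_litters = 4L,
                             n_embryos_per_litter = 3L,
                             n_cells_per_embryo = 100L, edu_window = 0.5,
                             litter_jitter_sd = 0, seed = 1L) {
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  req <- c("family", "mu_birth", "sigma_birth")
  if (!all(req %in% names(families)))
    stop("families needs columns: ", paste(req, collapse = ", "))
  if (any(families$sigma_birth < 0)) stop("sigma_birth must be >= 0")
  stopifnot(n_litters > 0, n_embryos_per_litter > 0, n_cells_per_embryo > 0,
            edu_window > 0, litter_jitter_sd >= 0)
  structure(list(families = families, timepoints = as.numeric(timepoints),
                 n_litters = as.integer(n_litters),
                 n_embryos_per_litter = as.integer(n_embryos_per_litter),
                 n_cells_per_embryo = as.integer(n_cells_per_embryo),
                 edu_window = edu_window, litter_jitter_sd = litter_jitter_sd,
                 seed = as.integer(seed)),
            class = "birth_sim_config")
}

#' Simulate a litter-level EdU co-labeling count table
#'
#' For each litter, embryo, family and pulse timepoint, draws per-cell
#' birthdates from the family's Gaussian birth wave and counts how many of
#' the `n_marker` marker-positive cells have a birthdate inside the pulse
#' window. One litter's embryos share a litter-specific time shift when
#' `litter_jitter_sd > 0`.
#'
#' @param cfg A [birth_sim_config()].
#' @return data.frame with columns
#'   `litter_id, embryo_id, timepoint, family, n_marker, n_colabel`.
#' @export
make_birth_counts <- function(cfg) {
  stopifnot(inherits(cfg, "birth_sim_config"))
  rows <- vector("list", cfg$n_litters * cfg$n_embryos_per_litter *
                   nrow(cfg$families))
  k <- 0L
  for (l in seq_len(cfg$n_litters)) {
    set.seed(cfg$seed + 1000L * l)
    shift <- if (cfg$litter_jitter_sd > 0)
      stats::rnorm(1, 0, cfg$litter_jitter_sd) else 0
    for (e in seq_len(cfg$n_embryos_per_litter)) {
      for (f in seq_len(nrow(cfg$families))) {
        mu <- cfg$families$mu_birth[f] + shift
        sg <- cfg$families$sigma_birth[f]
        bd <- if (sg > 0) stats::rnorm(cfg$n_cells_per_embryo, mu, sg)
              else rep(mu, cfg$n_cells_per_embryo)
        n_co <- vapply(cfg$timepoints, function(t)
          sum(bd >= t & bd < t + cfg$edu_window), integer(1))
        k <- k + 1L
        rows[[k]] <- data.frame(
          litter_id = sprintf("L%02d", l), embryo_id = sprintf("L%02d_E%d", l, e),
          timepoint = cfg$timepoints, family = cfg$families$family[f],
          n_marker = cfg$n_cells_per_embryo, n_colabel = n_co,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for simulated cell-type composition time series
#'
#' @param types data.frame with columns `type, mu_peak, sigma, weight`:
#'   Gaussian abundance profile of each type over embryonic time.
#' @param timepoints Embryonic days (quarter-day spacing in the emulated
#'   design), strictly increasing.
#' @param n_cells_per_timepoint Cells sampled per timepoint.
#' @param seed Integer RNG seed.
#' @return A `composition_sim_config` list.
#' @export
composition_sim_config <- function(types, timepoints,
                                   n_cells_per_timepoint = 1000L, seed = 1L) {
  if (nrow(types) == 0) stop("at least one type is required")
  req <- c("type", "mu_peak", "sigma", "weight")
  if (!all(req %in% names(types)))
    stop("types needs columns: ", paste(req, collapse = ", "))
  if (any(types$weight <= 0)) stop("weights must be positive")
  if (any(types$sigma <= 0)) stop("sigma must be positive")
  if (length(timepoints) == 0 || any(diff(timepoints) <= 0))
    stop("timepoints must be non-empty and strictly increasing")
  structure(list(types = types, timepoints = as.numeric(timepoints),
                 n_cells_per_timepoint = as.integer(n_cells_per_timepoint),
                 seed = as.integer(seed)),
            class = "composition_sim_config")
}

#' Simulate cell-type proportion time series
#'
#' At each timepoint the expected type mix is proportional to
#' `weight * dnorm(t, mu_peak, sigma)`; observed proportions come from a
#' multinomial draw of `n_cells_per_timepoint` cells, so per-timepoint
#' proportions sum to 1 exactly.
#'
#' @param cfg A [composition_sim_config()].
#' @return List of composition series (see [composition_series()]), one
#'   per type.
#' @export
make_composition_series <- function(cfg) {
  stopifnot(inherits(cfg, "composition_sim_config"))
  set.seed(cfg$seed)
  K <- nrow(cfg$types)
  props <- matrix(0, length(cfg$timepoints), K)
  for (i in seq_along(cfg$timepoints)) {
    w <- cfg$types$weight * stats::dnorm(cfg$timepoints[i], cfg$types$mu_peak,
                                         cfg$types$sigma)
    if (sum(w) <= 0) w <- rep(1, K)
    draw <- stats::rmultinom(1, cfg$n_cells_per_timepoint, w / sum(w))
    props[i, ] <- draw / cfg$n_cells_per_timepoint
  }
  out <- lapply(seq_len(K), function(k)
    composition_series(cfg$types$type[k], cfg$timepoints, props[, k],
                       compositional = TRUE))
  names(out) <- cfg$types$type
  out
}

#' Configuration for simulated dorsoventral depth profiles
#'
#' @param n_bins_raw Raw profile length (bins).
#' @param peaks data.frame with columns
#'   `genotype, marker, center_bin, width, amplitude`: Gaussian signal
#'   bumps per (genotype, marker); several rows per pair allowed.
#' @param noise_sd SD of additive noise per bin (profiles are clipped at
#'   0 so values stay nonnegative).
#' @param n_replicates Replicates per (genotype, marker).
#' @param seed Integer RNG seed.
#' @return A `profile_sim_config` list.
#' @export
profile_sim_config <- function(n_bins_raw, peaks, noise_sd = 0,
                               n_replicates = 3L, seed = 1L) {
  req <- c("genotype", "marker", "center_bin", "width", "amplitude")
  if (!all(req %in% names(peaks)))
    stop("peaks needs columns: ", paste(req, collapse = ", "))
  if (any(peaks$amplitude < 0)) stop("amplitudes must be >= 0")
  if (any(peaks$center_bin < 1 | peaks$center_bin > n_bins_raw))
    stop("center_bin must lie within [1, n_bins_raw]")
  stopifnot(n_bins_raw >= 1, noise_sd >= 0, n_replicates >= 1)
  structure(list(n_bins_raw = as.integer(n_bins_raw), peaks = peaks,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "profile_sim_config")
}

#' Simulate binned dorsoventral signal profiles
#'
#' @param cfg A [profile_sim_config()].
#' @return data.frame in long format:
#'   `genotype, marker, replicate, bin, value` with `value >= 0` and bin 1
#'   dorsal-most.
#' @export
make_depth_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "profile_sim_config"))
  bins <- seq_len(cfg$n_bins_raw)
  pairs <- unique(cfg$peaks[, c("genotype", "marker")])
  out <- list(); k <- 0L
  for (i in seq_len(nrow(pairs))) {
    pk <- cfg$peaks[cfg$peaks$genotype == pairs$genotype[i] &
                      cfg$peaks$marker == pairs$marker[i], , drop = FALSE]
    base <- rep(0, cfg$n_bins_raw)
    for (j in seq_len(nrow(pk)))
      base <- base + pk$amplitude[j] *
        exp(-(bins - pk$center_bin[j])^2 / (2 * pk$width[j]^2))
    set.seed(cfg$seed + 101L * i)
    for (r in seq_len(cfg$n_replicates)) {
      v <- base
      if (cfg$noise_sd > 0)
        v <- pmax(v + stats::rnorm(cfg$n_bins_raw, 0, cfg$noise_sd), 0)
      k <- k + 1L
      out[[k]] <- data.frame(genotype = pairs$genotype[i],
                             marker = pairs$marker[i], replicate = r,
                             bin = bins, value = v, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
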