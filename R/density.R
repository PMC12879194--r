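#' Two-dimensional kernel density estimate on a regular grid
#'
#' Axis-aligned Gaussian product kernel evaluated on a resolution x
#' resolution grid (MASS::kde2d semantics with the bandwidth expressed as
#' the kernel standard deviation per axis). With `bandwidth = NULL` the
#' normal-reference rule is used per axis. Grid limits extend beyond the
#' data range by `pad_sd` kernel SDs so the density mass is captured on
#' the grid.
#'
#' @param x,y Point coordinates (>= 2 points).
#' @param resolution Grid points per axis (default 100).
#' @param bandwidth `NULL` (auto) or length-1/2 numeric: kernel SD (h_x,
#'   h_y).
#' @param pad_sd Grid padding in kernel SDs (default 3.5).
#' @return A `density_grid` list: `x`, `y` (grid vectors), `z`
#'   (resolution x resolution density matrix), `bandwidth`, `resolution`.
#' @export
kde2d_grid <- function(x, y, resolution = 100L, bandwidth = NULL,
                       pad_sd = 3.5) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("kde2d needs at least 2 points")
  if (is.null(bandwidth)) {
    hx <- MASS::bandwidth.nrd(x) / 4
    hy <- MASS::bandwidth.nrd(y) / 4
    if (hx <= 0 || hy <= 0)
      stop("degenerate bandwidth: points identical along an axis; ",
           "supply bandwidth explicitly")
  } else {
    bandwidth <- rep_len(bandwidth, 2)
    hx <- bandwidth[1]; hy <- bandwidth[2]
    if (hx <= 0 || hy <= 0) stop("bandwidth must be positive")
  }
  lims <- c(range(x) + c(-1, 1) * pad_sd * hx,
            range(y) + c(-1, 1) * pad_sd * hy)
  # MASS::kde2d treats h as 4x the kernel SD
  k <- MASS::kde2d(x, y, h = c(4 * hx, 4 * hy), n = resolution, lims = lims)
  structure(list(x = k$x, y = k$y, z = k$z, bandwidth = c(hx = hx, hy = hy),
                 resolution = as.integer(resolution)),
            class = "density_grid")
}

#' Evaluate the Gaussian KDE at arbitrary points
#'
#' Exact kernel sum (not grid interpolation), using the same bandwidth
#' convention as [kde2d_grid()].
#'
#' @param x,y Sample points defining the KDE.
#' @param at_x,at_y Evaluation points (default: the sample itself).
#' @param bandwidth As in [kde2d_grid()].
#' @return Numeric vector of density values.
#' @export
kde2d_at_points <- function(x, y, at_x = x, at_y = y, bandwidth = NULL) {
  if (is.null(bandwidth)) {
    hx <- MASS::bandwidth.nrd(x) / 4
    hy <- MASS::bandwidth.nrd(y) / 4
    if (hx <= 0 || hy <= 0) stop("degenerate bandwidth")
  } else {
    bandwidth <- rep_len(bandwidth, 2)
    hx <- bandwidth[1]; hy <- bandwidth[2]
  }
  n <- length(x)
  vapply(seq_along(at_x), function(i)
    mean(stats::dnorm(at_x[i], x, hx) * stats::dnorm(at_y[i], y, hy)),
    numeric(1))
}

#' Highest-density contour levels over sample points
#'
#' For each fraction alpha the threshold is the density of the
#' ceiling(alpha * n)-th densest point; the member set is every point
#' whose density is at or above the threshold (ties included), i.e. the
#' contour drawn to fit the densest alpha fraction of points. Levels are
#' nested: smaller alpha gives an equal-or-higher threshold.
#'
#' @param density_at_points Density evaluated at each sample point (e.g.
#'   [kde2d_at_points()]).
#' @param fractions Fractions in (0, 1], default
#'   `c(0.50, 0.25, 0.15, 0.05, 0.025)`.
#' @return An `hdr_levels` data-structure: data.frame `alpha, threshold,
#'   n_members` plus a `members` attribute (list of logical vectors).
#' @export
hdr_levels <- function(density_at_points,
                       fractions = c(0.50, 0.25, 0.15, 0.05, 0.025)) {
  if (length(fractions) == 0) stop("fractions must be non-empty")
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  n <- length(density_at_points)
  ord <- sort(density_at_points, decreasing = TRUE)
  fractions <- sort(fractions, decreasing = TRUE)
  thr <- vapply(fractions, function(a) ord[ceiling(a * n)], numeric(1))
  members <- lapply(thr, function(th) density_at_points >= th)
  out <- data.frame(alpha = fractions, threshold = thr,
                    n_members = vapply(members, sum, integer(1)))
  attr(out, "members") <- members
  class(out) <- c("hdr_levels", "data.frame")
  out
}

#' Dorsoventral depth histogram of normalized y-coordinates
#'
#' Assigns each template-frame y-coordinate to one of `n_bins` half-open
#' bins spanning the full dorsoventral extent (default the template range
#' `[-2000, 2000]`), bin 1 dorsal-most. Coordinates outside the range are
#' clipped into the end bins with a warning. Optional smoothing is a
#' Gaussian kernel smoother over bins; raw counts are always retained.
#'
#' @param y Template-frame y-coordinates.
#' @param n_bins Number of bins (default 200).
#' @param range_y Dorsoventral range `c(ventral, dorsal)`.
#' @param smooth Apply Gaussian smoothing (default `FALSE`).
#' @param smooth_sd Smoother SD in bins (default 3).
#' @return A `depth_profile` list: `counts` (length `n_bins`, bin 1
#'   dorsal-most), `smoothed` (or `NULL`), `edges` (dorsal-to-ventral bin
#'   edges), `n_bins`.
#' @export
depth_histogram <- function(y, n_bins = 200L, range_y = c(-2000, 2000),
                            smooth = FALSE, smooth_sd = 3) {
  stopifnot(n_bins >= 1, length(range_y) == 2, range_y[1] < range_y[2])
  y_v <- range_y[1]; y_d <- range_y[2]
  if (any(y < y_v | y > y_d))
    warning(sum(y < y_v | y > y_d),
            " coordinate(s) outside the template range; clipped to end bins")
  width <- (y_d - y_v) / n_bins
  # bin 1 dorsal-most, half-open toward ventral: bin i covers
  # (y_d - i*width, y_d - (i-1)*width], dorsal end closed
  idx <- floor((y_d - y) / width) + 1
  idx[y == y_d] <- 1L
  idx <- pmin(pmax(idx, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  smoothed <- if (smooth) gaussian_smooth(counts, smooth_sd) else NULL
  structure(list(counts = counts, smoothed = smoothed,
                 edges = seq(y_d, y_v, length.out = n_bins + 1),
                 n_bins = as.integer(n_bins)),
            class = "depth_profile")
}

gaussian_smooth <- function(v, sd_bins) {
  n <- length(v)
  half <- ceiling(4 * sd_bins)
  k <- stats::dnorm(-half:half, 0, sd_bins)
  k <- k / sum(k)
  out <- stats::filter(c(rep(v[1], half), v, rep(v[n], half)), k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Compress a raw profile to a common bin number and normalize
#'
#' Raw bins are aggregated by sum into `n_bins_common` equal spans, with
#' raw bins that straddle a boundary pro-rated by fractional overlap; the
#' compressed profile is then normalized to sum to 1 so bins are
#' proportions of that replicate's total signal. The dorsal view is the
#' first `dorsal_bins` bins; quintiles split the common bins into 5 equal
#' dorsoventral groups.
#'
#' @param values Raw profile (bin 1 dorsal-most), length >=
#'   `n_bins_common`.
#' @param n_bins_common Common bin number (default 80).
#' @param dorsal_bins Dorsal-view length (default 56).
#' @return A `compressed_profile` list: `weights` (length
#'   `n_bins_common`, summing to 1), `dorsal_view`, `quintile` (bin ->
#'   quintile index 1..5), `raw_total`.
#' @export
compress_profile <- function(values, n_bins_common = 80L, dorsal_bins = 56L) {
  n_raw <- length(values)
  if (n_raw < n_bins_common)
    stop("cannot upsample: raw profile has fewer bins than n_bins_common")
  if (any(values < 0)) stop("raw profile values must be >= 0")
  edges <- seq(0, n_raw, length.out = n_bins_common + 1)
  agg <- numeric(n_bins_common)
  for (i in seq_len(n_bins_common)) {
    lo <- edges[i]; hi <- edges[i + 1]
    j0 <- floor(lo) + 1; j1 <- ceiling(hi)
    for (j in j0:j1) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) agg[i] <- agg[i] + values[j] * overlap
    }
  }
  tot <- sum(agg)
  if (tot <= 0) stop("profile has no signal")
  w <- agg / tot
  quint <- rep(1:5, each = ceiling(n_bins_common / 5),
               length.out = n_bins_common)
  structure(list(weights = w,
                 dorsal_view = w[seq_len(min(dorsal_bins, n_bins_common))],
                 quintile = quint, raw_total = tot),
            class = "compressed_profile")
}

#' Colocalization profile from two thresholded-signal masks
#'
#' Elementwise product of two equal-length binary (0/1) profiles, the
#' row-collapsed analogue of multiplying two thresholded images before
#' histogramming the product.
#'
#' @param mask_a,mask_b Binary vectors of equal length.
#' @return Numeric product profile.
#' @export
colocalize_profiles <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b))
    stop("shape error: masks must have equal length")
  if (!all(mask_a %in% c(0, 1)) || !all(mask_b %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  mask_a * mask_b
}

#' Quintile ANOVA on compressed dorsoventral profiles
#'
#' Each replicate's compressed profile is reduced to 5 quintile weights
#' (sums of its 16-bin dorsoventral groups when `n_bins_common = 80`),
#' which feed a three-way ANOVA with all interactions
#' (genotype x quintile x cell-type). Post-hoc pairwise genotype
#' comparisons are run per (quintile, cell-type) cell via Tukey HSD.
#'
#' @param profiles data.frame with columns
#'   `genotype, cell_type, replicate, bin, weight` of compressed-profile
#'   weights (bin 1 dorsal-most).
#' @param n_quintiles Number of depth groups (default 5).
#' @return A `quintile_stats` list: `anova` (data.frame term, df, F, p),
#'   `posthoc` (data.frame quintile, cell_type, comparison, diff, p_adj),
#'   `quintile_weights` (the per-replicate quintile table).
#' @export
quintile_stats <- function(profiles, n_quintiles = 5L) {
  req <- c("genotype", "cell_type", "replicate", "bin", "weight")
  if (!all(req %in% names(profiles)))
    stop("profiles needs columns: ", paste(req, collapse = ", "))
  n_bins <- max(profiles$bin)
  qmap <- rep(seq_len(n_quintiles), each = ceiling(n_bins / n_quintiles),
              length.out = n_bins)
  profiles$quintile <- qmap[profiles$bin]
  qw <- stats::aggregate(weight ~ genotype + cell_type + replicate + quintile,
                         data = profiles, FUN = sum)
  reps <- stats::aggregate(replicate ~ genotype + cell_type, data = qw,
                           FUN = function(v) length(unique(v)))
  if (any(reps$replicate < 2))
    stop("need >= 2 replicates per genotype x cell-type group")
  qw$genotype <- factor(qw$genotype)
  qw$cell_type <- factor(qw$cell_type)
  qw$quintile_f <- factor(qw$quintile)
  multi_type <- nlevels(qw$cell_type) > 1
  form <- if (multi_type) weight ~ genotype * quintile_f * cell_type
          else weight ~ genotype * quintile_f
  fit <- stats::aov(form, data = qw)
  an <- summary(fit)[[1]]
  anova_tab <- data.frame(term = trimws(rownames(an)), df = an$Df,
                          F = an$`F value`, p = an$`Pr(>F)`,
                          stringsAsFactors = FALSE)
  post <- list(); k <- 0L
  for (q in sort(unique(qw$quintile))) for (ct in levels(qw$cell_type)) {
    d <- qw[qw$quintile == q & qw$cell_type == ct, ]
    if (nlevels(droplevels(d$genotype)) < 2) next
    a1 <- stats::aov(weight ~ genotype, data = droplevels(d))
    tk <- tryCatch(stats::TukeyHSD(a1)$genotype, error = function(e) NULL)
    if (is.null(tk)) next
    for (r in seq_len(nrow(tk))) {
      k <- k + 1L
      post[[k]] <- data.frame(quintile = q, cell_type = ct,
                              comparison = rownames(tk)[r],
                              diff = tk[r, "diff"], p_adj = tk[r, "p adj"],
                              stringsAsFactors = FALSE)
    }
  }
  posthoc <- if (k > 0) do.call(rbind, post) else
    data.frame(quintile = integer(), cell_type = character(),
               comparison = character(), diff = numeric(), p_adj = numeric())
  rownames(posthoc) <- NULL
  structure(list(anova = anova_tab, posthoc = posthoc, quintile_weights = qw),
            class = "quintile_stats")
}

#' Two-way composition ANOVA with per-type Tukey comparisons
#'
#' For replicate cell-type composition tables (percentage of all neurons
#' per subtype per replicate), runs a two-way ANOVA
#' (cell-type x genotype) and Tukey HSD between genotypes for each
#' cell-type.
#'
#' @param composition data.frame with columns
#'   `genotype, cell_type, replicate, value`.
#' @return List with `anova` and `posthoc` data.frames as in
#'   [quintile_stats()].
#' @export
composition_anova <- function(composition) {
  req <- c("genotype", "cell_type", "replicate", "value")
  if (!all(req %in% names(composition)))
    stop("composition needs columns: ", paste(req, collapse = ", "))
  composition$genotype <- factor(composition$genotype)
  composition$cell_type <- factor(composition$cell_type)
  fit <- stats::aov(value ~ cell_type * genotype, data = composition)
  an <- summary(fit)[[1]]
  anova_tab <- data.frame(term = trimws(rownames(an)), df = an$Df,
                          F = an$`F value`, p = an$`Pr(>F)`,
                          stringsAsFactors = FALSE)
  post <- list(); k <- 0L
  for (ct in levels(composition$cell_type)) {
    d <- droplevels(composition[composition$cell_type == ct, ])
    if (nlevels(d$genotype) < 2) next
    tk <- tryCatch(stats::TukeyHSD(stats::aov(value ~ genotype, data = d))$genotype,
                   error = function(e) NULL)
    if (is.null(tk)) next
    for (r in seq_len(nrow(tk))) {
      k <- k + 1L
      post[[k]] <- data.frame(cell_type = ct, comparison = rownames(tk)[r],
                              diff = tk[r, "diff"], p_adj = tk[r, "p adj"],
                              stringsAsFactors = FALSE)
    }
  }
  posthoc <- if (k > 0) do.call(rbind, post) else
    data.frame(cell_type = character(), comparison = character(),
               diff = numeric(), p_adj = numeric())
  rownames(posthoc) <- NULL
  list(anova = anova_tab, posthoc = posthoc)
}
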