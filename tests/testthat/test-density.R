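test_that("2D KDE grids are normalized densities at the requested resolution", {
  set.seed(1)
  x <- rnorm(500); y <- rnorm(500, sd = 2)
  g <- kde2d_grid(x, y)
  expect_equal(dim(g$z), c(100L, 100L))
  riemann <- sum(g$z) * diff(g$x[1:2]) * diff(g$y[1:2])
  expect_equal(riemann, 1, tolerance = 0.01)

  # closed form: a single kernel evaluated at its own center
  h <- 2
  expect_equal(kde2d_at_points(0, 0, 0, 0, bandwidth = h),
               1 / (2 * pi * h^2))

  expect_error(kde2d_grid(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(kde2d_grid(1, 1), "2 points")
})

test_that("HDR thresholds follow the densest-fraction rule and nest", {
  h <- hdr_levels(c(1, 2, 3, 4), fractions = 0.5)
  expect_equal(h$threshold, 3)
  expect_equal(h$n_members, 2L)

  # alpha = 1 keeps every point
  expect_equal(hdr_levels(c(1, 2, 3, 4), fractions = 1)$n_members, 4L)

  # nesting and monotone thresholds on a realistic sample
  set.seed(2)
  x <- rnorm(400); y <- rnorm(400)
  d <- kde2d_at_points(x, y)
  hs <- hdr_levels(d)
  expect_true(all(diff(hs$threshold) >= 0))  # rows ordered alpha-descending
  m <- attr(hs, "members")
  for (i in seq_len(length(m) - 1))
    expect_true(all(m[[i + 1]] <= m[[i]]))   # smaller alpha nested inside

  expect_error(hdr_levels(d, numeric(0)), "non-empty")
  expect_error(hdr_levels(d, 1.5), "in \\(0, 1\\]")
})

test_that("HDR coverage converges to the nominal fraction", {
  set.seed(3)
  x <- rnorm(2000); y <- rnorm(2000)
  hs <- hdr_levels(kde2d_at_points(x, y))
  cover <- 100 * hs$n_members / 2000
  expect_equal(cover, 100 * hs$alpha, tolerance = 0.04)  # within 2 points
})

test_that("depth histograms bin 200-fold, conserve counts, and clip", {
  set.seed(4)
  y <- runif(10000, -2000, 2000)
  dp <- depth_histogram(y)
  expect_equal(dp$n_bins, 200L)
  expect_length(dp$counts, 200L)
  expect_equal(sum(dp$counts), 10000L)
  # multinomial oracle: for 10,000 draws over 200 equiprobable bins the
  # simulated 99th percentile of the max/min count ratio is 2.85
  expect_lt(max(dp$counts) / min(dp$counts), 2.85)

  # dorsal-most coordinate lands in bin 1, ventral-most in bin 200
  ends <- depth_histogram(c(2000, -2000), n_bins = 200)
  expect_equal(which(ends$counts == 1), c(1L, 200L))

  expect_warning(out <- depth_histogram(c(0, 2500)), "clipped")
  expect_equal(sum(out$counts), 2L)
  expect_equal(out$counts[1], 1L)

  sm <- depth_histogram(y, smooth = TRUE)
  expect_equal(sum(sm$counts), 10000L)       # raw counts retained
  expect_length(sm$smoothed, 200L)
})

test_that("profile compression pro-rates, normalizes, and exposes views", {
  cp <- compress_profile(c(1, 3, 5, 7), n_bins_common = 2)
  expect_equal(cp$weights, c(0.25, 0.75))  # sums (4, 12) normalized

  v <- c(2, 4, 6, 8, 10)
  same <- compress_profile(v, n_bins_common = 5)
  expect_equal(same$weights, v / sum(v))

  raw <- abs(rnorm(200)) + 0.1
  cp80 <- compress_profile(raw)
  expect_length(cp80$weights, 80L)
  expect_equal(sum(cp80$weights), 1, tolerance = 1e-9)
  expect_length(cp80$dorsal_view, 56L)
  expect_equal(unname(table(cp80$quintile)), rep(16L, 5), ignore_attr = TRUE)
  # total signal conserved before normalization
  expect_equal(cp80$raw_total, sum(raw))

  expect_error(compress_profile(1:10, n_bins_common = 80), "upsample")
})

test_that("colocalization is the elementwise mask product", {
  a <- c(0, 1, 1, 1, 0, 0)
  expect_equal(colocalize_profiles(a, a), a)
  b <- c(1, 0, 0, 0, 1, 1)
  expect_equal(colocalize_profiles(a, b), rep(0, 6))
  m1 <- rep(0, 20); m1[8:14] <- 1
  m2 <- rep(0, 20); m2[10:12] <- 1
  prod <- colocalize_profiles(m1, m2)
  expect_equal(which(prod == 1), 10:12)
  expect_error(colocalize_profiles(a, b[-1]), "shape")
  expect_error(colocalize_profiles(a * 2, b), "binary")
})

test_that("quintile ANOVA flags genotype shifts and not their absence", {
  mk_profiles <- function(center_mut) {
    cfg <- profile_sim_config(
      160,
      peaks = data.frame(genotype = c("wt", "mut"), marker = "m1",
                         center_bin = c(40, center_mut), width = 12,
                         amplitude = 5),
      noise_sd = 0.05, n_replicates = 3, seed = 17)
    pr <- make_depth_profiles(cfg)
    do.call(rbind, lapply(split(pr, list(pr$genotype, pr$replicate)),
      function(d) {
        cp <- compress_profile(d$value[order(d$bin)])
        data.frame(genotype = d$genotype[1], cell_type = "m1",
                   replicate = d$replicate[1], bin = seq_along(cp$weights),
                   weight = cp$weights)
      }))
  }
  shifted <- quintile_stats(mk_profiles(80))
  inter <- shifted$anova[shifted$anova$term == "genotype:quintile_f", ]
  expect_lt(inter$p, 0.001)

  flat <- quintile_stats(mk_profiles(40))
  inter0 <- flat$anova[flat$anova$term == "genotype:quintile_f", ]
  expect_gt(inter0$p, 0.05)

  expect_equal(sort(unique(shifted$quintile_weights$quintile)), 1:5)
})

test_that("per-quintile post hoc separates hand-sized group differences", {
  # one-way oracle: {0.30, 0.32, 0.31} vs {0.50, 0.52, 0.51} gives
  # t = 0.2 / (0.01 * sqrt(2/3)) = 24.49 and p well below 0.001
  prof <- expand.grid(genotype = c("wt", "mut"), replicate = 1:3,
                      bin = 1:5, stringsAsFactors = FALSE)
  prof$cell_type <- "ct"
  base <- c(wt = 0.30, mut = 0.50)
  jit <- c(0, 0.02, 0.01)
  prof$weight <- base[prof$genotype] + jit[prof$replicate]
  # remaining quintiles share the rest so replicate totals stay sane
  q1 <- quintile_stats(prof, n_quintiles = 5)
  ph <- q1$posthoc[q1$posthoc$quintile == 1, ]
  expect_lt(ph$p_adj, 0.001)
  expect_equal(abs(ph$diff), 0.2, tolerance = 1e-9)

  # identical groups across genotypes: F = 0, p = 1 for the genotype term
  prof$weight <- 0.2 + jit[prof$replicate]
  q0 <- quintile_stats(prof)
  gen <- q0$anova[q0$anova$term == "genotype", ]
  expect_equal(gen$F, 0, tolerance = 1e-12)
  expect_equal(gen$p, 1, tolerance = 1e-12)
})

test_that("two-way composition ANOVA runs Tukey per cell type", {
  set.seed(9)
  comp <- expand.grid(genotype = c("ctl", "dko"), replicate = 1:3,
                      cell_type = c("M", "N", "X"), stringsAsFactors = FALSE)
  eff <- ifelse(comp$cell_type == "M" & comp$genotype == "dko", 10, 0)
  comp$value <- 20 + eff + rnorm(nrow(comp), 0, 1)
  res <- composition_anova(comp)
  expect_true(all(c("cell_type", "genotype", "cell_type:genotype") %in%
                    res$anova$term))
  pm <- res$posthoc[res$posthoc$cell_type == "M", ]
  pn <- res$posthoc[res$posthoc$cell_type == "N", ]
  expect_lt(pm$p_adj, 0.01)
  expect_gt(pn$p_adj, 0.05)
})
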