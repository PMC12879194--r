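test_that("litter fractions average embryos and propagate missing data", {
  counts <- data.frame(
    litter_id = "L1", embryo_id = c("E1", "E2"), timepoint = 11.5,
    family = "A", n_marker = c(10, 10), n_colabel = c(3, 5))
  fr <- colabel_fractions(counts)
  expect_equal(fr$fraction, 0.4)  # mean(0.3, 0.5)

  # upper bound: all marker cells co-labeled
  full <- transform(counts, n_colabel = n_marker)
  expect_equal(colabel_fractions(full)$fraction, 1.0)

  # zero marker cells: missing, never zero
  none <- transform(counts, n_marker = 0, n_colabel = 0)
  expect_message(fr0 <- colabel_fractions(none), "missing")
  expect_true(is.na(fr0$fraction))

  expect_error(colabel_fractions(transform(counts, n_colabel = 11)),
               "exceed")
})

test_that("cumulative curves follow the normalization arithmetic", {
  # two timepoints with litter means 0.2 and 0.3; p = (40, 60);
  # a litter with f = 0.25 at t2 gets C = 100*0.25/0.5 + 40 = 90
  fr <- data.frame(litter_id = rep(c("L1", "L2"), each = 2),
                   timepoint = rep(c(1, 2), 2), family = "A",
                   fraction = c(0.2, 0.25, 0.2, 0.35))
  cc <- cumulative_curves(fr)
  expect_equal(cc$percents$p, c(40, 60))
  expect_equal(cc$curves$cumulative_percent[
    cc$curves$litter_id == "L1" & cc$curves$timepoint == 2], 90)

  # mean over litters at the final timepoint is exactly 100
  final <- cc$curves[cc$curves$timepoint == 2, ]
  expect_equal(mean(final$cumulative_percent), 100)
  expect_equal(sum(cc$percents$p), 100)

  # single timepoint: p = 100 and mean C = 100
  one <- cumulative_curves(data.frame(litter_id = c("L1", "L2"),
                                      timepoint = 12, family = "A",
                                      fraction = c(0.1, 0.3)))
  expect_equal(one$percents$p, 100)
  expect_equal(mean(one$curves$cumulative_percent), 100)

  expect_error(cumulative_curves(transform(fr, fraction = 0)), "no-|signal")
})

test_that("cumulative curves are conserved and nondecreasing on synthetic data", {
  bc <- make_birth_counts(edu_design_birth_cfg(seed = 8))
  cc <- cumulative_curves(colabel_fractions(bc))
  for (fam in unique(cc$percents$family))
    expect_equal(sum(cc$percents$p[cc$percents$family == fam]), 100)
  # the litter-mean curve is nondecreasing by construction; individual
  # litter curves may dip locally by at most the within-timepoint spread
  for (fam in unique(cc$curves$family)) {
    d <- cc$curves[cc$curves$family == fam, ]
    mcurve <- aggregate(cumulative_percent ~ timepoint, data = d, FUN = mean)
    expect_true(all(diff(mcurve$cumulative_percent) >= -1e-9))
    spread <- max(vapply(split(d$cumulative_percent, d$timepoint),
                         function(v) diff(range(v)), numeric(1)))
    for (r in split(d, d$litter_id)) {
      r <- r[order(r$timepoint), ]
      expect_true(all(diff(r$cumulative_percent) >= -spread - 1e-9))
    }
  }
  finals <- aggregate(cumulative_percent ~ family,
                      data = cc$curves[cc$curves$timepoint == 13.5, ],
                      FUN = mean)
  expect_equal(finals$cumulative_percent, rep(100, nrow(finals)))
})

test_that("sigmoid fits recover exact and noisy generating parameters", {
  x <- seq(10.5, 13.5, by = 0.5)
  y4 <- 0 + (100 - 0) / (1 + (11.75 / x)^8)
  f4 <- fit_sigmoid(x, y4, model = "4PL", fallback = FALSE)
  expect_true(f4$converged)
  expect_equal(unname(f4$params), c(0, 100, 11.75, 8), tolerance = 1e-4)
  expect_equal(f4$halfmax, 11.75, tolerance = 1e-6)

  # analytic identity of the 4PL form: y(c) = (a + d) / 2
  p <- f4$params
  y_at_c <- p["a"] + (p["d"] - p["a"]) / (1 + (p["c"] / p["c"])^p["b"])
  expect_equal(unname(y_at_c), unname((p["a"] + p["d"]) / 2))

  # noisy logistic: xmid recovered within 0.2 (tolerance fixed from a
  # 200-replicate simulation of this exact design)
  xmids <- vapply(1:20, function(s) {
    set.seed(s)
    xx <- seq(10.5, 13.5, length.out = 7)
    yy <- 100 / (1 + exp((12.0 - xx) / 0.4)) + rnorm(7, 0, 2)
    f <- fit_sigmoid(xx, yy, model = "logistic")
    unname(f$params["xmid"])
  }, numeric(1))
  expect_true(all(abs(xmids - 12.0) < 0.2))

  # logistic invariant: y(xmid) = Asym / 2
  set.seed(31)
  yy <- 100 / (1 + exp((12.0 - x) / 0.4)) + rnorm(7, 0, 1)
  fl <- fit_sigmoid(x, yy, model = "logistic")
  pl <- fl$params
  expect_equal(unname(pl["Asym"] / (1 + exp((pl["xmid"] - pl["xmid"]) / pl["scal"]))),
               unname(pl["Asym"] / 2))

  # hopeless input yields a flagged non-fit, not an error
  bad <- fit_sigmoid(x, rep(c(0, 100), length.out = 7), model = "logistic")
  expect_false(bad$converged)
  expect_true(is.na(bad$halfmax))
})

test_that("4PL falls back to 5PL when the symmetric fit is poor", {
  # strongly asymmetric curve with no slow-growth phase
  x <- seq(10.5, 13.5, by = 0.5)
  y <- 100 / (1 + (11.2 / x)^40)^0.08
  f <- fit_sigmoid(x, y, model = "4PL", fallback = TRUE, r2_min = 0.999)
  expect_true(f$converged)
  if (f$model == "5PL") expect_true(is.finite(f$halfmax))
})

test_that("pairwise inflection tests match hand-computed t and BH values", {
  mk <- function(xmids, scals) lapply(seq_along(xmids), function(i)
    structure(list(model = "logistic",
                   params = c(Asym = 100, xmid = xmids[i], scal = scals[i]),
                   halfmax = xmids[i], rss = 0, r_squared = 1,
                   converged = TRUE), class = "sigmoid_fit"))
  # identical samples: t = 0, p = 1
  fits <- list(A = mk(c(10, 10.1, 9.9), c(0.4, 0.5, 0.45)),
               B = mk(c(10, 10.1, 9.9), c(0.4, 0.5, 0.45)))
  tt <- inflection_tests(fits)
  xm <- tt[tt$statistic == "xmid", ]
  expect_equal(xm$t, 0)
  expect_equal(xm$p, 1)

  # hand formula: t = 2 / (0.1 * sqrt(2/3)) = 24.49, df = 4
  fits2 <- list(A = mk(c(9.9, 10.0, 10.1), c(0.4, 0.41, 0.39)),
                B = mk(c(11.9, 12.0, 12.1), c(0.4, 0.41, 0.39)))
  tt2 <- inflection_tests(fits2)
  xm2 <- tt2[tt2$statistic == "xmid", ]
  expect_equal(abs(xm2$t), 2 / (0.1 * sqrt(2 / 3)), tolerance = 1e-6)
  expect_equal(xm2$df, 4)
  expect_equal(xm2$p, 2 * pt(-abs(xm2$t), 4), tolerance = 1e-10)

  # BH step-up by hand: {0.01, 0.02, 0.03} -> {0.03, 0.03, 0.03}
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
  expect_true(all(tt2$q >= tt2$p - 1e-12))
})

test_that("per-litter logistic fits feed the family comparison pipeline", {
  bc <- make_birth_counts(edu_design_birth_cfg(seed = 21))
  fits <- replicate_logistic_fits(bc)
  expect_named(fits, c("F1", "F2", "F3"))
  expect_true(all(vapply(fits, length, integer(1)) == 4L))
  tab <- inflection_tests(fits)
  expect_equal(nrow(tab), 6L)  # 3 pairs x 2 statistics
  expect_true(all(tab$q >= tab$p - 1e-12, na.rm = TRUE))
  expect_true(all(tab$q <= 1, na.rm = TRUE))
  # clearly separated waves: all xmid pairs significant
  expect_true(all(tab$q[tab$statistic == "xmid"] < 0.01))
})
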