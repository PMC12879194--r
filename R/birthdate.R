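#' Litter-level EdU co-labeling fractions
#'
#' For each embryo the co-labeled fraction is `n_colabel / n_marker`; the
#' mean of these fractions across the embryos of a litter is one data
#' point. Embryos with zero marker-positive cells at a timepoint
#' contribute a missing value, never 0.
#'
#' @param counts data.frame with columns
#'   `litter_id, embryo_id, timepoint, family, n_marker, n_colabel`.
#' @return data.frame `litter_id, timepoint, family, fraction` with one
#'   row per litter x timepoint x family; `fraction` in `[0, 1]` or `NA`.
#' @export
colabel_fractions <- function(counts) {
  req <- c("litter_id", "embryo_id", "timepoint", "family", "n_marker",
           "n_colabel")
  if (!all(req %in% names(counts)))
    stop("counts needs columns: ", paste(req, collapse = ", "))
  if (any(counts$n_colabel > counts$n_marker, na.rm = TRUE))
    stop("n_colabel cannot exceed n_marker")
  frac <- ifelse(counts$n_marker > 0, counts$n_colabel / counts$n_marker, NA)
  if (anyNA(frac))
    message(sum(is.na(frac)), " embryo-timepoint records had no marker+ cells; ",
            "recorded as missing")
  agg <- stats::aggregate(frac,
                          by = list(litter_id = counts$litter_id,
                                    timepoint = counts$timepoint,
                                    family = counts$family),
                          FUN = function(v) if (all(is.na(v))) NA_real_
                                            else mean(v, na.rm = TRUE))
  names(agg)[4] <- "fraction"
  agg <- agg[order(agg$family, agg$litter_id, agg$timepoint), ]
  rownames(agg) <- NULL
  agg
}

#' Cumulative birthdating curves
#'
#' Per family: the per-timepoint mean fraction over litters `m_t` is
#' normalized to a birth percentage `p_t = 100 m_t / sum(m)`, so the p's
#' describe the percent of the family born at each pulse time within the
#' measured range. The mean birth percentage of all prior timepoints is
#' then added to each litter's own (normalized) value at a timepoint, so
#' within-timepoint variation is preserved while the mean cumulative
#' co-labeling at the final timepoint is exactly 100.
#'
#' @param fractions Output of [colabel_fractions()] (columns
#'   `litter_id, timepoint, family, fraction`).
#' @return List with `curves` (data.frame
#'   `litter_id, timepoint, family, cumulative_percent`) and `percents`
#'   (data.frame `family, timepoint, p` with the normalized per-timepoint
#'   mean birth percentages).
#' @export
cumulative_curves <- function(fractions) {
  req <- c("litter_id", "timepoint", "family", "fraction")
  if (!all(req %in% names(fractions)))
    stop("fractions needs columns: ", paste(req, collapse = ", "))
  curves <- list(); percents <- list()
  for (fam in unique(fractions$family)) {
    d <- fractions[fractions$family == fam, , drop = FALSE]
    tps <- sort(unique(d$timepoint))
    m <- vapply(tps, function(t)
      mean(d$fraction[d$timepoint == t], na.rm = TRUE), numeric(1))
    if (!any(is.finite(m)) || sum(m, na.rm = TRUE) == 0)
      stop("no co-labeling signal for family ", fam)
    tot <- sum(m, na.rm = TRUE)
    p <- 100 * m / tot
    prior <- c(0, cumsum(p))[seq_along(p)]
    d$cumulative_percent <- 100 * d$fraction / tot +
      prior[match(d$timepoint, tps)]
    curves[[fam]] <- d[, c("litter_id", "timepoint", "family",
                           "cumulative_percent")]
    percents[[fam]] <- data.frame(family = fam, timepoint = tps, p = p,
                                  stringsAsFactors = FALSE)
  }
  out_c <- do.call(rbind, curves); rownames(out_c) <- NULL
  out_p <- do.call(rbind, percents); rownames(out_p) <- NULL
  list(curves = out_c, percents = out_p)
}

# GraphPad-style dose-response forms with time as the "concentration" axis
fourpl <- function(x, a, d, c, b) a + (d - a) / (1 + (c / x)^b)
fivepl <- function(x, a, d, c, b, s) a + (d - a) / (1 + (c / x)^b)^s

# x at which a converged fit crosses half of its dynamic range
halfmax_time <- function(pred, lo, hi, bottom, top) {
  target <- (bottom + top) / 2
  f <- function(x) pred(x) - target
  if (f(lo) * f(hi) > 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Fit a sigmoid to a birthdating time series
#'
#' Three model families are supported: the self-starting logistic
#' (`SSlogis`: `Asym / (1 + exp((xmid - x)/scal))`), the four-parameter
#' logistic 4PL (`a + (d - a)/(1 + (c/x)^b)`, half-max at `x = c`) and the
#' asymmetric five-parameter 5PL (`a + (d - a)/(1 + (c/x)^b)^s`). When a
#' 4PL fit fails to converge or explains less than `r2_min` of the
#' variance (a negligible slow-growth phase makes the symmetric form
#' unfit), the fit falls back to the 5PL.
#'
#' @param x Timepoints (embryonic days).
#' @param y Values (cumulative percent, typically).
#' @param model "logistic", "4PL" or "5PL".
#' @param fallback If `TRUE` (default) a failing 4PL falls back to 5PL.
#' @param r2_min R-squared threshold triggering the fallback.
#' @return A `sigmoid_fit` list: `model`, `params` (named vector),
#'   `halfmax` (fitted half-max time), `rss`, `r_squared`, `converged`.
#'   Non-convergence of all candidates yields `converged = FALSE`, never
#'   an error.
#' @export
fit_sigmoid <- function(x, y, model = c("4PL", "logistic", "5PL"),
                        fallback = TRUE, r2_min = 0.95) {
  model <- match.arg(model)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n_par <- c(logistic = 3L, `4PL` = 4L, `5PL` = 5L)[[model]]
  if (length(unique(x)) < n_par)
    stop("need at least ", n_par, " distinct x values for a ", model, " fit")
  fit <- fit_sigmoid_one(x, y, model)
  if (model == "4PL" && fallback &&
      (!fit$converged || fit$r_squared < r2_min)) {
    fit5 <- fit_sigmoid_one(x, y, "5PL")
    if (fit5$converged) fit <- fit5
  }
  fit
}

fit_sigmoid_one <- function(x, y, model) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxiter = 1024, maxfev = 10000)
  bottom <- min(y); top <- max(y)
  half <- (bottom + top) / 2
  c0 <- x[which.min(abs(y - half))]
  increasing <- stats::cor(x, y) >= 0
  b0 <- if (increasing) 5 else -5
  res <- tryCatch({
    if (model == "logistic") {
      f <- stats::nls(y ~ SSlogis(x, Asym, xmid, scal),
                      data = data.frame(x = x, y = y),
                      control = stats::nls.control(maxiter = 500,
                                                   warnOnly = FALSE))
      p <- stats::coef(f)
      list(fit = f, params = p, halfmax = unname(p["xmid"]))
    } else if (model == "4PL") {
      f <- minpack.lm::nlsLM(
        y ~ fourpl(x, a, d, c, b), data = data.frame(x = x, y = y),
        start = list(a = bottom, d = top, c = c0, b = b0),
        lower = c(-Inf, -Inf, min(x) / 4, -100),
        upper = c(Inf, Inf, max(x) * 4, 100), control = ctrl)
      p <- stats::coef(f)
      list(fit = f, params = p, halfmax = unname(p["c"]))
    } else {
      f <- minpack.lm::nlsLM(
        y ~ fivepl(x, a, d, c, b, s), data = data.frame(x = x, y = y),
        start = list(a = bottom, d = top, c = c0, b = b0, s = 1),
        lower = c(-Inf, -Inf, min(x) / 4, -100, 1e-3),
        upper = c(Inf, Inf, max(x) * 4, 100, 100), control = ctrl)
      p <- stats::coef(f)
      pred <- function(z) fivepl(z, p["a"], p["d"], p["c"], p["b"], p["s"])
      hm <- halfmax_time(pred, min(x) / 4, max(x) * 4, p["a"], p["d"])
      list(fit = f, params = p, halfmax = hm)
    }
  }, error = function(e) NULL)
  if (is.null(res)) {
    return(structure(list(model = model, params = NULL, halfmax = NA_real_,
                          rss = NA_real_, r_squared = NA_real_,
                          converged = FALSE), class = "sigmoid_fit"))
  }
  rss <- sum(stats::residuals(res$fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(model = model, params = res$params, halfmax = res$halfmax,
                 rss = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 converged = TRUE),
            class = "sigmoid_fit")
}

#' Pairwise inflection and steepness tests across families
#'
#' Per-replicate logistic fits yield one inflection time (`xmid`) and one
#' scaling factor (`scal`, curve steepness) per replicate; for every pair
#' of families a two-sample t-test compares each statistic's
#' distributions, with Benjamini-Hochberg adjustment across the family
#' pairs of each statistic.
#'
#' @param fits Named list: family -> list of `sigmoid_fit` objects from
#'   per-replicate logistic fits (non-converged fits are dropped).
#' @param var_equal Equal-variance t-test (default `TRUE`); `FALSE` gives
#'   Welch.
#' @return data.frame
#'   `family_A, family_B, statistic, t, df, p, q` (q = BH-adjusted p).
#' @export
inflection_tests <- function(fits, var_equal = TRUE) {
  stats_of <- function(fl, par) {
    v <- vapply(fl, function(f)
      if (isTRUE(f$converged) && par %in% names(f$params))
        unname(f$params[par]) else NA_real_, numeric(1))
    v[is.finite(v)]
  }
  fams <- names(fits)
  if (length(fams) < 2) stop("need at least two families")
  rows <- list(); k <- 0L
  for (par in c("xmid", "scal")) {
    vals <- lapply(fits, stats_of, par = par)
    for (i in seq_len(length(fams) - 1)) for (j in seq(i + 1, length(fams))) {
      a <- vals[[i]]; b <- vals[[j]]
      if (length(a) < 2 || length(b) < 2)
        stop("need >= 2 converged replicate fits per family")
      tt <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                     error = function(e) NULL)
      k <- k + 1L
      rows[[k]] <- data.frame(
        family_A = fams[i], family_B = fams[j], statistic = par,
        t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
        df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
        p = if (is.null(tt)) NA_real_ else tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (par in unique(out$statistic)) {
    sel <- out$statistic == par
    out$q[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Estimate per-family half-maximal birthdates from a count table
#'
#' Builds cumulative curves, fits one sigmoid per family to the pooled
#' litter-level replicate points, and reports the half-max crossing as
#' the family's birthdate. Because the cumulative co-labeling at a pulse
#' time t counts every birth up to the end of that pulse's labeling
#' window, the fitted half-max on the pulse-time axis is shifted by
#' `edu_window` to land on the birthdate axis.
#'
#' @param counts A birth count table (see [colabel_fractions()]).
#' @param model Sigmoid family passed to [fit_sigmoid()].
#' @param edu_window Pulse labeling window length (days) used when the
#'   counts were collected; added to the fitted half-max. Use 0 to read
#'   the raw half-max on the pulse-time axis.
#' @return data.frame `family, halfmax, birthdate, converged`.
#' @export
estimate_birthdates <- function(counts, model = "4PL", edu_window = 0.5) {
  cc <- cumulative_curves(colabel_fractions(counts))$curves
  out <- lapply(split(cc, cc$family), function(d) {
    ok <- is.finite(d$cumulative_percent)
    f <- fit_sigmoid(d$timepoint[ok], d$cumulative_percent[ok], model = model)
    data.frame(family = d$family[1], halfmax = f$halfmax,
               birthdate = f$halfmax + edu_window, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit per-litter logistic curves for each family
#'
#' Convenience wrapper: builds cumulative curves from a count table and
#' fits one logistic sigmoid per litter replicate per family.
#'
#' @param counts A birth count table (see [colabel_fractions()]).
#' @return Named list family -> list of `sigmoid_fit`.
#' @export
replicate_logistic_fits <- function(counts) {
  cc <- cumulative_curves(colabel_fractions(counts))$curves
  out <- list()
  for (fam in unique(cc$family)) {
    d <- cc[cc$family == fam, ]
    out[[fam]] <- lapply(split(d, d$litter_id), function(r) {
      ok <- is.finite(r$cumulative_percent)
      tryCatch(fit_sigmoid(r$timepoint[ok], r$cumulative_percent[ok],
                           model = "logistic"),
               error = function(e)
                 structure(list(model = "logistic", params = NULL,
                                halfmax = NA_real_, rss = NA_real_,
                                r_squared = NA_real_, converged = FALSE),
                           class = "sigmoid_fit"))
    })
  }
  out
}
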