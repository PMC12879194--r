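#' Construct a composition (or ranked-expression) series
#'
#' @param label Type or gene name.
#' @param x Ordered grid (timepoints or expression ranks), strictly
#'   increasing, length >= 2.
#' @param v Values (proportions or expression), same length as `x`.
#' @param compositional If `TRUE`, values must lie in `[0, 1]`.
#' @return A `composition_series` list.
#' @export
composition_series <- function(label, x, v, compositional = FALSE) {
  if (length(x) < 2) stop("a series needs at least 2 points")
  if (length(x) != length(v)) stop("x and v must have equal length")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (compositional && (any(v < -1e-12) || any(v > 1 + 1e-12)))
    stop("compositional values must lie in [0, 1]")
  structure(list(label = label, x = as.numeric(x), v = as.numeric(v),
                 compositional = compositional),
            class = "composition_series")
}

#' Per-timepoint cell-type composition from labeled cells
#'
#' Builds a contingency table of cell types per timepoint and converts it
#' to fractions; at every timepoint the fractions across types sum to 1.
#' Empty timepoints are omitted with a warning.
#'
#' @param timepoint Per-cell timepoint (numeric).
#' @param type Per-cell type label.
#' @return Named list of `composition_series`, one per type, on the
#'   common timepoint grid.
#' @export
composition_timeseries <- function(timepoint, type) {
  stopifnot(length(timepoint) == length(type))
  keep <- is.finite(timepoint) & !is.na(type)
  timepoint <- timepoint[keep]; type <- type[keep]
  if (length(timepoint) == 0) stop("no cells")
  tab <- table(timepoint, type)
  n_t <- rowSums(tab)
  if (any(n_t == 0)) {
    warning("omitting ", sum(n_t == 0), " empty timepoint(s)")
    tab <- tab[n_t > 0, , drop = FALSE]
    n_t <- n_t[n_t > 0]
  }
  frac <- sweep(unclass(tab), 1, n_t, "/")
  tps <- as.numeric(rownames(tab))
  out <- lapply(colnames(tab), function(ty)
    composition_series(ty, tps, frac[, ty], compositional = TRUE))
  names(out) <- colnames(tab)
  out
}

series_values <- function(s) {
  if (inherits(s, "composition_series")) s$v else as.numeric(s)
}

#' Dynamic-time-warping distance between two curves
#'
#' Textbook dynamic program over local costs `d(i, j) = |a_i - b_j|` with
#' unit-weight steps (diagonal, vertical, horizontal) and no window; the
#' distance is the unnormalized accumulated cost at the end of both
#' series. A valid monotone contiguous warping path is returned.
#'
#' @param a,b `composition_series` objects or numeric vectors of length
#'   at least 2.
#' @return A `dtw_result` list: `distance`, `path` (two-column index
#'   matrix), `local_cost` ("abs_diff/unit_steps/unnormalized").
#' @export
dtw_distance <- function(a, b) {
  va <- series_values(a); vb <- series_values(b)
  if (length(va) < 2 || length(vb) < 2)
    stop("degenerate series: DTW needs length >= 2")
  n <- length(va); m <- length(vb)
  D <- matrix(Inf, n, m)
  cost <- abs(outer(va, vb, "-"))
  D[1, ] <- cumsum(cost[1, ])
  D[, 1] <- cumsum(cost[, 1])
  for (i in 2:n) for (j in 2:m)
    D[i, j] <- cost[i, j] + min(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
  # backtrack
  path <- list(c(n, m)); i <- n; j <- m
  while (i > 1 || j > 1) {
    if (i == 1) j <- j - 1
    else if (j == 1) i <- i - 1
    else {
      opts <- c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      step <- which.min(opts)
      if (step == 1) { i <- i - 1; j <- j - 1 }
      else if (step == 2) i <- i - 1
      else j <- j - 1
    }
    path[[length(path) + 1]] <- c(i, j)
  }
  path <- do.call(rbind, rev(path))
  colnames(path) <- c("a", "b")
  structure(list(distance = D[n, m], path = path,
                 local_cost = "abs_diff/unit_steps/unnormalized"),
            class = "dtw_result")
}

#' Two-sided DTW permutation test
#'
#' The observed DTW distance between two curves is compared with a null
#' distribution obtained by shuffling the value ordering of the curves
#' and recomputing the distance; `p = n_greater / n_perm`, the proportion
#' of permutations with a strictly greater distance. The test is
#' two-sided in interpretation: p near 0 means the curves are further
#' apart than chance, p near 1 means they are closer than chance
#' (typical for genuinely similar curve shapes). When the number of
#' distinct orderings is at most `n_perm`, all orderings are enumerated
#' exactly instead of sampled.
#'
#' @param a,b `composition_series` or numeric vectors (length >= 3).
#' @param n_perm Number of permutations (default 100000).
#' @param seed Integer RNG seed.
#' @param shuffle "both" (default) shuffles both curves independently;
#'   "b_only" shuffles only the second curve.
#' @return A `dtw_perm_test` list: `observed`, `n_perm`, `n_greater`,
#'   `p`, `exhaustive`, `shuffle`, `seed`.
#' @export
dtw_permutation_test <- function(a, b, n_perm = 100000L, seed = 1L,
                                 shuffle = c("both", "b_only")) {
  shuffle <- match.arg(shuffle)
  va <- series_values(a); vb <- series_values(b)
  if (length(va) < 3 || length(vb) < 3)
    stop("permutation test needs series of length >= 3")
  if (n_perm < 1) stop("n_perm must be >= 1")
  observed <- dtw_cost_cpp(va, vb)
  n <- length(va); m <- length(vb)
  total <- if (shuffle == "both") factorial(n) * factorial(m) else factorial(m)
  exhaustive <- is.finite(total) && total <= n_perm
  if (exhaustive) {
    if (shuffle == "both") {
      pa <- all_orderings(n); pb <- all_orderings(m)
      grid <- expand.grid(ia = seq_len(nrow(pa)), ib = seq_len(nrow(pb)))
      perm_a <- pa[grid$ia, , drop = FALSE]
      perm_b <- pb[grid$ib, , drop = FALSE]
    } else {
      perm_b <- all_orderings(m)
      perm_a <- matrix(rep(seq_len(n), nrow(perm_b)), ncol = n, byrow = TRUE)
    }
    n_used <- nrow(perm_a)
  } else {
    set.seed(as.integer(seed))
    n_used <- as.integer(n_perm)
    perm_b <- t(replicate(n_used, sample.int(m)))
    perm_a <- if (shuffle == "both") t(replicate(n_used, sample.int(n)))
              else matrix(rep(seq_len(n), n_used), ncol = n, byrow = TRUE)
  }
  null_d <- dtw_null_cpp(va, vb, perm_a, perm_b)
  n_greater <- sum(null_d > observed)
  structure(list(observed = observed, n_perm = n_used,
                 n_greater = n_greater, p = n_greater / n_used,
                 exhaustive = exhaustive, shuffle = shuffle,
                 seed = as.integer(seed), null = null_d),
            class = "dtw_perm_test")
}

# all orderings of 1..n as rows (n! x n); callers keep n small
all_orderings <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_orderings(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

#' Pairwise DTW distances and permutation p-values
#'
#' @param series Named list of `composition_series` (>= 2).
#' @param n_perm Permutations per pair.
#' @param seed Base seed; each unordered pair uses a deterministic
#'   sub-seed so single-pair calls reproduce matrix entries.
#' @param shuffle Passed to [dtw_permutation_test()].
#' @return List with symmetric `distance` and `p` matrices (diagonal
#'   distance 0, diagonal p `NA`).
#' @export
pairwise_dtw <- function(series, n_perm = 1000L, seed = 1L,
                         shuffle = "both") {
  K <- length(series)
  if (K < 2) stop("need at least two series")
  labs <- names(series)
  if (is.null(labs)) labs <- paste0("S", seq_len(K))
  D <- matrix(0, K, K, dimnames = list(labs, labs))
  P <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    r <- dtw_permutation_test(series[[i]], series[[j]], n_perm = n_perm,
                              seed = pair_subseed(seed, i, j),
                              shuffle = shuffle)
    D[i, j] <- D[j, i] <- r$observed
    P[i, j] <- P[j, i] <- r$p
  }
  list(distance = D, p = P)
}

#' Deterministic sub-seed for pair (i, j) of a pairwise DTW run
#'
#' @param seed Base seed.
#' @param i,j Pair indices.
#' @return Integer sub-seed below 2^31.
#' @export
pair_subseed <- function(seed, i, j) {
  as.integer((as.numeric(seed) + 7919 * i + 104729 * j) %% 2147483647)
}
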