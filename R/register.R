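#' @useDynLib chronotopy, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The ten anchor-landmark roles of a section
#'
#' Every section is annotated with exactly ten anatomical anchor points:
#' the dorsal-most extent of each dorsal horn, the lateral-most extent of
#' each dorsal horn, the base of the dorsal columns, the lateral-most and
#' ventral-most extents of each ventral horn, and the midline point where
#' the dorsal and ventral halves of the ventricular zone diverge (taken as
#' the dorsal-horn/ventral-horn boundary).
#'
#' @return Character vector of the 10 role names.
#' @export
anchor_roles <- function() {
  c("DH_dorsal_L", "DH_dorsal_R", "DH_lateral_L", "DH_lateral_R",
    "DC_base", "VH_lateral_L", "VH_lateral_R", "VH_ventral_L",
    "VH_ventral_R", "DV_junction")
}

#' Construct a landmark table for one section
#'
#' @param section_id Section identifier (length-1 character).
#' @param roles Character vector of anchor roles.
#' @param x,y Numeric coordinates, same length as `roles`.
#' @param frame Coordinate frame tag: "raw", "rotated" or "template".
#' @return A `section_landmarks` data.frame with columns
#'   `section_id, role, x, y` and a `frame` attribute.
#' @export
section_landmarks <- function(section_id, roles, x, y, frame = "raw") {
  stopifnot(length(roles) == length(x), length(x) == length(y))
  validate_anchor_roles(roles)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("anchor coordinates must be finite")
  out <- data.frame(section_id = as.character(section_id), role = roles,
                    x = as.numeric(x), y = as.numeric(y),
                    stringsAsFactors = FALSE)
  dv <- out[out$role == "DV_junction", c("x", "y")]
  dc <- out[out$role == "DC_base", c("x", "y")]
  if (isTRUE(all.equal(as.numeric(dv), as.numeric(dc))))
    stop("DV_junction and DC_base must be distinct points")
  attr(out, "frame") <- match.arg(frame, c("raw", "rotated", "template"))
  class(out) <- c("section_landmarks", "data.frame")
  out
}

validate_anchor_roles <- function(roles) {
  expected <- anchor_roles()
  if (length(roles) != 10L || !setequal(roles, expected) || anyDuplicated(roles))
    stop("a section requires exactly the 10 anchor roles, each once: ",
         paste(expected, collapse = ", "))
  invisible(TRUE)
}

#' Construct a cell table
#'
#' @param section_id,x,y Per-cell section id and coordinates.
#' @param type_label,family_label,edu_flag,genotype,segment_group Optional
#'   per-cell categorical annotations (recycled if length 1).
#' @param frame Coordinate frame tag.
#' @return A `cell_table` data.frame with a `frame` attribute.
#' @export
cell_table <- function(section_id, x, y, type_label = NA_character_,
                       family_label = NA_character_, edu_flag = NA,
                       genotype = NA_character_, segment_group = NA_character_,
                       frame = "raw") {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n > 0 && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("cell coordinates must be finite")
  out <- data.frame(section_id = rep_len(as.character(section_id), n),
                    x = as.numeric(x), y = as.numeric(y),
                    type_label = rep_len(as.character(type_label), n),
                    family_label = rep_len(as.character(family_label), n),
                    edu_flag = rep_len(edu_flag, n),
                    genotype = rep_len(as.character(genotype), n),
                    segment_group = rep_len(as.character(segment_group), n),
                    stringsAsFactors = FALSE)
  attr(out, "frame") <- match.arg(frame, c("raw", "rotated", "template"))
  class(out) <- c("cell_table", "data.frame")
  out
}

cell_frame <- function(cells) {
  f <- attr(cells, "frame")
  if (is.null(f)) "raw" else f
}

set_frame <- function(obj, frame) {
  attr(obj, "frame") <- frame
  obj
}

#' Idealized spinal cord template specification
#'
#' The canonical coordinate frame onto which all sections are registered.
#' The dorsal-most dorsal-horn anchors sit at y = +2000 and the
#' ventral-most ventral-horn anchors at y = -2000 arbitrary units; the
#' lateral dorsal-horn anchors sit at x = -2000/+2000. The intermediate
#' template positions (dorsal-column base, lateral dorsal horn, lateral
#' ventral horn) are arbitrary and may be overridden per segment group to
#' fit the ideal diagram.
#'
#' @param Y_D,Y_V Dorsal/ventral extreme template y (+2000 / -2000).
#' @param X_L,X_R Left/right lateral dorsal-horn template x (-2000 / +2000).
#' @param Y_DC Template y of the dorsal-column base.
#' @param Y_LAT Template y of the lateral dorsal-horn anchors.
#' @param Y_VLAT Template y of the lateral ventral-horn anchors.
#' @param X_VLAT Template |x| of the lateral ventral-horn anchors.
#' @return A `template_spec` list.
#' @export
template_spec <- function(Y_D = 2000, Y_V = -2000, X_L = -2000, X_R = 2000,
                          Y_DC = 1200, Y_LAT = 800, Y_VLAT = -800,
                          X_VLAT = 1600) {
  if (!(Y_D > Y_DC && Y_DC > Y_LAT && Y_LAT > 0 && 0 > Y_VLAT && Y_VLAT > Y_V))
    stop("template y positions must satisfy Y_D > Y_DC > Y_LAT > 0 > Y_VLAT > Y_V")
  if (!(X_L < 0 && 0 < X_R)) stop("template x positions must satisfy X_L < 0 < X_R")
  structure(list(Y_D = Y_D, Y_V = Y_V, X_L = X_L, X_R = X_R, Y_DC = Y_DC,
                 Y_LAT = Y_LAT, Y_VLAT = Y_VLAT, X_VLAT = abs(X_VLAT)),
            class = "template_spec")
}

anchor_xy <- function(anchors, role) {
  r <- anchors[anchors$role == role, , drop = FALSE]
  c(x = r$x[1], y = r$y[1])
}

#' Rotate a section so its midline is vertical
#'
#' Rigid transform (translation + rotation): the dorsal/ventral-horn
#' junction anchor is moved to the origin and all coordinates are rotated
#' so the dorsal-column base lies on the positive y axis, i.e. the two
#' midline anchors end up with identical x-coordinates and dorsal is up.
#'
#' @param cells A `cell_table` in the raw frame.
#' @param anchors The section's `section_landmarks` in the raw frame.
#' @return List with rotated `cells` and `anchors` (frame "rotated").
#' @export
rotate_to_midline <- function(cells, anchors) {
  if (cell_frame(cells) != "raw" || cell_frame(anchors) != "raw")
    stop("rotate_to_midline expects raw-frame inputs")
  dv <- anchor_xy(anchors, "DV_junction")
  dc <- anchor_xy(anchors, "DC_base")
  b <- dc - dv
  r <- sqrt(sum(b^2))
  if (r < .Machine$double.eps^0.5)
    stop("degenerate geometry: DV_junction and DC_base coincide")
  # rotation taking (b_x, b_y) onto (0, r)
  ct <- b["y"] / r
  st <- b["x"] / r
  rot <- function(x, y) {
    x0 <- x - dv["x"]; y0 <- y - dv["y"]
    list(x = as.numeric(ct * x0 - st * y0), y = as.numeric(st * x0 + ct * y0))
  }
  pc <- rot(cells$x, cells$y)
  pa <- rot(anchors$x, anchors$y)
  cells$x <- pc$x; cells$y <- pc$y
  anchors$x <- pa$x; anchors$y <- pa$y
  list(cells = set_frame(cells, "rotated"),
       anchors = set_frame(anchors, "rotated"))
}

# Control pairs for the piecewise-linear y warp of one hemisection.
# side: "L" or "R". Returns rotated-frame y (ascending) and template y.
warp_controls <- function(anchors, spec, side) {
  g <- function(role) anchor_xy(anchors, role)["y"]
  src <- c(g(paste0("VH_ventral_", side)), g(paste0("VH_lateral_", side)),
           g("DV_junction"), g(paste0("DH_lateral_", side)), g("DC_base"),
           g(paste0("DH_dorsal_", side)))
  dst <- c(spec$Y_V, spec$Y_VLAT, 0, spec$Y_LAT, spec$Y_DC, spec$Y_D)
  names(src) <- names(dst) <- c(paste0("VH_ventral_", side),
                                paste0("VH_lateral_", side), "DV_junction",
                                paste0("DH_lateral_", side), "DC_base",
                                paste0("DH_dorsal_", side))
  if (any(diff(src) <= 0)) {
    bad <- which(diff(src) <= 0)[1]
    stop(sprintf("landmark order violated between anchors '%s' and '%s' (%s hemisection)",
                 names(src)[bad], names(src)[bad + 1], side))
  }
  list(src = unname(src), dst = unname(dst), names = names(src))
}

# Monotone piecewise-linear map through control pairs; terminal segments
# extended linearly beyond the outermost controls.
pw_linear <- function(y, src, dst) {
  n <- length(src)
  out <- stats::approx(src, dst, xout = y, rule = 2)$y
  lo <- y < src[1]
  hi <- y > src[n]
  if (any(lo)) {
    s <- (dst[2] - dst[1]) / (src[2] - src[1])
    out[lo] <- dst[1] + s * (y[lo] - src[1])
  }
  if (any(hi)) {
    s <- (dst[n] - dst[n - 1]) / (src[n] - src[n - 1])
    out[hi] <- dst[n] + s * (y[hi] - src[n])
  }
  out
}

# x scale for one hemisection, blended linearly in rotated y between the
# dorsal-horn-lateral and ventral-horn-lateral scales, clamped outside.
x_scale <- function(y, anchors, spec, side) {
  dh <- anchor_xy(anchors, paste0("DH_lateral_", side))
  vh <- anchor_xy(anchors, paste0("VH_lateral_", side))
  x_t_dh <- if (side == "L") spec$X_L else spec$X_R
  x_t_vh <- if (side == "L") -spec$X_VLAT else spec$X_VLAT
  if (abs(dh["x"]) < .Machine$double.eps^0.5 ||
      abs(vh["x"]) < .Machine$double.eps^0.5)
    stop("degenerate geometry: lateral anchor on the midline")
  s_dh <- x_t_dh / dh["x"]
  s_vh <- x_t_vh / vh["x"]
  w <- (y - vh["y"]) / (dh["y"] - vh["y"])
  w <- pmin(pmax(w, 0), 1)
  as.numeric(s_vh + w * (s_dh - s_vh))
}

warp_xy_side <- function(x, y, anchors, spec, side) {
  ctl <- warp_controls(anchors, spec, side)
  list(x = x * x_scale(y, anchors, spec, side),
       y = pw_linear(y, ctl$src, ctl$dst))
}

#' Stretch a rotated section onto the idealized template
#'
#' The y-coordinate of each cell is mapped by a monotone piecewise-linear
#' function through the six control pairs of its hemisection (ventral-horn
#' ventral, ventral-horn lateral, dorsoventral junction, dorsal-horn
#' lateral, dorsal-column base, dorsal-horn dorsal). The x-coordinate is
#' scaled per hemisection so the lateral dorsal-horn anchors land at
#' X_L/X_R, with the scale blended linearly in y between the dorsal-horn
#' and ventral-horn lateral scales (clamped to the nearer scale outside
#' that range). Cells exactly on the midline (x = 0) use the mean of the
#' left/right hemisection maps.
#'
#' @param cells Rotated-frame `cell_table`.
#' @param anchors Rotated-frame `section_landmarks`.
#' @param spec A [template_spec()].
#' @return List with template-frame `cells` and `anchors`.
#' @export
warp_to_template <- function(cells, anchors, spec = template_spec()) {
  if (cell_frame(cells) != "rotated" || cell_frame(anchors) != "rotated")
    stop("warp_to_template expects rotated-frame inputs")
  warp_tbl <- function(tbl) {
    x <- tbl$x; y <- tbl$y
    xo <- numeric(length(x)); yo <- numeric(length(y))
    left <- x < 0; right <- x > 0; mid <- x == 0
    if (any(left)) {
      p <- warp_xy_side(x[left], y[left], anchors, spec, "L")
      xo[left] <- p$x; yo[left] <- p$y
    }
    if (any(right)) {
      p <- warp_xy_side(x[right], y[right], anchors, spec, "R")
      xo[right] <- p$x; yo[right] <- p$y
    }
    if (any(mid)) {
      pl <- warp_xy_side(x[mid], y[mid], anchors, spec, "L")
      pr <- warp_xy_side(x[mid], y[mid], anchors, spec, "R")
      xo[mid] <- (pl$x + pr$x) / 2
      yo[mid] <- (pl$y + pr$y) / 2
    }
    tbl$x <- xo; tbl$y <- yo
    tbl
  }
  list(cells = set_frame(warp_tbl(cells), "template"),
       anchors = set_frame(warp_tbl(anchors), "template"))
}

#' Normalize a raw section onto the template
#'
#' Composition of [rotate_to_midline()] and [warp_to_template()]: section
#' coordinates are rotated so the midline anchors share an x-coordinate,
#' then each hemisection is stretched to fit the ideal spinal cord
#' diagram.
#'
#' @inheritParams warp_to_template
#' @param cells Raw-frame `cell_table`.
#' @param anchors Raw-frame `section_landmarks`.
#' @return List with template-frame `cells` and `anchors`.
#' @export
normalize_section <- function(cells, anchors, spec = template_spec()) {
  r <- rotate_to_midline(cells, anchors)
  warp_to_template(r$cells, r$anchors, spec)
}

#' Mirror two cell populations onto opposite hemisections
#'
#' For genotype-comparison overlays the reference population is reflected
#' onto the left hemisection (x <= 0) and the alternative population onto
#' the right (x >= 0); y is unchanged and a provenance label is retained.
#'
#' @param ref_cells,alt_cells Template-frame `cell_table`s.
#' @param ref_label,alt_label Provenance labels stored in `overlay_group`.
#' @return Combined template-frame `cell_table` with an `overlay_group`
#'   column.
#' @export
mirror_overlay <- function(ref_cells, alt_cells, ref_label = "ref",
                           alt_label = "alt") {
  if (cell_frame(ref_cells) != "template" || cell_frame(alt_cells) != "template")
    stop("frame mismatch: mirror_overlay expects both tables in the template frame")
  ref_cells$x <- -abs(ref_cells$x)
  alt_cells$x <- abs(alt_cells$x)
  ref_cells$overlay_group <- ref_label
  alt_cells$overlay_group <- alt_label
  out <- rbind(ref_cells, alt_cells)
  set_frame(out, "template")
}

#' Downsample a reference population to match an alternative total
#'
#' Each cell type's count is multiplied by the ratio
#' r = alt_total / ref_total and rounded half-to-even; that many cells of
#' the type are sampled without replacement. Used to match wild-type cell
#' numbers to a null genotype before mirrored overlays.
#'
#' @param ref_cells A `cell_table`.
#' @param alt_total Total cell count of the population to match (> 0).
#' @param seed Integer seed for the sampling.
#' @param type_col Column defining types (default "type_label").
#' @return Downsampled `cell_table` (same frame as input).
#' @export
downsample_matched <- function(ref_cells, alt_total, seed = 1L,
                               type_col = "type_label") {
  stopifnot(alt_total > 0)
  n_ref <- nrow(ref_cells)
  r <- alt_total / n_ref
  if (r > 1) {
    warning("alt_total exceeds reference total; cannot upsample, returning input")
    return(ref_cells)
  }
  frame <- cell_frame(ref_cells)
  set.seed(as.integer(seed))
  keep <- unlist(lapply(split(seq_len(n_ref), ref_cells[[type_col]]),
                        function(idx) {
                          k <- round(r * length(idx))  # round-half-to-even
                          sort(sample(idx, k))
                        }), use.names = FALSE)
  out <- ref_cells[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  set_frame(out, frame)
}
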