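# Sector/quadrant geometry on labelled cross-section rasters.
#
# Coordinate convention: image row/column, origin top-left, 0-based; a pixel
# at 0-based (row i, col j) has its centre at continuous (x = j + 0.5,
# y = i + 0.5). Polygons are matrices with columns x, y in these continuous
# coordinates; all reported areas are in physical units (pixel_size^2).

# ---- polygon / polyline primitives ----------------------------------------

polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_area <- function(poly) abs(polygon_area_signed(poly))

# Even-odd ray casting, vectorised over query points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polyline_lengths <- function(pl) {
  d <- diff(pl)
  sqrt(rowSums(d^2))
}

polyline_length <- function(pl) sum(polyline_lengths(pl))

# Point at arc-length fraction t in [0, 1] along a polyline.
point_at_fraction <- function(pl, t) {
  if (nrow(pl) == 1L) return(pl[1, ])
  seg <- polyline_lengths(pl)
  cum <- c(0, cumsum(seg))
  target <- t * cum[length(cum)]
  i <- findInterval(target, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pl) - 1L)
  if (seg[i] == 0) return(pl[i, ])
  u <- (target - cum[i]) / seg[i]
  pl[i, ] + u * (pl[i + 1L, ] - pl[i, ])
}

# Sub-polyline between arc-length fractions t0 < t1, reusing the original
# vertices strictly between the two split points so that concatenated
# portions rebuild the original polyline exactly.
sub_polyline <- function(pl, t0, t1) {
  seg <- polyline_lengths(pl)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  a <- t0 * total; b <- t1 * total
  keep <- which(cum > a + 1e-12 & cum < b - 1e-12)
  rbind(point_at_fraction(pl, t0),
        pl[keep, , drop = FALSE],
        point_at_fraction(pl, t1))
}

# Resample a polyline at given arc-length fractions.
resample_polyline <- function(pl, fracs) {
  t(vapply(fracs, function(t) point_at_fraction(pl, t), numeric(2)))
}

# ---- label image -----------------------------------------------------------

RPP_CLASSES <- c(background = 0L, primary_bone = 1L, vascular = 2L,
                 medullary = 3L, remodelled = 4L, ocl = 5L, el = 6L)

#' Labelled cross-section raster
#'
#' A class-coded raster of a mid-diaphyseal cross-section with a physical
#' pixel size. Class codes: 0 background, 1 primary bone, 2 primary
#' vascular space (including secondarily enlarged primary canals with no
#' secondary deposition), 3 medullary cavity, 4 secondarily remodelled bone
#' (secondary osteons, CCCB), 5 outer circumferential layer (OCL),
#' 6 endosteal lamellar layer (EL).
#'
#' @param raster Integer matrix of class codes (rows = image rows).
#' @param pixel_size Physical side length of one pixel (> 0).
#' @return A `label_image`.
#' @export
label_image <- function(raster, pixel_size = 1) {
  raster <- as.matrix(raster)
  storage.mode(raster) <- "integer"
  if (!all(raster %in% RPP_CLASSES))
    stop("raster contains values outside the class mapping 0..6")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(raster = raster, pixel_size = pixel_size),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("label_image: %d x %d px, pixel size %g\n",
              nrow(x$raster), ncol(x$raster), x$pixel_size))
  tab <- table(factor(x$raster, levels = RPP_CLASSES,
                      labels = names(RPP_CLASSES)))
  print(tab)
  invisible(x)
}

# ---- sector specification --------------------------------------------------

#' Sector specification
#'
#' A measurement sector bounded by two borders following the curvature of
#' the inner and outer posthatching-cortex surfaces and two roughly radial
#' sides. Radial sides are oriented inner -> outer; the inner and outer
#' borders run from side 1 to side 2 (the constructor re-orients its inputs
#' as needed).
#'
#' @param inner,outer Polylines (n x 2 matrices, columns x, y) following the
#'   inner and outer cortical surfaces.
#' @param side1,side2 Radial side polylines.
#' @param sector_index Integer index of the sector.
#' @return A `sector_spec`.
#' @export
sector_spec <- function(inner, outer, side1, side2, sector_index = 1L) {
  as_pl <- function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 2L) stop("polylines must be n x 2, n >= 2")
    storage.mode(p) <- "double"
    unname(p)
  }
  inner <- as_pl(inner); outer <- as_pl(outer)
  side1 <- as_pl(side1); side2 <- as_pl(side2)
  first <- function(p) p[1, ]; last <- function(p) p[nrow(p), ]
  rev_pl <- function(p) p[nrow(p):1, , drop = FALSE]
  d2 <- function(a, b) sum((a - b)^2)
  # orient sides inner -> outer
  if (d2(first(side1), first(inner)) + d2(first(side1), last(inner)) >
      d2(last(side1), first(inner)) + d2(last(side1), last(inner)))
    side1 <- rev_pl(side1)
  if (d2(first(side2), first(inner)) + d2(first(side2), last(inner)) >
      d2(last(side2), first(inner)) + d2(last(side2), last(inner)))
    side2 <- rev_pl(side2)
  # orient boundaries side1 -> side2
  if (d2(first(inner), first(side1)) > d2(last(inner), first(side1)))
    inner <- rev_pl(inner)
  if (d2(first(outer), last(side1)) > d2(last(outer), last(side1)))
    outer <- rev_pl(outer)
  spec <- structure(list(sector_index = as.integer(sector_index),
                         inner = inner, outer = outer,
                         side1 = side1, side2 = side2),
                    class = "sector_spec")
  poly <- sector_polygon(spec)
  if (polygon_area(poly) <= 0 || polygon_self_intersects(poly))
    stop("sector boundaries do not close into a simple polygon")
  spec
}

sector_polygon <- function(spec) {
  rbind(spec$side1,
        spec$outer,
        spec$side2[nrow(spec$side2):1, , drop = FALSE],
        spec$inner[nrow(spec$inner):1, , drop = FALSE])
}

# Crude O(n^2) segment-intersection check, adequate for audit-sized polygons.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n > 400L) return(FALSE)  # skip quadratic check on dense polygons
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
      (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1L || (i == 1L && j == n) || (i == n && j == 1L)) next
      if (j < i) next
      a1 <- poly[i, ]; a2 <- poly[if (i == n) 1L else i + 1L, ]
      b1 <- poly[j, ]; b2 <- poly[if (j == n) 1L else j + 1L, ]
      if (seg_int(a1, a2, b1, b2)) return(TRUE)
    }
  }
  FALSE
}

# ---- quadrant construction -------------------------------------------------

#' Divide a sector into four radial quadrants
#'
#' Splits each radial side at arc-length fractions 1/4, 2/4, 3/4 and joins
#' corresponding split points by separators that follow the section
#' circumference. Separators are blended curves: at fraction t the
#' separator interpolates, point by point in arc-length parameterisation,
#' between the inner and the outer boundary (`separator = "blend"`), or is
#' a straight chord (`"chord"`). Quadrant a is adjacent to the inner
#' boundary (the oldest cortex), d to the outer.
#'
#' @param sector A `sector_spec`.
#' @param n_quadrants Number of radial quadrants (default 4).
#' @param separator `"blend"` or `"chord"`.
#' @param n_sep_points Sample points per blended separator.
#' @return List of `quadrant_geometry` objects ordered a (inner) to d
#'   (outer), each with elements `sector_index`, `quadrant_index`,
#'   `polygon`, `area` (pixel units; scale by pixel_size^2 for physical).
#' @export
build_quadrants <- function(sector, n_quadrants = 4L,
                            separator = c("blend", "chord"),
                            n_sep_points = 41L) {
  separator <- match.arg(separator)
  nq <- as.integer(n_quadrants)
  if (nq < 2L) stop("n_quadrants must be >= 2")
  fr <- seq(0, 1, length.out = nq + 1L)
  sgrid <- seq(0, 1, length.out = n_sep_points)
  inner_s <- resample_polyline(sector$inner, sgrid)
  outer_s <- resample_polyline(sector$outer, sgrid)
  seps <- vector("list", nq + 1L)
  seps[[1L]] <- sector$inner
  seps[[nq + 1L]] <- sector$outer
  for (k in seq_len(nq - 1L)) {
    t <- fr[k + 1L]
    mid <- if (separator == "blend") {
      (1 - t) * inner_s + t * outer_s
    } else {
      rbind(point_at_fraction(sector$side1, t),
            point_at_fraction(sector$side2, t))
    }
    # force endpoints onto the actual side split points so boundaries close
    mid[1L, ] <- point_at_fraction(sector$side1, t)
    mid[nrow(mid), ] <- point_at_fraction(sector$side2, t)
    seps[[k + 1L]] <- mid
  }
  labels <- letters[seq_len(nq)]
  out <- vector("list", nq)
  for (k in seq_len(nq)) {
    s1 <- sub_polyline(sector$side1, fr[k], fr[k + 1L])
    s2 <- sub_polyline(sector$side2, fr[k], fr[k + 1L])
    lower <- seps[[k]]
    upper <- seps[[k + 1L]]
    poly <- rbind(s1,
                  upper,
                  s2[nrow(s2):1, , drop = FALSE],
                  lower[nrow(lower):1, , drop = FALSE])
    out[[k]] <- structure(list(sector_index = sector$sector_index,
                               quadrant_index = labels[k],
                               polygon = poly,
                               area = polygon_area(poly)),
                          class = "quadrant_geometry")
  }
  out
}

# ---- measurement -----------------------------------------------------------

#' Measure one quadrant on a label image
#'
#' Integrates class areas over pixels whose centres fall inside the
#' quadrant polygon. Vascular area is class 2; excluded area is remodelled
#' bone (class 4) plus, when `exclude_layers` is TRUE, OCL (5) and EL (6).
#' Non-cortex pixels (background, medullary cavity) are always removed from
#' the porosity denominator. Porosity is set missing when the excluded plus
#' non-cortex fraction of the quadrant exceeds `missing_threshold`,
#' implementing the rule that quadrants whose primary cortex is mostly or
#' wholly obliterated carry no porosity value.
#'
#' @param image A `label_image`.
#' @param quadrant A `quadrant_geometry`.
#' @param exclude_layers Exclude OCL/EL from the denominator (default TRUE).
#' @param missing_threshold Fraction of the quadrant above which porosity is
#'   reported missing (default 0.5).
#' @return A `quadrant_measure` list: `quadrant_index`, `quadrant_area`,
#'   `vascular_area`, `excluded_area`, `porosity`, `excluded_classes`
#'   (which exclusion classes were present). Areas in physical units.
#' @export
measure_quadrant <- function(image, quadrant, exclude_layers = TRUE,
                             missing_threshold = 0.5) {
  stopifnot(inherits(image, "label_image"),
            inherits(quadrant, "quadrant_geometry"))
  poly <- quadrant$polygon
  nr <- nrow(image$raster); nc <- ncol(image$raster)
  if (min(poly[, 1]) < 0 || min(poly[, 2]) < 0 ||
      max(poly[, 1]) > nc || max(poly[, 2]) > nr)
    stop("quadrant polygon extends outside the raster")
  j0 <- max(1L, floor(min(poly[, 1]) + 0.5))
  j1 <- min(nc, ceiling(max(poly[, 1]) + 0.5))
  i0 <- max(1L, floor(min(poly[, 2]) + 0.5))
  i1 <- min(nr, ceiling(max(poly[, 2]) + 0.5))
  jj <- j0:j1; ii <- i0:i1
  px <- rep(jj - 0.5, each = length(ii))
  py <- rep(ii - 0.5, times = length(jj))
  inside <- points_in_polygon(px, py, poly)
  if (!any(inside))
    stop("quadrant polygon contains no pixel centres")
  cls <- image$raster[cbind(rep(ii, times = length(jj))[inside],
                            rep(jj, each = length(ii))[inside])]
  a <- image$pixel_size^2
  n_in <- sum(inside)
  vasc <- sum(cls == 2L) * a
  excl_classes <- if (exclude_layers) c(4L, 5L, 6L) else 4L
  excl <- sum(cls %in% excl_classes) * a
  noncortex <- sum(cls %in% c(0L, 3L)) * a
  qarea <- n_in * a
  denom <- qarea - excl - noncortex
  frac_gone <- (excl + noncortex) / qarea
  porosity <- if (frac_gone > missing_threshold || denom <= 0) {
    NA_real_
  } else {
    quadrant_porosity(vasc, qarea, excl + noncortex)
  }
  structure(list(quadrant_index = quadrant$quadrant_index,
                 quadrant_area = qarea,
                 vascular_area = vasc,
                 excluded_area = excl,
                 noncortex_area = noncortex,
                 porosity = porosity,
                 excluded_classes = sort(unique(cls[cls %in% c(4L, 5L, 6L)]))),
            class = "quadrant_measure")
}

#' Measure a full section
#'
#' Builds quadrants for every sector, measures each, and assembles
#' per-sector porosity profiles, the element's mean RPP, and OCL/EL
#' relative thicknesses pooled over all measured sectors.
#'
#' @param image A `label_image`.
#' @param sectors List of `sector_spec`s.
#' @param ... Passed to [measure_quadrant()] and [build_quadrants()].
#' @return List with `profiles` (list of length-4 numeric vectors),
#'   `mean_rpp` (an `rpp_trajectory`), `layers` (data.frame: layer,
#'   relative_area_percent), and `measures` (nested quadrant measures).
#' @export
measure_section <- function(image, sectors, ...) {
  if (length(sectors) == 0) stop("at least one sector is required")
  dots <- list(...)
  bq_args <- dots[names(dots) %in% c("n_quadrants", "separator", "n_sep_points")]
  mq_args <- dots[names(dots) %in% c("exclude_layers", "missing_threshold")]
  profiles <- list(); measures <- list()
  cortex_px <- 0; ocl_px <- 0; el_px <- 0
  for (s in seq_along(sectors)) {
    quads <- do.call(build_quadrants, c(list(sectors[[s]]), bq_args))
    qm <- lapply(quads, function(q)
      do.call(measure_quadrant, c(list(image, q), mq_args)))
    profiles[[s]] <- vapply(qm, function(m) m$porosity, numeric(1))
    measures[[s]] <- qm
    # pooled layer accounting over the sector polygon
    sec_cls <- section_classes_in_polygon(image, sector_polygon(sectors[[s]]))
    cortex_px <- cortex_px + sum(sec_cls %in% c(1L, 2L, 4L, 5L, 6L))
    ocl_px <- ocl_px + sum(sec_cls == 5L)
    el_px <- el_px + sum(sec_cls == 6L)
  }
  layers <- data.frame(
    layer = c("OCL", "EL"),
    relative_area_percent = if (cortex_px > 0)
      c(relative_layer_thickness(ocl_px, cortex_px),
        relative_layer_thickness(el_px, cortex_px))
    else c(NA_real_, NA_real_))
  list(profiles = profiles,
       mean_rpp = mean_rpp(profiles),
       layers = layers,
       measures = measures)
}

section_classes_in_polygon <- function(image, poly) {
  nr <- nrow(image$raster); nc <- ncol(image$raster)
  j0 <- max(1L, floor(min(poly[, 1]) + 0.5))
  j1 <- min(nc, ceiling(max(poly[, 1]) + 0.5))
  i0 <- max(1L, floor(min(poly[, 2]) + 0.5))
  i1 <- min(nr, ceiling(max(poly[, 2]) + 0.5))
  jj <- j0:j1; ii <- i0:i1
  px <- rep(jj - 0.5, each = length(ii))
  py <- rep(ii - 0.5, times = length(jj))
  inside <- points_in_polygon(px, py, poly)
  image$raster[cbind(rep(ii, times = length(jj))[inside],
                     rep(jj, each = length(ii))[inside])]
}

#' Place measurement sectors automatically
#'
#' Traces sectors centred at the requested angular positions: radial sides
#' run along rays from the medullary-cavity centroid, and the inner/outer
#' borders follow the cortex boundary sampled at fine angular steps. A
#' convenience for synthetic and well-segmented sections; sectors on real
#' material are usually drawn by the analyst.
#'
#' @param image A `label_image` containing a closed cortex ring around a
#'   medullary cavity.
#' @param n_sectors Number of sectors.
#' @param angular_positions Centre angles in degrees (default equally
#'   spaced starting at 0; 0 = +x axis, counterclockwise in image
#'   coordinates).
#' @param angular_width Sector angular width in degrees (default 60).
#' @param angle_step Angular sampling step for the traced borders (degrees).
#' @return List of `sector_spec`s.
#' @export
place_sectors_auto <- function(image, n_sectors = 3L,
                               angular_positions = NULL,
                               angular_width = 60,
                               angle_step = 2) {
  stopifnot(inherits(image, "label_image"))
  if (is.null(angular_positions))
    angular_positions <- seq(0, 360, length.out = n_sectors + 1L)[seq_len(n_sectors)]
  if (length(angular_positions) != n_sectors)
    stop("angular_positions must have length n_sectors")
  ras <- image$raster
  cortex <- which(matrix(ras %in% c(1L, 2L, 4L, 5L, 6L), nrow(ras)),
                  arr.ind = TRUE)
  if (nrow(cortex) == 0) stop("no cortex pixels in image")
  cavity <- which(ras == 3L, arr.ind = TRUE)
  centre <- if (nrow(cavity) > 0) {
    c(mean(cavity[, 2]) - 0.5, mean(cavity[, 1]) - 0.5)
  } else {
    c(mean(cortex[, 2]) - 0.5, mean(cortex[, 1]) - 0.5)
  }
  rmax <- sqrt(max((cortex[, 2] - 0.5 - centre[1])^2 +
                     (cortex[, 1] - 0.5 - centre[2])^2)) + 2
  trace_ray <- function(theta) {
    rad <- theta * pi / 180
    dx <- cos(rad); dy <- -sin(rad)  # image y grows downward
    rr <- seq(0.5, rmax, by = 0.5)
    xs <- centre[1] + rr * dx; ys <- centre[2] + rr * dy
    jj <- floor(xs) + 1L; ii <- floor(ys) + 1L
    ok <- jj >= 1L & jj <= ncol(ras) & ii >= 1L & ii <= nrow(ras)
    hit <- rep(FALSE, length(rr))
    hit[ok] <- ras[cbind(ii[ok], jj[ok])] %in% c(1L, 2L, 4L, 5L, 6L)
    if (!any(hit))
      stop(sprintf("cortex ring not closed: no cortex along ray at %.1f deg",
                   theta))
    r_in <- rr[which(hit)[1L]]
    r_out <- rr[max(which(hit))]
    list(inner = c(centre[1] + r_in * dx, centre[2] + r_in * dy),
         outer = c(centre[1] + r_out * dx, centre[2] + r_out * dy))
  }
  out <- vector("list", n_sectors)
  for (s in seq_len(n_sectors)) {
    th0 <- angular_positions[s] - angular_width / 2
    th1 <- angular_positions[s] + angular_width / 2
    thetas <- seq(th0, th1, by = angle_step)
    if (thetas[length(thetas)] != th1) thetas <- c(thetas, th1)
    pts <- lapply(thetas, trace_ray)
    inner <- do.call(rbind, lapply(pts, `[[`, "inner"))
    outer <- do.call(rbind, lapply(pts, `[[`, "outer"))
    side1 <- rbind(pts[[1L]]$inner, pts[[1L]]$outer)
    side2 <- rbind(pts[[length(pts)]]$inner, pts[[length(pts)]]$outer)
    out[[s]] <- sector_spec(inner = inner, outer = outer,
                            side1 = side1, side2 = side2, sector_index = s)
  }
  out
}
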