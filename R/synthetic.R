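# Seeded synthetic fixtures with analytic ground truth: label-image
# cross-sections with known radial porosity structure, and RPP datasets with
# known group structure.

#' Blueprint for a synthetic cross-section
#'
#' Describes a circular mid-shaft cross-section: medullary cavity, cortex
#' ring, a radial porosity law, pore-size distribution, optional remodelled
#' patches and OCL/EL rims.
#'
#' @param cavity_radius Medullary cavity radius in pixels (> 0).
#' @param cortex_thickness Cortex thickness in pixels (> 0).
#' @param radial_porosity_function Function mapping relative cortical depth
#'   in [0, 1] (0 = inner surface) to a target pore area fraction in
#'   [0, 0.72].
#' @param pore_mean,pore_sd Mean and sd of pore radii in pixels.
#' @param remodel_patches List of patches, each
#'   `list(angle = c(deg0, deg1), depth = c(d0, d1))`, painted as
#'   remodelled bone (class 4).
#' @param ocl_fraction,el_fraction Relative thicknesses in [0, 1] of the
#'   outer circumferential and endosteal lamellar rims.
#' @param margin Background margin in pixels.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `section_blueprint`.
#' @export
section_blueprint <- function(cavity_radius = 80,
                              cortex_thickness = 120,
                              radial_porosity_function = function(d) 0.40 - 0.30 * d,
                              pore_mean = 2.2, pore_sd = 0.55,
                              remodel_patches = list(),
                              ocl_fraction = 0, el_fraction = 0,
                              margin = 10, seed = 1L) {
  if (cavity_radius <= 0 || cortex_thickness <= 0)
    stop("cavity_radius and cortex_thickness must be positive")
  if (ocl_fraction < 0 || ocl_fraction > 1 || el_fraction < 0 || el_fraction > 1)
    stop("layer fractions must lie in [0, 1]")
  if (ocl_fraction + el_fraction >= 1)
    stop("OCL and EL rims must leave some primary cortex")
  dg <- seq(0, 1, length.out = 101)
  fv <- vapply(dg, radial_porosity_function, numeric(1))
  if (any(fv < 0 | fv > 0.9)) stop("target pore fraction must lie in [0, 0.9]")
  if (max(fv) > 0.72)
    stop("target pore fraction above 0.72 is infeasible for hard-core packing")
  structure(list(cavity_radius = cavity_radius,
                 cortex_thickness = cortex_thickness,
                 radial_porosity_function = radial_porosity_function,
                 pore_mean = pore_mean, pore_sd = pore_sd,
                 remodel_patches = remodel_patches,
                 ocl_fraction = ocl_fraction, el_fraction = el_fraction,
                 margin = margin, seed = as.integer(seed)),
            class = "section_blueprint")
}

#' Generate a synthetic labelled cross-section
#'
#' Builds the class raster for a blueprint. Pores are non-overlapping disks
#' placed on a jittered polar lattice whose local spacing is solved from
#' the target pore fraction at that depth; per-row disk areas are rescaled
#' to hit the target fraction exactly, so the blueprint's porosity law is
#' the analytic ground truth. The jitter amplitude shrinks to zero as the
#' target fraction approaches the lattice packing limit, preserving the
#' hard-core (non-overlap) property at all feasible fractions.
#'
#' @param blueprint A `section_blueprint`.
#' @return List with `image` (a [label_image()]), `ground_truth` (data.frame
#'   of depth bins with target pore fractions), and `blueprint`.
#' @export
generate_section <- function(blueprint) {
  stopifnot(inherits(blueprint, "section_blueprint"))
  set.seed(blueprint$seed)
  bp <- blueprint
  R0 <- bp$cavity_radius
  Tc <- bp$cortex_thickness
  R1 <- R0 + Tc
  n <- 2L * ceiling(R1 + bp$margin)
  cx <- n / 2; cy <- n / 2
  xs <- (seq_len(n) - 0.5) - cx
  ys <- (seq_len(n) - 0.5) - cy
  # raster[i, j]: rows are y, columns x
  rr <- sqrt(outer(ys^2, xs^2, "+"))
  ras <- matrix(0L, n, n)
  ras[rr < R0] <- 3L
  in_cortex <- rr >= R0 & rr < R1
  ras[in_cortex] <- 1L
  depth <- (rr - R0) / Tc
  if (bp$el_fraction > 0)
    ras[in_cortex & depth < bp$el_fraction] <- 6L
  if (bp$ocl_fraction > 0)
    ras[in_cortex & depth > 1 - bp$ocl_fraction] <- 5L

  # primary zone radial band
  zlo <- R0 + bp$el_fraction * Tc
  zhi <- R1 - bp$ocl_fraction * Tc

  f_at <- function(r) bp$radial_porosity_function((r - R0) / Tc)
  pores_x <- numeric(0); pores_y <- numeric(0); pores_r <- numeric(0)
  # stratify pore rows at quarter-depth breaks so no row straddles a
  # quadrant band; pore area then integrates correctly per quadrant
  breaks <- sort(unique(pmin(pmax(c(zlo, R0 + Tc * c(0.25, 0.5, 0.75), zhi),
                                  zlo), zhi)))
  for (seg in seq_len(length(breaks) - 1L)) {
  r <- breaks[seg]
  seg_hi <- breaks[seg + 1L]
  while (r < seg_hi - 1e-9) {
    f <- f_at(min(r + bp$pore_mean, seg_hi))
    if (f <= 1e-4) { r <- r + 2 * bp$pore_mean; next }
    abar <- pi * (bp$pore_mean^2 + bp$pore_sd^2)
    s <- sqrt(abar / f)
    s <- min(s, seg_hi - r)      # last row: shrink slab to fit the band
    if (s < 2 * 0.2 * bp$pore_mean) break
    rmid <- r + s / 2
    # area target from the slab-averaged law, so discontinuities that fall
    # inside a row transfer the right amount of pore area
    f <- mean(vapply(seq(r, r + s, length.out = 13), f_at, numeric(1)))
    if (f > 1e-4) {
      npore <- max(1L, round(2 * pi * rmid / s))
      ang <- (seq_len(npore) - 1) / npore * 2 * pi + stats::runif(1, 0, 2 * pi)
      radii <- stats::rnorm(npore, bp$pore_mean, bp$pore_sd)
      radii <- pmax(radii, 0.2 * bp$pore_mean)
      # rescale disk areas so the row hits its target fraction exactly
      target_area <- f * 2 * pi * rmid * s
      radii <- radii * sqrt(target_area / sum(pi * radii^2))
      cell <- min(s, 2 * pi * rmid / npore)
      rcap <- 0.495 * cell
      radii <- pmin(radii, rcap)
      # second pass: push lost area back onto uncapped pores
      deficit <- target_area - sum(pi * radii^2)
      if (deficit > 0) {
        free <- radii < rcap - 1e-9
        if (any(free)) {
          radii[free] <- pmin(sqrt(radii[free]^2 + deficit / (pi * sum(free))),
                              rcap)
        }
      }
      jit <- pmax(0, 0.5 * (cell - 2 * max(radii))) * 0.9
      dr <- stats::runif(npore, -jit, jit)
      dt <- stats::runif(npore, -jit, jit) / rmid
      px <- cx + (rmid + dr) * cos(ang + dt)
      py <- cy + (rmid + dr) * sin(ang + dt)
      pores_x <- c(pores_x, px); pores_y <- c(pores_y, py)
      pores_r <- c(pores_r, radii)
    }
    r <- r + s
  }
  }
  # rasterise pores: class 2 where the pixel is primary bone
  for (p in seq_along(pores_r)) {
    rad <- pores_r[p]
    j0 <- max(1L, floor(pores_x[p] - rad)); j1 <- min(n, ceiling(pores_x[p] + rad) + 1L)
    i0 <- max(1L, floor(pores_y[p] - rad)); i1 <- min(n, ceiling(pores_y[p] + rad) + 1L)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    d2 <- outer((ii - 0.5 - pores_y[p])^2, (jj - 0.5 - pores_x[p])^2, "+")
    sel <- d2 <= rad^2 & ras[ii, jj, drop = FALSE] == 1L
    block <- ras[ii, jj, drop = FALSE]
    block[sel] <- 2L
    ras[ii, jj] <- block
  }
  # remodelled patches overwrite everything in the cortex
  for (patch in bp$remodel_patches) {
    a0 <- patch$angle[1] * pi / 180; a1 <- patch$angle[2] * pi / 180
    d0 <- patch$depth[1]; d1 <- patch$depth[2]
    th <- atan2(-outer(ys, rep(1, n)), outer(rep(1, n), xs))  # image-ccw angle
    th <- (th + 2 * pi) %% (2 * pi)
    sel <- in_cortex & depth >= d0 & depth <= d1 &
      th >= (a0 %% (2 * pi)) & th <= (a1 %% (2 * pi))
    ras[sel] <- 4L
  }
  bins <- data.frame(depth_lo = seq(0, 0.95, by = 0.05),
                     depth_hi = seq(0.05, 1, by = 0.05))
  bins$target_fraction <- vapply(seq_len(nrow(bins)), function(i) {
    mid <- (bins$depth_lo[i] + bins$depth_hi[i]) / 2
    if (mid < bp$el_fraction || mid > 1 - bp$ocl_fraction) 0
    else bp$radial_porosity_function(mid)
  }, numeric(1))
  list(image = label_image(ras, pixel_size = 1),
       ground_truth = bins,
       blueprint = bp)
}

#' Expected mean RPP of a blueprint
#'
#' Analytic target porosity per quadrant: the blueprint's porosity law
#' averaged over each quadrant's depth range, weighted by annulus area and
#' restricted to the primary zone (OCL/EL rims carry no pores and are
#' excluded from the measurement denominator).
#'
#' @param blueprint A `section_blueprint`.
#' @param n_quadrants Number of radial quadrants (default 4).
#' @return Numeric vector of expected porosities in percent (NA where a
#'   quadrant contains no primary zone).
#' @export
expected_quadrant_rpp <- function(blueprint, n_quadrants = 4L) {
  bp <- blueprint
  R0 <- bp$cavity_radius; Tc <- bp$cortex_thickness
  vapply(seq_len(n_quadrants), function(k) {
    dlo <- (k - 1) / n_quadrants; dhi <- k / n_quadrants
    dlo <- max(dlo, bp$el_fraction); dhi <- min(dhi, 1 - bp$ocl_fraction)
    if (dhi <= dlo) return(NA_real_)
    d <- seq(dlo, dhi, length.out = 201)
    w <- R0 + d * Tc                   # annulus circumference weight
    f <- vapply(d, bp$radial_porosity_function, numeric(1))
    100 * sum(f * w) / sum(w)
  }, numeric(1))
}

# ---- synthetic RPP datasets ------------------------------------------------

#' Design for a synthetic RPP dataset
#'
#' Defines group-specific polynomial mean trajectories over quadrant index
#' 1..4, sector-level Gaussian noise, per-quadrant missingness (higher in
#' the inner quadrants, where perimedullary remodelling erases the primary
#' record), and specimen metadata.
#'
#' The default design emulates the structure recovered from a duck
#' ontogenetic series: four groups with quadratic mean trajectories of
#' common shape and intercepts stepping from highly porous (young, fast
#' depositing) to compact (mature), separation between neighbouring groups
#' about 6.5 residual sd.
#'
#' @param n_groups Number of trajectory groups.
#' @param group_mean_trajectories List of polynomial coefficient vectors
#'   (intercept first), evaluated at quadrant index 1..4, in porosity
#'   percent.
#' @param noise_sd Sector-level Gaussian noise sd in porosity points.
#' @param n_elements_per_group Elements per group.
#' @param missingness_rates Length-4 per-quadrant missingness probabilities
#'   (quadrants a..d).
#' @param n_sectors Sectors per element.
#' @param ages_by_group List of candidate ages (dph) per group.
#' @param strategies_by_group Character vector of developmental strategies,
#'   one per group.
#' @param elements_per_specimen Elements pooled under one specimen id.
#' @param seed Integer seed.
#' @return A `dataset_design`.
#' @export
dataset_design <- function(n_groups = 4L,
                           group_mean_trajectories = NULL,
                           noise_sd = 2,
                           n_elements_per_group = 20L,
                           missingness_rates = c(0, 0, 0, 0),
                           n_sectors = 3L,
                           ages_by_group = NULL,
                           strategies_by_group = NULL,
                           elements_per_specimen = 1L,
                           seed = 1L) {
  if (n_groups < 1L) stop("n_groups must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(missingness_rates) != 4L ||
      any(missingness_rates < 0 | missingness_rates > 1))
    stop("missingness_rates must be 4 probabilities in [0, 1]")
  if (is.null(group_mean_trajectories)) {
    # adjacent group curves separated by 5 residual sd of the mean RPP
    # (sector noise averages over n_sectors), parallel quadratics
    step <- 5 * noise_sd / sqrt(n_sectors)
    intercepts <- seq(55, by = -step, length.out = n_groups)
    group_mean_trajectories <- lapply(intercepts, function(a) c(a, -4, 1.5))
  }
  if (length(group_mean_trajectories) != n_groups)
    stop("need one coefficient vector per group")
  if (is.null(ages_by_group))
    ages_by_group <- as.list(round(seq(4, 50, length.out = n_groups)))
  if (is.null(strategies_by_group))
    strategies_by_group <- rep(c("altricial", "precocial"),
                               length.out = n_groups)
  structure(list(n_groups = as.integer(n_groups),
                 group_mean_trajectories = group_mean_trajectories,
                 noise_sd = noise_sd,
                 n_elements_per_group = as.integer(n_elements_per_group),
                 missingness_rates = missingness_rates,
                 n_sectors = as.integer(n_sectors),
                 ages_by_group = ages_by_group,
                 strategies_by_group = strategies_by_group,
                 elements_per_specimen = as.integer(elements_per_specimen),
                 seed = as.integer(seed)),
            class = "dataset_design")
}

poly_eval <- function(coefs, x) {
  drop(outer(x, seq_along(coefs) - 1, `^`) %*% coefs)
}

#' Generate a synthetic RPP dataset
#'
#' Simulates the tidy long-format RPP table: per element, `n_sectors`
#' sector profiles equal to the group polynomial evaluated at quadrant
#' index 1..4 plus independent Gaussian noise per sector and quadrant
#' (truncated to [0, 100]). Missingness is applied per element and
#' quadrant; inner-quadrant missingness is correlated (a missing implies b
#' missing with probability at least 0.7, with the conditional for
#' a-present solved to preserve the marginal rate of b), mimicking
#' perimedullary remodelling spreading outward.
#'
#' @param design A `dataset_design`.
#' @return List with `table` (long tidy data.frame: specimen_id, taxon,
#'   element, element_id, age_dph, dev_strategy, sector, q, porosity),
#'   `truth` (data.frame element_id, group), and `design`.
#' @export
generate_rpp_dataset <- function(design) {
  stopifnot(inherits(design, "dataset_design"))
  set.seed(design$seed)
  de <- design
  q <- 1:4
  rows <- list(); truth <- list()
  eidx <- 0L
  for (g in seq_len(de$n_groups)) {
    mu <- poly_eval(de$group_mean_trajectories[[g]], q)
    for (e in seq_len(de$n_elements_per_group)) {
      eidx <- eidx + 1L
      element_id <- sprintf("E%03d", eidx)
      spec_id <- sprintf("S%03d",
                         ceiling(eidx / de$elements_per_specimen))
      element <- RPP_ELEMENTS[((eidx - 1L) %% length(RPP_ELEMENTS)) + 1L]
      age <- de$ages_by_group[[g]][((e - 1L) %% length(de$ages_by_group[[g]])) + 1L]
      strat <- de$strategies_by_group[g]
      # element-level missingness with correlated inner quadrants
      r <- de$missingness_rates
      miss <- stats::runif(4) < r
      if (miss[1]) {
        miss[2] <- stats::runif(1) < max(0.7, r[2])
      } else if (r[1] > 0 && r[1] < 1) {
        p_b <- max(0, min(1, (r[2] - max(0.7, r[2]) * r[1]) / (1 - r[1])))
        miss[2] <- stats::runif(1) < p_b
      }
      for (s in seq_len(de$n_sectors)) {
        v <- mu + stats::rnorm(4, 0, de$noise_sd)
        v <- pmin(pmax(v, 0), 100)
        v[miss] <- NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = spec_id, taxon = "synthetic",
          element = element, element_id = element_id,
          age_dph = age, dev_strategy = strat,
          sector = s, q = letters[q], porosity = v,
          stringsAsFactors = FALSE)
      }
      truth[[eidx]] <- data.frame(element_id = element_id, group = g,
                                  stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows),
       truth = do.call(rbind, truth),
       design = de)
}
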