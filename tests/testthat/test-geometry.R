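# Helper: circular annulus sector spec (centre cx,cy; image-ccw angles in
# degrees).
annulus_sector <- function(r_in, r_out, a0, a1, cx = 200, cy = 200,
                           n_arc = 31) {
  th <- seq(a0, a1, length.out = n_arc) * pi / 180
  inner <- cbind(cx + r_in * cos(th), cy - r_in * sin(th))
  outer <- cbind(cx + r_out * cos(th), cy - r_out * sin(th))
  sector_spec(inner, outer,
              side1 = rbind(inner[1, ], outer[1, ]),
              side2 = rbind(inner[n_arc, ], outer[n_arc, ]))
}

test_that("quadrants of an annulus sector match the closed-form areas", {
  sec <- annulus_sector(50, 150, -30, 30)
  quads <- build_quadrants(sec)
  expect_identical(vapply(quads, `[[`, character(1), "quadrant_index"),
                   letters[1:4])
  areas <- vapply(quads, `[[`, numeric(1), "area")
  exact <- sapply(1:4, function(k)
    (pi / 3) / 2 * ((50 + 25 * k)^2 - (50 + 25 * (k - 1))^2))
  # polygonal arcs underestimate slightly; 0.1% agreement at 31 vertices
  expect_equal(areas, exact, tolerance = 1e-3)
  # inner quadrants are smaller than outer ones
  expect_true(all(diff(areas) > 0))
  # partition property: quadrant areas sum exactly to the sector area
  expect_equal(sum(areas),
               rppbone:::polygon_area(rppbone:::sector_polygon(sec)),
               tolerance = 1e-9)
})

test_that("a rectangular sector degenerates to four equal rectangles", {
  sec <- sector_spec(inner = rbind(c(0, 0), c(10, 0)),
                     outer = rbind(c(0, 40), c(10, 40)),
                     side1 = rbind(c(0, 0), c(0, 40)),
                     side2 = rbind(c(10, 0), c(10, 40)))
  quads <- build_quadrants(sec)
  areas <- vapply(quads, `[[`, numeric(1), "area")
  expect_equal(areas, rep(100, 4), tolerance = 1e-9)
})

test_that("quadrant partition is exact for irregular sectors", {
  set.seed(42)
  for (rep in 1:10) {
    th <- seq(-25, 25, length.out = 21) * pi / 180
    rin <- 60 + cumsum(rnorm(21, 0, 1.5))
    rout <- 140 + cumsum(rnorm(21, 0, 2))
    inner <- cbind(200 + rin * cos(th), 200 - rin * sin(th))
    outer <- cbind(200 + rout * cos(th), 200 - rout * sin(th))
    sec <- sector_spec(inner, outer,
                       side1 = rbind(inner[1, ], outer[1, ]),
                       side2 = rbind(inner[21, ], outer[21, ]))
    quads <- build_quadrants(sec)
    expect_equal(sum(vapply(quads, `[[`, numeric(1), "area")),
                 rppbone:::polygon_area(rppbone:::sector_polygon(sec)),
                 tolerance = 1e-9)
  }
})

test_that("quadrant measurement integrates class areas correctly", {
  ras <- matrix(1L, 400, 400)
  img <- label_image(ras)
  sec <- annulus_sector(50, 150, -30, 30)
  quads <- build_quadrants(sec)
  # all primary bone: porosity 0
  m <- measure_quadrant(img, quads[[2]])
  expect_equal(m$porosity, 0)
  # checkerboard of primary/vascular: porosity 50 up to discretisation
  ras2 <- ras
  ras2[(row(ras2) + col(ras2)) %% 2 == 0] <- 2L
  m2 <- measure_quadrant(label_image(ras2), quads[[2]])
  expect_equal(m2$porosity, 50, tolerance = 0.02)
  # physical units scale with pixel_size^2
  m3 <- measure_quadrant(label_image(ras2, pixel_size = 2), quads[[2]])
  expect_equal(m3$quadrant_area, 4 * m2$quadrant_area)
  expect_equal(m3$porosity, m2$porosity)
})

test_that("mostly remodelled quadrants are reported missing", {
  ras <- matrix(1L, 400, 400)
  # remodel the left 60% of the image
  ras[, 1:240] <- 4L
  img <- label_image(ras)
  # quadrant fully inside the remodelled zone
  sec <- sector_spec(inner = rbind(c(20, 100), c(60, 100)),
                     outer = rbind(c(20, 300), c(60, 300)),
                     side1 = rbind(c(20, 100), c(20, 300)),
                     side2 = rbind(c(60, 100), c(60, 300)))
  quads <- build_quadrants(sec)
  m <- measure_quadrant(img, quads[[1]])
  expect_true(is.na(m$porosity))
  expect_equal(m$excluded_area, m$quadrant_area)
  # threshold rule: 60% excluded -> missing at default 0.5, measured at 0.7
  sec2 <- sector_spec(inner = rbind(c(180, 100), c(280, 100)),
                      outer = rbind(c(180, 300), c(280, 300)),
                      side1 = rbind(c(180, 100), c(180, 300)),
                      side2 = rbind(c(280, 100), c(280, 300)))
  q2 <- build_quadrants(sec2)[[1]]
  expect_true(is.na(measure_quadrant(img, q2)$porosity))
  expect_false(is.na(measure_quadrant(img, q2,
                                      missing_threshold = 0.7)$porosity))
})

test_that("porosity measurement is equivariant under 90-degree rotation", {
  bp <- section_blueprint(cavity_radius = 50, cortex_thickness = 80,
                          seed = 19)
  gs <- generate_section(bp)
  n <- nrow(gs$image$raster)
  sec <- annulus_sector(55, 125, -20, 20, cx = n / 2, cy = n / 2)
  prof <- vapply(build_quadrants(sec), function(q)
    measure_quadrant(gs$image, q)$porosity, numeric(1))
  # rotate raster 90 deg clockwise: (x, y) -> (n - y, x)
  rot_ras <- t(gs$image$raster[nrow(gs$image$raster):1, ])
  rot <- function(pl) cbind(n - pl[, 2], pl[, 1])
  sec_r <- sector_spec(rot(sec$inner), rot(sec$outer),
                       rot(sec$side1), rot(sec$side2))
  prof_r <- vapply(build_quadrants(sec_r), function(q)
    measure_quadrant(label_image(rot_ras), q)$porosity, numeric(1))
  expect_equal(prof_r, prof, tolerance = 1e-12)
})

test_that("automatic sector placement handles symmetric and off-centre rings", {
  bp <- section_blueprint(cavity_radius = 60, cortex_thickness = 90,
                          radial_porosity_function = function(d) 0,
                          seed = 2)
  gs <- generate_section(bp)
  secs <- place_sectors_auto(gs$image, 3)
  expect_length(secs, 3)
  areas <- vapply(secs, function(s)
    rppbone:::polygon_area(rppbone:::sector_polygon(s)), numeric(1))
  # perfect annulus at three angles: congruent sectors
  expect_lt(diff(range(areas)) / mean(areas), 0.02)
  # single sector at a requested angle
  s1 <- place_sectors_auto(gs$image, 1, angular_positions = 90)
  expect_length(s1, 1)
  # off-centre cavity: still valid simple polygons with positive area
  ras <- gs$image$raster
  n <- nrow(ras)
  shift <- 20L
  ras2 <- matrix(0L, n, n)
  ras2[, 1:(n - shift)] <- ras[, (shift + 1):n]  # shift cavity off-centre
  secs2 <- place_sectors_auto(label_image(ras2), 3)
  for (s in secs2)
    expect_gt(rppbone:::polygon_area(rppbone:::sector_polygon(s)), 0)
  # no cortex at all -> diagnostic error
  expect_error(place_sectors_auto(label_image(matrix(0L, 50, 50)), 3),
               "cortex")
})

test_that("a fully measured synthetic section yields zero porosity and no layers", {
  bp <- section_blueprint(cavity_radius = 60, cortex_thickness = 90,
                          radial_porosity_function = function(d) 0, seed = 8)
  gs <- generate_section(bp)
  res <- measure_section(gs$image, place_sectors_auto(gs$image, 3))
  expect_equal(as.numeric(res$mean_rpp), rep(0, 4))
  expect_equal(res$layers$relative_area_percent, c(0, 0))
})

test_that("OCL and EL relative thickness match the analytic annulus areas", {
  bp <- section_blueprint(cavity_radius = 70, cortex_thickness = 120,
                          ocl_fraction = 0.1, el_fraction = 0.08,
                          radial_porosity_function = function(d) 0.2,
                          seed = 31)
  gs <- generate_section(bp)
  res <- measure_section(gs$image, place_sectors_auto(gs$image, 3))
  R0 <- 70; R1 <- 190
  ocl_exp <- 100 * (R1^2 - (R1 - 0.1 * 120)^2) / (R1^2 - R0^2)
  el_exp <- 100 * ((R0 + 0.08 * 120)^2 - R0^2) / (R1^2 - R0^2)
  got <- res$layers$relative_area_percent
  expect_equal(got[1], ocl_exp, tolerance = 0.05)
  expect_equal(got[2], el_exp, tolerance = 0.05)
})
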