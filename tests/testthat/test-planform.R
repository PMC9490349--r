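test_that("outline of a dense rectangular face recovers its area", {
  m <- grid_block(length_mm = 200, width_mm = 100, thickness_mm = 30,
                  spacing = 1, tool_id = "rect")
  ol <- extract_active_outline(m, alpha = 10)
  expect_equal(ol$area_cm2, 200, tolerance = 0.01 * 200)
  expect_equal(unname(ol$centroid), c(0, 0), tolerance = 0.5)
})

test_that("alpha = Inf outline equals the convex hull of the projection", {
  set.seed(8)
  xy <- cbind(runif(800, -30, 30), runif(800, -50, 50))
  m <- surface_model(cbind(xy, z = 0), tool_id = "blob",
                     plane = rep("A", 800), active_planes = "A",
                     oriented = TRUE)
  ol <- extract_active_outline(m, alpha = Inf)
  hull <- xy[grDevices::chull(xy), ]
  expect_equal(ol$area_cm2,
               percussr:::polygon_area(hull) / 100, tolerance = 1e-12)
})

test_that("alpha-shape area matches a raster occupancy oracle within 2%", {
  set.seed(9)
  # random convex blob: points inside an ellipse
  n <- 6000
  xy <- cbind(runif(n, -40, 40), runif(n, -25, 25))
  keep <- (xy[, 1] / 40)^2 + (xy[, 2] / 25)^2 <= 1
  xy <- xy[keep, ]
  poly <- percussr:::alpha_shape(xy, alpha = 5)
  a_shape <- percussr:::polygon_area(poly)
  a_raster <- raster_area_oracle(xy, cell = 0.5)
  expect_equal(a_shape, a_raster, tolerance = 0.02 * a_raster)
})

test_that("collinear projections are refused", {
  m <- surface_model(cbind(rep(0, 20), seq(0, 19), rep(0, 20)) + 0,
                     tool_id = "line", plane = rep("A", 20),
                     active_planes = "A", oriented = TRUE)
  expect_error(extract_active_outline(m, alpha = 5),
               class = "percussr_degenerate")
})

test_that("pit planform: circles and rotated rectangles measure correctly", {
  # circular pit of radius 10: area ~ pi cm^2, bbox 20 x 20
  g <- as.matrix(expand.grid(x = seq(-12, 12, 0.4), y = seq(-12, 12, 0.4)))
  memb <- which(g[, 1]^2 + g[, 2]^2 <= 100)
  m <- surface_model(cbind(g, z = 0), tool_id = "circ",
                     plane = rep("A", nrow(g)), active_planes = "A",
                     oriented = TRUE)
  pits <- pits_from_members(m, list(memb))
  pits <- pit_planform_metrics(pits, m, alpha = 2)
  expect_equal(pits$area_cm2, pi, tolerance = 0.02 * pi)
  expect_equal(pits$length_mm, 20, tolerance = 0.02 * 20)
  expect_equal(pits$width_mm, 20, tolerance = 0.02 * 20)
  expect_equal(c(pits$centroid_x, pits$centroid_y), c(0, 0), tolerance = 0.1)

  # 10 x 20 rectangle rotated 45 degrees: oriented bbox stays (20, 10)
  gr <- as.matrix(expand.grid(x = seq(-5, 5, 0.25), y = seq(-10, 10, 0.25)))
  th <- pi / 4
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  gr45 <- gr %*% t(rot)
  bb <- percussr:::min_area_rect(gr45)
  expect_equal(bb$length_mm, 20, tolerance = 0.02 * 20)
  expect_equal(bb$width_mm, 10, tolerance = 0.02 * 10)
})

test_that("min-area rectangle matches a dense angle-sweep oracle", {
  set.seed(10)
  for (trial in 1:5) {
    xy <- cbind(runif(60, 0, 30), runif(60, 0, 18))
    got <- percussr:::min_area_rect(xy)
    want <- min_rect_oracle(xy)
    expect_equal(got$length_mm * got$width_mm, want$area,
                 tolerance = 1e-4 * want$area)
    expect_equal(got$length_mm, want$length, tolerance = 1e-3 * want$length)
  }
})

test_that("bbox dominates polygon: length >= width, bbox area >= polygon area", {
  set.seed(20)
  for (trial in 1:5) {
    xy <- cbind(runif(200, 0, 25), runif(200, 0, 25))
    poly <- percussr:::alpha_shape(xy, alpha = 6)
    bb <- percussr:::min_area_rect(poly)
    expect_gte(bb$length_mm, bb$width_mm)
    expect_gte(bb$length_mm * bb$width_mm,
               percussr:::polygon_area(poly) - 1e-9)
  }
})

square_outline <- function(side_mm, tool_id = "sq") {
  half <- side_mm / 2
  poly <- cbind(c(-half, half, half, -half), c(-half, -half, half, half))
  structure(list(tool_id = tool_id, plane = "A", polygon = poly,
                 area_cm2 = side_mm^2 / 100,
                 centroid = c(0, 0), alpha = Inf),
            class = "active_outline")
}

fake_pits <- function(polys, tool_id = "sq") {
  ctr <- t(vapply(polys, percussr:::polygon_centroid, numeric(2)))
  out <- tibble::tibble(
    tool_id = tool_id, plane = "A",
    pit_id = sprintf("pit_%02d", seq_along(polys)),
    point_idx = vector("list", length(polys)),
    n_points = NA_integer_,
    centroid_x = ctr[, 1], centroid_y = ctr[, 2],
    polygon = polys,
    area_cm2 = vapply(polys, percussr:::polygon_area, 0) / 100
  )
  class(out) <- c("percussr_pits", class(out))
  out
}

test_that("PA and D follow their arithmetic definitions", {
  ol <- square_outline(100) # 100 cm^2
  # disjoint pits of 5 and 15 cm^2
  p1 <- sqrt(500) / 2
  p2 <- sqrt(1500) / 2
  polys <- list(
    cbind(c(-40, -40 + 2 * p1, -40 + 2 * p1, -40), c(-40, -40, -40 + 2 * p1, -40 + 2 * p1)),
    cbind(c(10, 10 + 2 * p2, 10 + 2 * p2, 10), c(10, 10, 10 + 2 * p2, 10 + 2 * p2))
  )
  pits <- fake_pits(polys)
  s <- surface_damage_summary(pits, ol)
  expect_equal(s$pa_percent, 20, tolerance = 1e-6)
  expect_equal(s$density_per_cm2, 0.02, tolerance = 1e-12)
  expect_equal(s$density_per_cm2 * s$area_cm2, s$n_pits) # D * area = n

  # no pits
  s0 <- surface_damage_summary(pits[0, ], ol)
  expect_equal(s0$pa_percent, 0)
  expect_equal(s0$density_per_cm2, 0)

  # two 50%-overlapping pits of 10 cm^2: union 15, not 20
  side <- sqrt(1000)
  q1 <- cbind(c(0, side, side, 0), c(0, 0, side, side))
  q2 <- q1
  q2[, 1] <- q2[, 1] - side / 2 # shifted by half a side: 50% overlap
  s2 <- surface_damage_summary(fake_pits(list(q1 - 20, q2 - 20)), ol)
  expect_equal(s2$pa_percent, 15, tolerance = 1e-6)
})

test_that("PA is clipped to the outline and bounded by 100", {
  ol <- square_outline(40) # 16 cm^2
  big <- circle_poly(0, 0, 30) # covers the outline entirely
  s <- surface_damage_summary(fake_pits(list(big)), ol)
  expect_equal(s$pa_percent, 100, tolerance = 1e-6)
})

test_that("PA is invariant under rigid motion of the whole scene", {
  ol <- square_outline(60)
  pit <- circle_poly(5, -3, 8)
  s0 <- surface_damage_summary(fake_pits(list(pit)), ol)
  th <- 0.71
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  shift <- c(12.3, -4.5)
  move <- function(p) sweep(p %*% t(rot), 2, shift, "+")
  ol2 <- ol
  ol2$polygon <- move(ol$polygon)
  ol2$centroid <- as.vector(rot %*% ol$centroid + shift)
  s1 <- surface_damage_summary(fake_pits(list(move(pit))), ol2)
  expect_equal(s1$pa_percent, s0$pa_percent, tolerance = 1e-6)
})

test_that("DAC and DAE closed forms on circular outlines", {
  circ <- structure(list(tool_id = "c", plane = "A",
                         polygon = circle_poly(0, 0, 50, n = 2048),
                         area_cm2 = pi * 2500 / 100,
                         centroid = c(0, 0), alpha = Inf),
                    class = "active_outline")
  pits <- fake_pits(list(circle_poly(0, 0, 5), circle_poly(30, 0, 5)),
                    tool_id = "c")
  pits <- pit_position_metrics(pits, circ)
  expect_equal(pits$dac_mm, c(0, 30), tolerance = 1e-9)
  expect_equal(pits$dae_mm, c(50, 20), tolerance = 0.01)
})

test_that("DAE matches the exhaustive segment-distance oracle", {
  set.seed(15)
  poly <- cbind(c(0, 40, 55, 30, 12, -5), c(0, -5, 25, 45, 28, 20))
  ol <- structure(list(tool_id = "irr", plane = "A", polygon = poly,
                       area_cm2 = percussr:::polygon_area(poly) / 100,
                       centroid = percussr:::polygon_centroid(poly),
                       alpha = Inf),
                  class = "active_outline")
  cts <- cbind(runif(12, 10, 30), runif(12, 5, 25))
  pits <- fake_pits(lapply(seq_len(12), function(i)
    circle_poly(cts[i, 1], cts[i, 2], 1)), tool_id = "irr")
  pits <- pit_position_metrics(pits, ol)
  for (i in seq_len(12)) {
    expect_equal(pits$dae_mm[i],
                 seg_dist_oracle(c(pits$centroid_x[i], pits$centroid_y[i]),
                                 poly),
                 tolerance = 1e-9)
  }
  # convex outline: DAC + DAE >= distance from surface centre to boundary
  hullp <- poly[grDevices::chull(poly), ]
  olc <- ol
  olc$polygon <- hullp
  olc$centroid <- percussr:::polygon_centroid(hullp)
  pits2 <- pit_position_metrics(pits, olc)
  dmin_ctr <- seg_dist_oracle(olc$centroid, hullp)
  expect_true(all(pits2$dac_mm + pits2$dae_mm >= dmin_ctr - 1e-9))
})

test_that("planform summary assembles PA, D, DAC, DAE and handles no pits", {
  ol <- square_outline(80)
  pits <- fake_pits(list(circle_poly(-10, 0, 6), circle_poly(15, 10, 8)),
                    tool_id = "sq")
  s <- planform_summary(pits, ol)
  expect_equal(s$n_pits, 2L)
  expect_true(s$dac_min_mm <= s$dac_mean_mm && s$dac_mean_mm <= s$dac_max_mm)
  expect_true(all(c(s$dae_min_mm, s$dae_mean_mm, s$dae_max_mm) >= 0))
  expect_equal(s$density_per_cm2 * s$area_cm2, 2)

  s0 <- planform_summary(pits[0, ], ol)
  expect_equal(s0$n_pits, 0L)
  expect_true(is.na(s0$dac_mean_mm) && is.na(s0$dae_mean_mm))
  expect_error(surface_damage_summary(pits, square_outline(0)),
               class = "percussr_degenerate")
})
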