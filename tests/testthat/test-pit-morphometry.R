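make_flat_model <- function(spacing = 1, side = 40, z0 = 0) {
  g <- seq(-side / 2, side / 2, by = spacing)
  top <- as.matrix(expand.grid(x = g, y = g))
  pts <- cbind(top, z = z0)
  surface_model(pts, tool_id = "flat", plane = rep("A", nrow(pts)),
                active_planes = "A", oriented = TRUE)
}

test_that("TPI is zero on a perfect plane and shift-invariant", {
  m <- make_flat_model(spacing = 2, side = 60, z0 = 7)
  tpi <- compute_tpi(m, radius = 20)
  expect_true(all(abs(tpi$tpi) < 1e-9, na.rm = TRUE))
  expect_true(all(tpi$n_neighbours >= 5))

  m2 <- m
  m2$points[, 3] <- m2$points[, 3] + 123.456
  tpi2 <- compute_tpi(m2, radius = 20)
  expect_equal(tpi2$tpi, tpi$tpi, tolerance = 1e-9)
})

test_that("TPI of a single depressed grid point is its full depth", {
  g <- as.matrix(expand.grid(x = c(-5, 0, 5), y = c(-5, 0, 5)))
  z <- rep(0, 9)
  z[g[, 1] == 0 & g[, 2] == 0] <- -1
  m <- surface_model(cbind(g, z = z), tool_id = "grid9",
                     plane = rep("A", 9), active_planes = "A",
                     oriented = TRUE)
  tpi <- compute_tpi(m, radius = 20, k_min = 5)
  centre <- which(g[, 1] == 0 & g[, 2] == 0)
  expect_equal(tpi$tpi[centre], -1.0, tolerance = 1e-12)
})

test_that("TPI equals the O(N^2) neighbourhood-mean oracle", {
  sp <- surface_spec(length_mm = 50, width_mm = 50, thickness_mm = 20,
                     pits = tibble::tibble(x = 0, y = 0, radius_mm = 10,
                                           depth_mm = 3, profile = "gaussian"),
                     grain_noise_sd = 0.1, density_per_cm2 = 80, seed = 33)
  s <- generate_surface(sp)
  tpi <- compute_tpi(s$model, radius = 20)
  xy <- cbind(tpi$x, tpi$y)
  oracle <- tpi_oracle(xy, tpi$z, radius = 20, k_min = 5)
  expect_equal(tpi$tpi, oracle, tolerance = 1e-10)
})

test_that("TPI rejects bad radius and unoriented models", {
  m <- make_flat_model()
  expect_error(compute_tpi(m, radius = 0), class = "percussr_parameter")
  expect_error(compute_tpi(m, radius = -5), class = "percussr_parameter")
})

test_that("detection: clean plane yields no regions; pairing is checked", {
  m <- make_flat_model(spacing = 1, side = 50)
  tpi <- compute_tpi(m)
  pits <- detect_pit_regions(tpi, m)
  expect_equal(nrow(pits), 0)

  other <- make_flat_model(spacing = 1, side = 30)
  other$tool_id <- "other"
  expect_error(detect_pit_regions(tpi, other), class = "percussr_pairing")
})

test_that("detection finds exactly the planted pits and filters dimples", {
  gt <- tibble::tibble(x = c(-30, 25, 5), y = c(-50, -5, 55),
                       radius_mm = 15, depth_mm = 5)
  sp <- surface_spec(length_mm = 170, width_mm = 120, thickness_mm = 35,
                     pits = gt, grain_noise_sd = 0.1,
                     density_per_cm2 = 120, seed = 91)
  s <- generate_surface(sp)
  tpi <- compute_tpi(s$model)
  pits <- detect_pit_regions(tpi, s$model)
  expect_equal(nrow(pits), 3)
  m <- vapply(seq_len(3), function(j)
    which.min((gt$x - pits$centroid_x[j])^2 + (gt$y - pits$centroid_y[j])^2), 0L)
  expect_setequal(m, 1:3)
  err <- sqrt((gt$x[m] - pits$centroid_x)^2 + (gt$y[m] - pits$centroid_y)^2)
  expect_true(all(err <= 15 / 4)) # centroid error within radius / 4

  # adding a sub-criterion dimple (bbox length < 10 mm) changes nothing
  gt2 <- dplyr::bind_rows(gt, tibble::tibble(x = -40, y = 40, radius_mm = 3,
                                             depth_mm = 2))
  sp2 <- surface_spec(length_mm = 170, width_mm = 120, thickness_mm = 35,
                      pits = gt2, grain_noise_sd = 0.1,
                      density_per_cm2 = 120, seed = 91)
  s2 <- generate_surface(sp2)
  tpi2 <- compute_tpi(s2$model)
  pits2 <- detect_pit_regions(tpi2, s2$model)
  expect_equal(nrow(pits2), 3)
})

test_that("regions are disjoint and maximal under the linkage radius", {
  gt <- tibble::tibble(x = c(-25, 25), y = c(-30, 30), radius_mm = 13,
                       depth_mm = 4)
  sp <- surface_spec(length_mm = 120, width_mm = 100, thickness_mm = 30,
                     pits = gt, grain_noise_sd = 0.1,
                     density_per_cm2 = 100, seed = 13)
  s <- generate_surface(sp)
  tpi <- compute_tpi(s$model)
  pits <- detect_pit_regions(tpi, s$model)
  idx <- pits$point_idx
  expect_equal(length(unique(unlist(idx))), length(unlist(idx))) # disjoint
  # maximality: no masked point outside a region lies within the linkage
  # radius of that region
  thr <- attr(pits, "threshold")
  link <- attr(pits, "linkage_radius")
  masked <- tpi$point[!is.na(tpi$tpi) & tpi$tpi < -thr]
  for (i in seq_along(idx)) {
    inside <- idx[[i]]
    outside <- setdiff(masked, inside)
    if (length(outside) == 0) next
    pin <- s$model$points[inside, 1:2, drop = FALSE]
    pout <- s$model$points[outside, 1:2, drop = FALSE]
    dmin <- min(vapply(seq_len(nrow(pout)), function(j) {
      min(sqrt((pin[, 1] - pout[j, 1])^2 + (pin[, 2] - pout[j, 2])^2))
    }, 0))
    expect_gt(dmin, link)
  }
})

test_that("pit depth: flat patches sit on the hull, caps reach their depth", {
  m <- grid_block(length_mm = 80, width_mm = 60, thickness_mm = 25,
                  spacing = 1, tool_id = "slab")
  hull <- compute_convex_hull(m)
  aidx <- which(m$plane == "A")
  patch <- aidx[abs(m$points[aidx, 1]) < 10 & abs(m$points[aidx, 2]) < 10]
  pits <- pits_from_members(m, list(patch))
  pits <- measure_pit_depth(pits, hull, m)
  expect_lt(abs(pits$depth_mm), 1e-9)
  expect_lt(abs(pits$depth_max_mm), 1e-9)

  m2 <- carve_cap(m, 0, 0, radius = 15, depth = 5)
  m2 <- surface_model(m2$points, tool_id = "slab-carved", plane = m2$plane,
                      active_planes = "A", oriented = TRUE)
  hull2 <- compute_convex_hull(m2)
  aidx2 <- which(m2$plane == "A")
  members <- aidx2[sqrt(m2$points[aidx2, 1]^2 + m2$points[aidx2, 2]^2) < 15]
  pits2 <- pits_from_members(m2, list(members))
  pits2 <- measure_pit_depth(pits2, hull2, m2)
  expect_equal(pits2$depth_max_mm, -5, tolerance = 0.02 * 5)
  expect_lt(pits2$depth_mm, 0)

  # mismatched hull is refused
  expect_error(measure_pit_depth(pits2, hull, m2), class = "percussr_pairing")
})

test_that("gradient: ramps give tan(theta), planes give zero", {
  g <- as.matrix(expand.grid(x = seq(-20, 20, 1), y = seq(-20, 20, 1)))
  ramp <- surface_model(cbind(g, z = 0.25 * g[, 2]), tool_id = "ramp",
                        plane = rep("A", nrow(g)), active_planes = "A",
                        oriented = TRUE)
  members <- which(abs(g[, 1]) < 15 & abs(g[, 2]) < 15)
  pits <- pits_from_members(ramp, list(members))
  pits <- measure_pit_gradient(pits, ramp, fit_radius = 2)
  expect_equal(pits$gradient, 0.25, tolerance = 1e-6)

  flat <- make_flat_model(spacing = 1, side = 40)
  pitsf <- pits_from_members(flat, list(which(abs(flat$points[, 1]) < 15)))
  pitsf <- measure_pit_gradient(pitsf, flat, fit_radius = 2)
  expect_equal(pitsf$gradient, 0, tolerance = 1e-9)
})

test_that("cap gradient matches the analytic quadrature oracle within 2%", {
  a <- 15; d <- 5
  m <- grid_block(length_mm = 90, width_mm = 70, thickness_mm = 25,
                  spacing = 0.8, tool_id = "cap")
  m <- carve_cap(m, 0, 0, radius = a, depth = d)
  m <- surface_model(m$points, tool_id = "cap", plane = m$plane,
                     active_planes = "A", oriented = TRUE)
  aidx <- which(m$plane == "A")
  r_pt <- sqrt(m$points[aidx, 1]^2 + m$points[aidx, 2]^2)
  amax <- a - 2.5 # keep fit windows inside the cap
  members <- aidx[r_pt < amax]
  pits <- pits_from_members(m, list(members))
  pits <- measure_pit_gradient(pits, m, fit_radius = 2)
  # analytic cap slope |dz/dr| = r / sqrt(R^2 - r^2), averaged over the
  # sampled disc with uniform planimetric density (weight 2 pi r dr)
  R <- (a^2 + d^2) / (2 * d)
  num <- stats::integrate(function(r) r / sqrt(R^2 - r^2) * 2 * pi * r,
                          0, amax)$value
  den <- pi * amax^2
  expect_equal(pits$gradient, num / den, tolerance = 0.02)
})

test_that("roughness: zero on planes, bounded by noise amplitude, matches oracle", {
  g <- as.matrix(expand.grid(x = seq(-5, 5, 0.25), y = seq(-5, 5, 0.25)))
  flat <- surface_model(cbind(g, z = 0), tool_id = "r0",
                        plane = rep("A", nrow(g)), active_planes = "A",
                        oriented = TRUE)
  pits <- pits_from_members(flat, list(seq_len(nrow(g))))
  pits <- measure_pit_roughness(pits, flat, window = 0.5)
  expect_lt(pits$roughness_mm, 1e-9)

  set.seed(44)
  zn <- runif(nrow(g), -0.2, 0.2)
  noisy <- surface_model(cbind(g, z = zn), tool_id = "rn",
                         plane = rep("A", nrow(g)), active_planes = "A",
                         oriented = TRUE)
  pitsn <- pits_from_members(noisy, list(seq_len(nrow(g))))
  pitsn <- measure_pit_roughness(pitsn, noisy, window = 0.5)
  expect_gt(pitsn$roughness_mm, 0)
  expect_lt(pitsn$roughness_mm, 0.2)

  # direct per-point plane-fit oracle (O(N^2) neighbour search)
  pts <- noisy$points
  vals <- rep(NA_real_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d3 <- sqrt(rowSums(sweep(pts, 2, pts[i, ])^2))
    nbr <- which(d3 <= 0.5)
    if (length(nbr) < 4) next
    q <- pts[nbr, , drop = FALSE]
    ctr <- colMeans(q)
    sv <- svd(sweep(q, 2, ctr))
    nrm <- sv$v[, 3]
    vals[i] <- abs(sum((pts[i, ] - ctr) * nrm))
  }
  expect_equal(pitsn$roughness_mm, mean(vals, na.rm = TRUE),
               tolerance = 1e-9)
})

test_that("roughness window separates texture from long-wavelength form", {
  g <- as.matrix(expand.grid(x = seq(-10, 10, 0.25), y = seq(-25, 25, 0.25)))
  z <- 2 * sin(2 * pi * g[, 2] / 50) # amplitude 2 mm, wavelength 50 mm
  m <- surface_model(cbind(g, z = z), tool_id = "sine",
                     plane = rep("A", nrow(g)), active_planes = "A",
                     oriented = TRUE)
  pits <- pits_from_members(m, list(seq_len(nrow(g))))
  pits <- measure_pit_roughness(pits, m, window = 0.5)
  expect_lt(pits$roughness_mm, 0.05)
})

test_that("measured |depth_max| is monotone in the true pit depth", {
  depths <- c(2, 4, 6, 8)
  got <- vapply(depths, function(d) {
    sp <- surface_spec(length_mm = 100, width_mm = 80, thickness_mm = 40,
                       pits = tibble::tibble(x = 0, y = 0, radius_mm = 14,
                                             depth_mm = d),
                       grain_noise_sd = 0.1, density_per_cm2 = 100, seed = 5)
    s <- generate_surface(sp)
    hull <- compute_convex_hull(s$model)
    tpi <- compute_tpi(s$model)
    pits <- detect_pit_regions(tpi, s$model)
    pits <- measure_pit_depth(pits, hull, s$model)
    max(abs(pits$depth_max_mm))
  }, 0)
  expect_true(all(diff(got) > 0))
})

test_that("gradient and roughness are non-negative on detected pits", {
  sp <- surface_spec(length_mm = 90, width_mm = 70, thickness_mm = 30,
                     pits = tibble::tibble(x = 0, y = 0, radius_mm = 13,
                                           depth_mm = 4),
                     grain_noise_sd = 0.05, density_per_cm2 = 400, seed = 77)
  s <- generate_surface(sp)
  pits <- measure_pits(s$model, roughness = TRUE, window = 1)
  expect_true(all(pits$gradient >= 0))
  expect_true(all(pits$roughness_mm >= 0))
})
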