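# Independent brute-force oracles and fixture builders. Every oracle here
# is written against the definition, not against the package's code path.

# O(N^2) TPI: mean elevation of all neighbours within planimetric radius
tpi_oracle <- function(xy, z, radius, k_min = 5) {
  n <- nrow(xy)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    nbr <- which(d <= radius)
    nbr <- nbr[nbr != i]
    if (length(nbr) >= k_min) out[i] <- z[i] - mean(z[nbr])
  }
  out
}

# point-to-triangle distance via barycentric clamping written independently
# (project to plane, clamp to edges explicitly)
point_tri_dist_oracle <- function(p, a, b, c) {
  seg <- function(p, u, v) {
    w <- v - u
    t <- sum((p - u) * w) / sum(w * w)
    t <- min(1, max(0, t))
    sqrt(sum((p - (u + t * w))^2))
  }
  n <- pracma::cross(b - a, c - a)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-300) return(min(seg(p, a, b), seg(p, b, c), seg(p, a, c)))
  n <- n / nn
  proj <- p - sum((p - a) * n) * n
  # barycentric coordinates of the projection
  v0 <- b - a; v1 <- c - a; v2 <- proj - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(abs(sum((p - a) * n)))
  min(seg(p, a, b), seg(p, b, c), seg(p, a, c))
}

# is p strictly outside conv(S)? Exact brute force: p is outside iff some
# plane through three points of S has all of S on one side and p strictly
# on the other (a separating supporting plane exists among facet planes)
outside_convhull_oracle <- function(p, S, tol = 1e-9) {
  triples <- utils::combn(nrow(S), 3)
  for (j in seq_len(ncol(triples))) {
    a <- S[triples[1, j], ]; b <- S[triples[2, j], ]; cc <- S[triples[3, j], ]
    n <- pracma::cross(b - a, cc - a)
    nn <- sqrt(sum(n^2))
    if (nn < 1e-12) next
    n <- n / nn
    ds <- as.vector((S - matrix(a, nrow(S), 3, byrow = TRUE)) %*% n)
    dp <- sum((p - a) * n)
    if (max(ds) <= tol && dp > tol) return(TRUE)
    if (min(ds) >= -tol && dp < -tol) return(TRUE)
  }
  FALSE
}

# minimum-area enclosing rectangle by dense angle sweep
min_rect_oracle <- function(xy, n_angles = 20000) {
  best <- Inf
  sides <- c(NA, NA)
  for (th in seq(0, pi / 2, length.out = n_angles)) {
    r <- xy %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    a <- diff(range(r[, 1])) * diff(range(r[, 2]))
    if (a < best) {
      best <- a
      sides <- sort(c(diff(range(r[, 1])), diff(range(r[, 2]))),
                    decreasing = TRUE)
    }
  }
  list(length = sides[1], width = sides[2], area = best)
}

# occupancy-raster area of a point set's footprint at a given resolution
raster_area_oracle <- function(xy, cell = 0.5) {
  key <- paste(floor(xy[, 1] / cell), floor(xy[, 2] / cell))
  length(unique(key)) * cell^2
}

# shortest distance from a point to any segment of a closed polygon
seg_dist_oracle <- function(pt, poly) {
  n <- nrow(poly)
  dmin <- Inf
  for (i in seq_len(n)) {
    u <- poly[i, ]
    v <- poly[if (i == n) 1 else i + 1, ]
    w <- v - u
    t <- min(1, max(0, sum((pt - u) * w) / sum(w * w)))
    dmin <- min(dmin, sqrt(sum((pt - (u + t * w))^2)))
  }
  dmin
}

# exact two-sided MWU p-value from the null distribution (stats::pwilcox),
# independent of the package's enumeration
mwu_exact_p_oracle <- function(u1, n1, n2) {
  lo <- min(u1, n1 * n2 - u1)
  min(1, stats::pwilcox(lo, n1, n2) +
        (1 - stats::pwilcox(n1 * n2 - lo - 1, n1, n2)))
}

# regular-grid block surface (deterministic, noiseless unless sd > 0)
grid_block <- function(length_mm = 100, width_mm = 80, thickness_mm = 30,
                       spacing = 1, tool_id = "block", sd = 0, seed = 1) {
  xs <- seq(-width_mm / 2, width_mm / 2, by = spacing)
  ys <- seq(-length_mm / 2, length_mm / 2, by = spacing)
  top <- as.matrix(expand.grid(x = xs, y = ys))
  pts <- rbind(
    cbind(top, z = 0),
    cbind(top, z = -thickness_mm),
    as.matrix(expand.grid(x = range(xs), y = ys, z = seq(-thickness_mm, 0, by = spacing))),
    as.matrix(expand.grid(x = xs, y = range(ys), z = seq(-thickness_mm, 0, by = spacing)))
  )
  plane <- c(rep("A", nrow(top)), rep("A2", nrow(top)),
             rep(NA_character_, nrow(pts) - 2 * nrow(top)))
  if (sd > 0) {
    set.seed(seed)
    pts[, 3] <- pts[, 3] + rnorm(nrow(pts), 0, sd)
  }
  surface_model(pts, tool_id = tool_id, plane = plane, active_planes = "A",
                oriented = TRUE)
}

# carve a spherical-cap pit of given radius/depth into the A-plane of a model
carve_cap <- function(model, cx, cy, radius, depth) {
  idx <- which(model$plane == "A")
  r <- sqrt((model$points[idx, 1] - cx)^2 + (model$points[idx, 2] - cy)^2)
  R <- (radius^2 + depth^2) / (2 * depth)
  dz <- numeric(length(r))
  ins <- r < radius
  dz[ins] <- sqrt(R^2 - r[ins]^2) - (R - depth)
  model$points[idx, 3] <- model$points[idx, 3] - dz
  model
}

# build a percussr_pits tibble directly from chosen member points (bypasses
# detection, for measurement tests)
pits_from_members <- function(model, members_list, centroids = NULL) {
  rows <- lapply(seq_along(members_list), function(i) {
    idx <- members_list[[i]]
    tibble::tibble(
      tool_id = model$tool_id, plane = "A",
      pit_id = sprintf("pit_%02d", i),
      point_idx = list(idx), n_points = length(idx),
      centroid_x = if (is.null(centroids)) mean(model$points[idx, 1]) else centroids[i, 1],
      centroid_y = if (is.null(centroids)) mean(model$points[idx, 2]) else centroids[i, 2]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "tool_id") <- model$tool_id
  attr(out, "n_model_points") <- nrow(model$points)
  class(out) <- c("percussr_pits", class(out))
  out
}

# circle polygon helper
circle_poly <- function(cx, cy, r, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Table 1 vectors used by several statistical tests
table1_hammers <- function() {
  tools <- load_djouroutou_tables()
  tools[tools$tool_type == "hammer", ]
}
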