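# 2D computational-geometry helpers shared by the planform module.
# Polygons are n x 2 matrices of (x, y) in mm, open (last vertex != first).

# signed area by the shoelace formula (positive = counter-clockwise)
polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(poly) abs(polygon_signed_area(poly))

# area centroid of a simple polygon
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# even-odd point-in-polygon test
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2])) {
      xint <- poly[j, 1] + (pt[2] - poly[j, 2]) / (poly[i, 2] - poly[j, 2]) *
        (poly[i, 1] - poly[j, 1])
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# shortest distance from a point to a closed polyline (the polygon boundary)
point_to_boundary_dist <- function(pt, poly) {
  a <- poly
  b <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  px <- pt[1] - a[, 1]; py <- pt[2] - a[, 2]
  len2 <- ex^2 + ey^2
  t <- ifelse(len2 > 0, pmin(1, pmax(0, (px * ex + py * ey) / len2)), 0)
  dx <- px - t * ex; dy <- py - t * ey
  sqrt(min(dx^2 + dy^2))
}

# Minimum-area rotated rectangle (rotating calipers over convex-hull edges).
# Degenerate inputs (collinear) yield width 0 and length = max extent.
min_area_rect <- function(xy) {
  xy <- unique(xy[stats::complete.cases(xy), , drop = FALSE])
  n <- nrow(xy)
  if (n == 0) abort("no points for bounding box", class = "percussr_degenerate")
  if (n == 1) {
    return(list(length_mm = 0, width_mm = 0, angle = 0,
                corners = xy[c(1, 1, 1, 1), , drop = FALSE]))
  }
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  if (nrow(hull) == 2 || all(abs(polygon_signed_area(hull)) < 1e-12)) {
    # collinear: span along the principal direction
    d <- stats::prcomp(xy, center = TRUE)$x[, 1]
    len <- diff(range(d))
    ang <- atan2(xy[which.max(d), 2] - xy[which.min(d), 2],
                 xy[which.max(d), 1] - xy[which.min(d), 1])
    return(list(length_mm = len, width_mm = 0, angle = ang, corners = NULL))
  }
  m <- nrow(hull)
  nxt <- c(2:m, 1)
  best <- list(area = Inf)
  for (i in seq_len(m)) {
    e <- hull[nxt[i], ] - hull[i, ]
    ang <- atan2(e[2], e[1])
    rot <- matrix(c(cos(-ang), -sin(-ang), sin(-ang), cos(-ang)), 2, 2,
                  byrow = TRUE)
    r <- hull %*% t(rot)
    rx <- range(r[, 1]); ry <- range(r[, 2])
    area <- diff(rx) * diff(ry)
    if (area < best$area) {
      corners_r <- cbind(c(rx[1], rx[2], rx[2], rx[1]),
                         c(ry[1], ry[1], ry[2], ry[2]))
      best <- list(area = area, angle = ang,
                   sides = sort(c(diff(rx), diff(ry)), decreasing = TRUE),
                   corners = corners_r %*% rot)
    }
  }
  list(length_mm = best$sides[1], width_mm = best$sides[2],
       angle = best$angle, corners = best$corners)
}

# circumradius of triangles given vertex indices into xy
triangle_circumradius <- function(tri, xy) {
  a <- xy[tri[, 1], , drop = FALSE]
  b <- xy[tri[, 2], , drop = FALSE]
  cc <- xy[tri[, 3], , drop = FALSE]
  la <- sqrt(rowSums((b - cc)^2))
  lb <- sqrt(rowSums((a - cc)^2))
  lc <- sqrt(rowSums((a - b)^2))
  area2 <- abs((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
                 (cc[, 1] - a[, 1]) * (b[, 2] - a[, 2]))
  r <- la * lb * lc / (2 * area2)
  r[area2 < 1e-12] <- Inf
  r
}

# Alpha shape of a planar point set: Delaunay triangles (in-package
# Bowyer-Watson) with circumradius <= alpha; the outline is the largest
# closed boundary loop. alpha = Inf returns the convex hull.
alpha_shape <- function(xy, alpha) {
  xy <- unique(xy[stats::complete.cases(xy), , drop = FALSE])
  if (nrow(xy) < 3)
    abort("alpha shape needs at least 3 distinct points",
          class = "percussr_degenerate")
  if (!is.finite(alpha)) {
    h <- grDevices::chull(xy)
    poly <- xy[h, , drop = FALSE]
    if (nrow(poly) < 3 || polygon_area(poly) < 1e-12)
      abort("degenerate (collinear) point set", class = "percussr_degenerate")
    if (polygon_signed_area(poly) < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
    return(poly)
  }
  if (alpha <= 0) abort("alpha must be positive", class = "percussr_parameter")
  if (min_area_rect(xy)$width_mm < 1e-9)
    abort("degenerate (collinear) point set", class = "percussr_degenerate")
  tri <- cpp_delaunay(as.matrix(xy))
  if (nrow(tri) == 0)
    abort("degenerate (collinear) point set", class = "percussr_degenerate")
  keep <- triangle_circumradius(tri, xy) <= alpha
  tri <- tri[keep, , drop = FALSE]
  if (nrow(tri) == 0)
    abort("alpha too small: no triangles retained",
          class = "percussr_parameter")
  # boundary edges appear in exactly one retained triangle
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  bnd <- e[key %in% names(which(table(key) == 1)), , drop = FALSE]
  loops <- chain_edges(bnd)
  if (length(loops) == 0)
    abort("alpha shape produced no closed boundary",
          class = "percussr_degenerate")
  areas <- vapply(loops, function(l) polygon_area(xy[l, , drop = FALSE]), 0)
  poly <- xy[loops[[which.max(areas)]], , drop = FALSE]
  if (polygon_signed_area(poly) < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
  poly
}

# chain undirected boundary edges into closed vertex loops
chain_edges <- function(edges) {
  if (nrow(edges) == 0) return(list())
  adj <- list()
  for (k in seq_len(nrow(edges))) {
    i <- as.character(edges[k, 1]); j <- as.character(edges[k, 2])
    adj[[i]] <- c(adj[[i]], edges[k, 2])
    adj[[j]] <- c(adj[[j]], edges[k, 1])
  }
  used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  loops <- list()
  for (k in seq_len(nrow(edges))) {
    if (!is.null(used[[ekey(edges[k, 1], edges[k, 2])]])) next
    start <- edges[k, 1]
    cur <- edges[k, 2]
    used[[ekey(start, cur)]] <- TRUE
    loop <- c(start, cur)
    repeat {
      nbrs <- adj[[as.character(cur)]]
      nxt <- NA
      for (cand in nbrs) {
        if (is.null(used[[ekey(cur, cand)]])) { nxt <- cand; break }
      }
      if (is.na(nxt)) break
      used[[ekey(cur, nxt)]] <- TRUE
      if (nxt == start) break
      loop <- c(loop, nxt)
      cur <- nxt
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

# polyclip wrappers: polygons as list(list(x=, y=))
poly_to_pc <- function(poly) list(list(x = poly[, 1], y = poly[, 2]))

pc_area <- function(pc) {
  sum(vapply(pc, function(p) {
    abs(polygon_signed_area(cbind(p$x, p$y)))
  }, 0))
}

# area of the union of polygons, clipped to a boundary polygon
union_area_clipped <- function(polys, boundary) {
  if (length(polys) == 0) return(0)
  u <- poly_to_pc(polys[[1]])
  for (p in polys[-1]) u <- polyclip::polyclip(u, poly_to_pc(p), op = "union")
  clipped <- polyclip::polyclip(u, poly_to_pc(boundary), op = "intersection")
  pc_area(clipped)
}

# median nearest-neighbour spacing of a planar point set; coincident
# projections (e.g. points of opposite faces sharing x, y) are ignored
median_spacing <- function(xy) {
  if (nrow(xy) < 2) return(NA_real_)
  d <- cpp_nn_dist(as.matrix(xy))
  d <- d[d > 0]
  if (length(d) == 0) return(NA_real_)
  stats::median(d)
}
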