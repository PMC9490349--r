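#' Construct a tool surface model
#'
#' A surface model holds a tool's 3D point cloud (coordinates in mm), an
#' optional triangulation, and — once oriented — the assignment of points to
#' the six idealized planes used to describe percussive tools: `A` (upward
#' active surface), `A2` (opposite face), `B`/`B2` (forward/rear), `C`/`C2`
#' (left/right).
#'
#' @param points numeric matrix (n x 3) of x, y, z coordinates in mm.
#' @param faces optional integer matrix (m x 3) of 1-based triangle indices.
#' @param tool_id identifier carried through all downstream tables.
#' @param plane optional character vector (length n) of plane labels.
#' @param active_planes character vector of 1-2 active plane labels.
#' @param oriented logical; has [orient_model()] been applied?
#'
#' @return an object of class `percussr_surface`.
#' @export
surface_model <- function(points, faces = NULL, tool_id = "tool",
                          plane = NULL, active_planes = "A",
                          oriented = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 3) abort("points must have 3 columns")
  if (!is.numeric(points) || anyNA(points) || any(!is.finite(points)))
    abort("coordinates must be finite numbers", class = "percussr_malformed")
  if (nrow(points) < 4)
    abort("a surface model needs at least 4 points",
          class = "percussr_malformed")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    if (ncol(faces) != 3 || any(faces < 1) || any(faces > nrow(points)))
      abort("faces must index points (1-based, 3 columns)",
            class = "percussr_malformed")
  }
  if (!is.null(plane) && length(plane) != nrow(points))
    abort("plane must have one label per point")
  structure(
    list(tool_id = tool_id, points = points, faces = faces,
         plane = plane, active_planes = active_planes,
         oriented = oriented, units = "mm"),
    class = "percussr_surface"
  )
}

#' @export
print.percussr_surface <- function(x, ...) {
  cat("<percussr_surface> ", x$tool_id, "\n", sep = "")
  ext <- apply(x$points, 2, function(v) diff(range(v)))
  cat(sprintf("  %d points%s; extent %.1f x %.1f x %.1f mm\n",
              nrow(x$points),
              if (is.null(x$faces)) "" else
                sprintf(", %d faces", nrow(x$faces)),
              ext[1], ext[2], ext[3]))
  cat(sprintf("  oriented: %s; active plane(s): %s\n",
              x$oriented, paste(x$active_planes, collapse = ", ")))
  invisible(x)
}

# guard against collinear/coplanar clouds; returns covariance eigen pairs
check_nondegenerate <- function(points) {
  ctr <- sweep(points, 2, colMeans(points))
  ev <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)
  if (ev$values[1] <= 0 || ev$values[3] / ev$values[1] < 1e-12)
    abort("degenerate point cloud (collinear or coplanar)",
          class = "percussr_degenerate")
  ev
}

#' Orient a tool model into the six-plane frame
#'
#' Applies a rigid rotation (and centring translation) so that the maximum
#' extent of the cloud runs along the Y axis, the minimum-thickness
#' direction along Z, and the active surface faces upward (+Z). When
#' `up_hint` is not supplied, the upward face is chosen as the side of the
#' minimum-thickness axis with the higher planar point density — a stand-in
#' for the field protocol of facing the visibly most damaged surface up.
#' Afterwards every point is assigned to one of the six planes by the angle
#' between its locally fitted surface normal and the frame axes.
#'
#' @param model a [surface_model()].
#' @param up_hint optional 3-vector in input coordinates: the outward normal
#'   of the active face.
#' @param plane_angle_tol angular tolerance (degrees) for assigning points
#'   to planes; points at edges/corners stay unassigned.
#' @return the oriented `percussr_surface` with `plane` filled in; the
#'   applied rotation is stored in `attr(, "rotation")`.
#' @export
orient_model <- function(model, up_hint = NULL, plane_angle_tol = 30) {
  stopifnot(inherits(model, "percussr_surface"))
  pts <- model$points
  ev <- check_nondegenerate(pts)
  ctr <- colMeans(pts)
  centred <- sweep(pts, 2, ctr)

  # candidate rotations: eigenvector axis permutations consistent with the
  # extent ordering (max -> Y, min -> Z); ties broken by the smaller
  # rotation angle
  V <- ev$vectors
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- NULL
  for (pm in perms) {
    # columns of W: world X, Y, Z expressed in input coordinates
    W <- V[, c(pm[2], pm[1], pm[3])] # Y gets the first listed axis
    rot <- t(W)
    if (det(rot) < 0) rot[1, ] <- -rot[1, ] # flip X to stay right-handed
    r <- centred %*% t(rot)
    e <- apply(r, 2, function(v) diff(range(v)))
    emax <- max(e)
    ok <- e[2] >= emax * (1 - 1e-9) && e[3] <= min(e) * (1 + 1e-9)
    if (!ok) next
    ang <- acos(pmin(1, pmax(-1, (sum(diag(rot)) - 1) / 2)))
    if (is.null(best) || ang < best$ang - 1e-12) best <- list(rot = rot, ang = ang)
  }
  if (is.null(best))
    abort("could not orient model (ambiguous extents)",
          class = "percussr_degenerate")
  rot <- best$rot
  r <- centred %*% t(rot)

  # face the active surface up: with no hint, pick the face with greater
  # interior relief — percussive damage (pits, depressions) spreads the
  # height distribution of the damaged face, mirroring the field protocol
  # of facing the visibly most damaged surface upward
  flip <- diag(c(-1, 1, -1)) # flips Z while preserving Y and handedness
  if (!is.null(up_hint)) {
    h <- rot %*% (up_hint / sqrt(sum(up_hint^2)))
    if (h[3] < 0) { rot <- flip %*% rot; r <- centred %*% t(rot) }
  } else {
    xr <- range(r[, 1]); yr <- range(r[, 2]); zr <- range(r[, 3])
    tt <- diff(zr)
    interior <- r[, 1] > xr[1] + 0.05 * diff(xr) &
      r[, 1] < xr[2] - 0.05 * diff(xr) &
      r[, 2] > yr[1] + 0.05 * diff(yr) &
      r[, 2] < yr[2] - 0.05 * diff(yr)
    slab <- max(0.3 * tt, 1e-6)
    ztop <- r[interior & r[, 3] > zr[2] - slab, 3]
    zbot <- r[interior & r[, 3] < zr[1] + slab, 3]
    relief <- function(z) if (length(z) > 2) stats::sd(z) else 0
    if (relief(zbot) > relief(ztop)) {
      rot <- flip %*% rot
      r <- centred %*% t(rot)
    }
  }

  out <- model
  out$points <- r
  dimnames(out$points) <- list(NULL, c("x", "y", "z"))
  out$oriented <- TRUE
  out$plane <- assign_planes(out$points, angle_tol = plane_angle_tol)
  attr(out, "rotation") <- rot
  out
}

#' Assign points to the six idealized planes
#'
#' Estimates a surface normal per point from a local plane fit and labels
#' points whose outward normal lies within `angle_tol` degrees of a frame
#' axis: +Z = A, -Z = A2, +Y = B, -Y = B2, +X = C, -X = C2. Edge and corner
#' points remain `NA`.
#'
#' @param points oriented n x 3 coordinate matrix.
#' @param angle_tol angular tolerance in degrees.
#' @param fit_radius neighbourhood radius for the normal fit; defaults to
#'   four median 3D point spacings (3D, so that steep faces whose
#'   planimetric projection collapses to a line are still fitted at the
#'   surface's own scale).
#' @return character vector of plane labels (NA where unassigned).
#' @export
assign_planes <- function(points, angle_tol = 30, fit_radius = NULL) {
  if (is.null(fit_radius)) {
    d3 <- cpp_nn_dist3(points)
    d3 <- d3[d3 > 0]
    fit_radius <- 4 * stats::median(d3)
  }
  lp <- cpp_local_plane(points, fit_radius, 4L)
  nrm <- lp$normal
  # orient normals outward from the centroid
  ctr <- colMeans(points)
  rel <- sweep(points, 2, ctr)
  s <- sign(rowSums(nrm * rel))
  s[s == 0 | is.na(s)] <- 1
  nrm <- nrm * s
  axes <- rbind(A = c(0, 0, 1), A2 = c(0, 0, -1),
                B = c(0, 1, 0), B2 = c(0, -1, 0),
                C = c(1, 0, 0), C2 = c(-1, 0, 0))
  cosang <- nrm %*% t(axes)
  best <- max.col(cosang, ties.method = "first")
  lab <- rownames(axes)[best]
  maxcos <- cosang[cbind(seq_len(nrow(points)), best)]
  lab[is.na(maxcos) | maxcos < cos(angle_tol * pi / 180)] <- NA_character_
  lab[is.na(lp$slope)] <- NA_character_
  lab
}

# indices of points on the given planes (default: the active planes)
active_idx <- function(model, planes = model$active_planes) {
  if (is.null(model$plane))
    abort("model has no plane assignment; call orient_model() first")
  which(model$plane %in% planes)
}
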