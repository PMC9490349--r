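#' Compute the encompassing convex hull of a tool model
#'
#' The hull is the reference surface from which pit depths are measured:
#' an undamaged tool would coincide with (the upper part of) its hull, so
#' the signed distance of a surface point to the hull isolates material
#' removed by percussion.
#'
#' @param model a [surface_model()].
#' @return an object of class `percussr_hull`: hull vertex coordinates,
#'   outward-wound triangular facets, surface area (mm^2) and volume (mm^3).
#' @export
compute_convex_hull <- function(model) {
  stopifnot(inherits(model, "percussr_surface"))
  check_nondegenerate(model$points)
  f <- cpp_quickhull3(model$points)
  vidx <- sort(unique(as.vector(f)))
  remap <- match(as.vector(f), vidx)
  faces <- matrix(remap, ncol = 3)
  verts <- model$points[vidx, , drop = FALSE]
  a <- verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 2], , drop = FALSE]
  cc <- verts[faces[, 3], , drop = FALSE]
  cr <- cbind(
    (b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
    (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
    (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  )
  area <- sum(sqrt(rowSums(cr^2))) / 2
  # divergence theorem with outward facets
  volume <- sum(a[, 1] * cr[, 1] + a[, 2] * cr[, 2] + a[, 3] * cr[, 3]) / 6
  structure(
    list(tool_id = model$tool_id, n_model_points = nrow(model$points),
         vertices = verts, vertex_index = vidx, faces = faces,
         area_mm2 = area, volume_mm3 = volume),
    class = "percussr_hull"
  )
}

#' @export
print.percussr_hull <- function(x, ...) {
  cat(sprintf("<percussr_hull> %s: %d vertices, %d facets, area %.1f mm^2, volume %.1f mm^3\n",
              x$tool_id, nrow(x$vertices), nrow(x$faces), x$area_mm2,
              x$volume_mm3))
  invisible(x)
}

#' Signed distance from points to a convex hull surface
#'
#' Negative values lie inside/below the hull; every point of the model the
#' hull was computed from is at distance <= 0 (up to floating tolerance).
#'
#' @param hull a `percussr_hull`.
#' @param points n x 3 coordinate matrix.
#' @return numeric vector of signed distances in mm.
#' @export
hull_signed_distance <- function(hull, points) {
  stopifnot(inherits(hull, "percussr_hull"))
  points <- as.matrix(points)
  if (ncol(points) != 3) abort("points must have 3 columns")
  cpp_mesh_signed_dist(points, hull$vertices, hull$faces)
}
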