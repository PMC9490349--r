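#' Topographic position index of the active surface
#'
#' For every point on the active plane(s), TPI is its elevation minus the
#' mean elevation of all neighbours within a planimetric (x, y) radius —
#' the point-cloud analogue of the raster TPI used in DEM-based use-wear
#' protocols. Negative values mark depressions. The default 20 mm radius is
#' large enough that percussive pits are captured whole rather than split
#' into rim and floor.
#'
#' @param model an oriented [surface_model()].
#' @param radius neighbourhood radius in mm.
#' @param k_min minimum neighbour count; points with fewer neighbours get
#'   `NA` (undefined) rather than an extrapolated value.
#' @return a tibble of class `percussr_tpi` with one row per active-plane
#'   point: `point` (index into the model), `x`, `y`, `z`, `n_neighbours`,
#'   `tpi` (mm).
#' @export
compute_tpi <- function(model, radius = 20, k_min = 5) {
  stopifnot(inherits(model, "percussr_surface"))
  if (!is.numeric(radius) || radius <= 0)
    abort("radius must be positive", class = "percussr_parameter")
  if (!model$oriented)
    abort("model must be oriented (orient_model) before computing TPI")
  idx <- active_idx(model)
  pts <- model$points[idx, , drop = FALSE]
  res <- cpp_disc_mean(pts[, 1:2, drop = FALSE], pts[, 3], radius,
                       as.integer(k_min))
  out <- tibble::tibble(
    point = idx,
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    n_neighbours = res$n,
    tpi = pts[, 3] - res$mean_z
  )
  attr(out, "radius") <- radius
  attr(out, "k_min") <- k_min
  attr(out, "tool_id") <- model$tool_id
  attr(out, "n_model_points") <- nrow(model$points)
  class(out) <- c("percussr_tpi", class(out))
  out
}
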