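#' Detect discrete pit regions from a TPI field
#'
#' Points whose TPI falls below `-threshold` form the depression mask;
#' connected components of the mask under planimetric `linkage_radius`
#' adjacency are candidate pits ("maximum contiguous extent of each
#' depression"), and candidates whose oriented-bounding-box length is below
#' `min_length` (default 10 mm, the conventional size criterion separating
#' pits from dispersed micro-depressions) are discarded.
#'
#' The default threshold is noise-adaptive: `max(0.3, 3 * mad(TPI))` mm,
#' which reduces to a fixed 0.3 mm floor on clean surfaces.
#'
#' @param tpi a [compute_tpi()] result for the same model.
#' @param model the oriented `percussr_surface`.
#' @param threshold depression depth threshold in mm, or `"auto"`.
#' @param linkage_radius contiguity radius in mm; defaults to four times
#'   the median nearest-neighbour spacing of the active plane (uniformly
#'   random clouds only percolate above ~3 spacings, so smaller radii
#'   fragment genuine depressions).
#' @param min_length minimum oriented-bbox length in mm to keep a region.
#' @return a tibble of class `percussr_pits`, one row per pit: `pit_id`,
#'   `point_idx` (list column of model point indices), `n_points`,
#'   `centroid_x`, `centroid_y` (member means; replaced by the polygon
#'   centroid once [pit_planform_metrics()] runs).
#' @export
detect_pit_regions <- function(tpi, model, threshold = "auto",
                               linkage_radius = NULL, min_length = 10) {
  stopifnot(inherits(tpi, "percussr_tpi"), inherits(model, "percussr_surface"))
  if (!identical(attr(tpi, "tool_id"), model$tool_id) ||
      !identical(attr(tpi, "n_model_points"), nrow(model$points)))
    abort("tpi was computed from a different model",
          class = "percussr_pairing")
  if (identical(threshold, "auto"))
    threshold <- max(0.3, 3 * stats::mad(tpi$tpi, na.rm = TRUE))
  if (!is.numeric(threshold) || threshold <= 0)
    abort("threshold must be positive", class = "percussr_parameter")
  xy_all <- cbind(tpi$x, tpi$y)
  if (is.null(linkage_radius)) {
    sp <- median_spacing(xy_all)
    linkage_radius <- 4 * sp
  }
  if (!is.numeric(linkage_radius) || linkage_radius <= 0)
    abort("linkage_radius must be positive", class = "percussr_parameter")

  mask <- !is.na(tpi$tpi) & tpi$tpi < -threshold
  empty <- tibble::tibble(
    tool_id = character(), plane = character(), pit_id = character(),
    point_idx = list(), n_points = integer(),
    centroid_x = numeric(), centroid_y = numeric()
  )
  mk <- function(df) {
    attr(df, "threshold") <- threshold
    attr(df, "linkage_radius") <- linkage_radius
    attr(df, "min_length") <- min_length
    attr(df, "tool_id") <- model$tool_id
    attr(df, "n_model_points") <- nrow(model$points)
    class(df) <- c("percussr_pits", class(df))
    df
  }
  if (!any(mask)) return(mk(empty))

  sub <- tpi[mask, ]
  comp <- cpp_link_components(cbind(sub$x, sub$y), linkage_radius)
  plane_of <- function(i) model$plane[i][1]
  regions <- split(seq_len(nrow(sub)), comp)
  rows <- lapply(regions, function(r) {
    xy <- cbind(sub$x[r], sub$y[r])
    bb <- min_area_rect(xy)
    if (bb$length_mm < min_length) return(NULL)
    tibble::tibble(
      tool_id = model$tool_id,
      plane = plane_of(sub$point[r][1]),
      point_idx = list(sub$point[r]),
      n_points = length(r),
      centroid_x = mean(xy[, 1]), centroid_y = mean(xy[, 2])
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(mk(empty))
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$centroid_y, out$centroid_x), ]
  out <- dplyr::mutate(out, pit_id = sprintf("pit_%02d", dplyr::row_number()),
                       .after = "plane")
  mk(out)
}

check_pits_pairing <- function(pits, model) {
  if (!identical(attr(pits, "tool_id"), model$tool_id) ||
      !identical(attr(pits, "n_model_points"), nrow(model$points)))
    abort("pits were detected on a different model",
          class = "percussr_pairing")
}

#' Measure pit depth below the encompassing convex hull
#'
#' For each member point the signed distance to the nearest point of the
#' hull surface is computed (negative = below the hull). `depth_mm` is the
#' mean member deviation and `depth_max_mm` the deepest-point deviation;
#' both are reported because distributional summaries of real assemblages
#' do not disclose which aggregation was used.
#'
#' @param pits a `percussr_pits` tibble.
#' @param hull the [compute_convex_hull()] of the same model.
#' @param model the `percussr_surface`.
#' @return `pits` with `depth_mm` and `depth_max_mm` columns added.
#' @export
measure_pit_depth <- function(pits, hull, model) {
  stopifnot(inherits(pits, "percussr_pits"), inherits(hull, "percussr_hull"))
  check_pits_pairing(pits, model)
  if (!identical(hull$tool_id, model$tool_id) ||
      !identical(hull$n_model_points, nrow(model$points)))
    abort("hull was computed from a different model",
          class = "percussr_pairing")
  if (nrow(pits) == 0)
    return(dplyr::mutate(pits, depth_mm = numeric(0),
                         depth_max_mm = numeric(0)))
  ds <- lapply(pits$point_idx, function(idx) {
    hull_signed_distance(hull, model$points[idx, , drop = FALSE])
  })
  pits$depth_mm <- vapply(ds, mean, 0)
  pits$depth_max_mm <- vapply(ds, min, 0)
  pits
}

# shared machinery for the two local-plane-fit measures
local_plane_stats <- function(model, radius, min_points) {
  idx <- active_idx(model)
  pts <- model$points[idx, , drop = FALSE]
  lp <- cpp_local_plane(pts, radius, as.integer(min_points))
  list(idx = idx, n = lp$n, slope = lp$slope, dist = lp$dist)
}

#' Measure pit gradient (slope)
#'
#' The gradient of a pit is the mean, over its member points, of the local
#' slope — the tangent of the dip angle of a least-squares plane fitted to
#' each point's neighbourhood ("ratio change of the elevation over
#' distance"). Plane fits are used instead of finite differences because
#' pointwise slopes on irregular clouds amplify noise.
#'
#' @param pits a `percussr_pits` tibble.
#' @param model the `percussr_surface`.
#' @param fit_radius plane-fit neighbourhood radius in mm.
#' @return `pits` with a `gradient` column (dimensionless, >= 0).
#' @export
measure_pit_gradient <- function(pits, model, fit_radius = 2) {
  stopifnot(inherits(pits, "percussr_pits"))
  check_pits_pairing(pits, model)
  if (nrow(pits) == 0) return(dplyr::mutate(pits, gradient = numeric(0)))
  lp <- local_plane_stats(model, fit_radius, 4L) # self + >= 3 neighbours
  pits$gradient <- vapply(pits$point_idx, function(idx) {
    s <- lp$slope[match(idx, lp$idx)]
    s <- s[!is.na(s) & is.finite(s)]
    if (length(s) == 0)
      abort("pit too sparse for gradient estimation (no point has 3 in-radius neighbours)",
            class = "percussr_insufficient")
    mean(s)
  }, 0)
  pits
}

#' Measure pit surface roughness
#'
#' Per-point roughness is the absolute distance from the point to the
#' least-squares plane of its neighbourhood within `window` mm; the small
#' default window (0.5 mm) separates grain-scale texture from the pit's
#' form. The pit value is the mean over members with a defined value.
#'
#' @param pits a `percussr_pits` tibble.
#' @param model the `percussr_surface`.
#' @param window neighbourhood window in mm.
#' @return `pits` with a `roughness_mm` column (>= 0).
#' @export
measure_pit_roughness <- function(pits, model, window = 0.5) {
  stopifnot(inherits(pits, "percussr_pits"))
  check_pits_pairing(pits, model)
  if (nrow(pits) == 0) return(dplyr::mutate(pits, roughness_mm = numeric(0)))
  lp <- local_plane_stats(model, window, 4L)
  pits$roughness_mm <- vapply(pits$point_idx, function(idx) {
    d <- lp$dist[match(idx, lp$idx)]
    d <- d[!is.na(d)]
    if (length(d) == 0)
      abort("scan too sparse for roughness at this window (no member has 4 in-window points)",
            class = "percussr_insufficient")
    mean(d)
  }, 0)
  pits
}

#' Run the full 3D pit morphometry chain on one model
#'
#' Convenience wrapper: TPI, detection, depth, gradient and roughness in
#' one call.
#'
#' @param model an oriented `percussr_surface`.
#' @param hull optional precomputed hull.
#' @param tpi_radius,threshold,linkage_radius,min_length,fit_radius,window
#'   passed to the stage functions.
#' @param roughness compute roughness (needs dense scans)? Default TRUE.
#' @return a measured `percussr_pits` tibble.
#' @export
measure_pits <- function(model, hull = NULL, tpi_radius = 20,
                         threshold = "auto", linkage_radius = NULL,
                         min_length = 10, fit_radius = 2, window = 0.5,
                         roughness = TRUE) {
  if (is.null(hull)) hull <- compute_convex_hull(model)
  tpi <- compute_tpi(model, radius = tpi_radius)
  pits <- detect_pit_regions(tpi, model, threshold = threshold,
                             linkage_radius = linkage_radius,
                             min_length = min_length)
  pits <- measure_pit_depth(pits, hull, model)
  pits <- measure_pit_gradient(pits, model, fit_radius = fit_radius)
  if (roughness) pits <- measure_pit_roughness(pits, model, window = window)
  pits
}
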