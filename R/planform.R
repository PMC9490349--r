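#' Extract the planform outline of an active surface
#'
#' Projects the points of one plane to (x, y) and traces their alpha-shape
#' boundary — the point-cloud equivalent of vectorising an orthomosaic of
#' the active surface. The default alpha of five median point spacings
#' keeps large smooth outlines closed while following genuine concavities.
#'
#' @param model an oriented [surface_model()].
#' @param plane plane label, default `"A"`.
#' @param alpha alpha radius in mm (`Inf` gives the convex hull); default
#'   five median point spacings.
#' @return an object of class `active_outline`: `polygon` (n x 2, mm,
#'   counter-clockwise), `area_cm2`, `centroid` (mm), `plane`, `tool_id`.
#' @export
extract_active_outline <- function(model, plane = "A", alpha = NULL) {
  stopifnot(inherits(model, "percussr_surface"))
  idx <- active_idx(model, plane)
  if (length(idx) < 3)
    abort("plane has fewer than 3 points", class = "percussr_degenerate")
  xy <- model$points[idx, 1:2, drop = FALSE]
  if (is.null(alpha)) alpha <- 5 * median_spacing(xy)
  if (!is.numeric(alpha) || alpha <= 0)
    abort("alpha must be positive", class = "percussr_parameter")
  poly <- alpha_shape(xy, alpha)
  structure(
    list(tool_id = model$tool_id, plane = plane, polygon = poly,
         area_cm2 = polygon_area(poly) / 100,
         centroid = polygon_centroid(poly), alpha = alpha),
    class = "active_outline"
  )
}

#' @export
print.active_outline <- function(x, ...) {
  cat(sprintf("<active_outline> %s plane %s: area %.2f cm^2, %d boundary vertices\n",
              x$tool_id, x$plane, x$area_cm2, nrow(x$polygon)))
  invisible(x)
}

#' Planform metrics of each pit
#'
#' Builds each pit's planform polygon (alpha shape of its member points,
#' two median spacings by default, falling back to the convex hull when the
#' membership is too sparse for a closed concave outline), then measures
#' its area, its minimum-area rotated rectangle (length >= width), and its
#' polygon centroid ("geometric centre"). Set `use_point_centroid = TRUE`
#' to keep the member mass centre instead of the polygon centroid.
#'
#' @param pits a `percussr_pits` tibble.
#' @param model the `percussr_surface`.
#' @param alpha alpha radius in mm; default two median point spacings of
#'   the active plane.
#' @param use_point_centroid use the member mean instead of the polygon
#'   centroid for `centroid_x/y`.
#' @return `pits` with `polygon` (list column), `area_cm2`, `length_mm`,
#'   `width_mm` added and `centroid_x/y` updated.
#' @export
pit_planform_metrics <- function(pits, model, alpha = NULL,
                                 use_point_centroid = FALSE) {
  stopifnot(inherits(pits, "percussr_pits"))
  check_pits_pairing(pits, model)
  if (nrow(pits) == 0) {
    return(dplyr::mutate(pits, polygon = list(), area_cm2 = numeric(0),
                         length_mm = numeric(0), width_mm = numeric(0)))
  }
  if (is.null(alpha)) {
    sp <- median_spacing(model$points[active_idx(model), 1:2, drop = FALSE])
    alpha <- 2 * sp
  }
  polys <- lapply(pits$point_idx, function(idx) {
    xy <- model$points[idx, 1:2, drop = FALSE]
    if (nrow(unique(xy)) < 3 || min_area_rect(xy)$width_mm < 1e-9)
      abort("pit members are collinear; no planform polygon",
            class = "percussr_degenerate")
    tryCatch(alpha_shape(xy, alpha),
             error = function(e) alpha_shape(xy, Inf))
  })
  bbs <- lapply(polys, function(p) min_area_rect(p))
  pits$polygon <- polys
  pits$area_cm2 <- vapply(polys, polygon_area, 0) / 100
  pits$length_mm <- vapply(bbs, `[[`, 0, "length_mm")
  pits$width_mm <- vapply(bbs, `[[`, 0, "width_mm")
  if (!use_point_centroid) {
    cts <- t(vapply(polys, polygon_centroid, numeric(2)))
    pits$centroid_x <- cts[, 1]
    pits$centroid_y <- cts[, 2]
  }
  pits
}

#' Surface-level damage summary: PA and pit density
#'
#' PA is the percentage of the active-surface area covered by pitting —
#' the area of the union of the pit polygons clipped to the outline (union,
#' so overlapping pits are not double-counted). D is the number of discrete
#' pits per cm^2 of active surface.
#'
#' @param pits a `percussr_pits` tibble with planform polygons (run
#'   [pit_planform_metrics()] first), or zero rows.
#' @param outline an [extract_active_outline()] result.
#' @return one-row tibble: `tool_id`, `plane`, `n_pits`, `area_cm2`
#'   (outline), `pa_percent`, `density_per_cm2`.
#' @export
surface_damage_summary <- function(pits, outline) {
  stopifnot(inherits(outline, "active_outline"))
  if (outline$area_cm2 <= 0)
    abort("outline has zero area", class = "percussr_degenerate")
  n <- nrow(pits)
  if (n == 0) {
    pa <- 0
  } else {
    if (!"polygon" %in% names(pits))
      abort("pits lack planform polygons; run pit_planform_metrics() first")
    covered_mm2 <- union_area_clipped(pits$polygon, outline$polygon)
    pa <- 100 * (covered_mm2 / 100) / outline$area_cm2
    if (covered_mm2 <= 0)
      warn("no pit polygon intersects the outline")
  }
  tibble::tibble(
    tool_id = outline$tool_id, plane = outline$plane,
    n_pits = as.integer(n), area_cm2 = outline$area_cm2,
    pa_percent = pa, density_per_cm2 = n / outline$area_cm2
  )
}

#' Pit position metrics: DAC and DAE
#'
#' DAC is the Euclidean distance from each pit's geometric centre to the
#' geometric centre of the active surface; DAE is the shortest distance
#' from the pit centre to the outline boundary.
#'
#' @param pits a `percussr_pits` tibble with centroids.
#' @param outline an [extract_active_outline()] result.
#' @return `pits` with `dac_mm` and `dae_mm` columns added (zero-row input
#'   passes through).
#' @export
pit_position_metrics <- function(pits, outline) {
  stopifnot(inherits(outline, "active_outline"))
  if (nrow(pits) == 0)
    return(dplyr::mutate(pits, dac_mm = numeric(0), dae_mm = numeric(0)))
  ctr <- outline$centroid
  pits$dac_mm <- sqrt((pits$centroid_x - ctr[1])^2 +
                        (pits$centroid_y - ctr[2])^2)
  pits$dae_mm <- vapply(seq_len(nrow(pits)), function(i) {
    point_to_boundary_dist(c(pits$centroid_x[i], pits$centroid_y[i]),
                           outline$polygon)
  }, 0)
  pits
}

#' Full planform summary of one active surface
#'
#' Combines [surface_damage_summary()] with min/mean/max summaries of DAC
#' and DAE. With zero pits the DAC/DAE summaries are `NA` (flagged
#' undefined), PA and D are 0.
#'
#' @param pits a measured `percussr_pits` tibble (with polygons and
#'   positions; they are computed here if missing).
#' @param outline an [extract_active_outline()] result.
#' @param model the `percussr_surface` (needed only if polygons/positions
#'   are still missing).
#' @return one-row tibble with columns `tool_id`, `plane`, `n_pits`,
#'   `area_cm2`, `pa_percent`, `density_per_cm2`, `dac_min_mm`,
#'   `dac_mean_mm`, `dac_max_mm`, `dae_min_mm`, `dae_mean_mm`,
#'   `dae_max_mm`.
#' @export
planform_summary <- function(pits, outline, model = NULL) {
  if (nrow(pits) > 0 && !"polygon" %in% names(pits)) {
    if (is.null(model))
      abort("pits lack polygons; supply the model or run pit_planform_metrics()")
    pits <- pit_planform_metrics(pits, model)
  }
  if (nrow(pits) > 0 && !"dac_mm" %in% names(pits))
    pits <- pit_position_metrics(pits, outline)
  base <- surface_damage_summary(pits, outline)
  if (nrow(pits) == 0) {
    pos <- tibble::tibble(dac_min_mm = NA_real_, dac_mean_mm = NA_real_,
                          dac_max_mm = NA_real_, dae_min_mm = NA_real_,
                          dae_mean_mm = NA_real_, dae_max_mm = NA_real_)
  } else {
    pos <- tibble::tibble(
      dac_min_mm = min(pits$dac_mm), dac_mean_mm = mean(pits$dac_mm),
      dac_max_mm = max(pits$dac_mm), dae_min_mm = min(pits$dae_mm),
      dae_mean_mm = mean(pits$dae_mm), dae_max_mm = max(pits$dae_mm)
    )
  }
  dplyr::bind_cols(base, pos)
}
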