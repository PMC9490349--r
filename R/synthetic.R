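# Synthetic surfaces and assemblages with known ground truth. These are the
# package's validation instruments: tabular blocks with one flat active
# face, discrete concave pits of known centre/radius/depth, and additive
# grain noise whose amplitude follows the raw-material grain ranking.

# run code under a temporary RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Grain-noise presets by raw material
#'
#' Surface noise standard deviations (mm) monotone in the qualitative grain
#' ranking of the raw materials: granodiorite (medium grain) < quartzite
#' (coarse) < metamorphosed granite (very coarse). Magnitudes are the
#' package's own modelling choices.
#' @return named numeric vector.
#' @export
material_noise_sd <- function() c(GD = 0.05, Q = 0.15, MG = 0.25)

#' Specify a synthetic tool surface
#'
#' A tabular block with its length along Y, width along X, thickness along
#' Z, the flat active face on top (z = 0), and discrete concave pits carved
#' into it.
#'
#' @param length_mm,width_mm,thickness_mm block dimensions.
#' @param pits data frame with columns `x`, `y` (centre, mm; origin at the
#'   face centre), `radius_mm`, `depth_mm` and optionally `profile`
#'   (`"spherical_cap"` or `"gaussian"`). `NULL` for an undamaged block.
#' @param raw_material `"GD"`, `"Q"` or `"MG"` — sets the grain-noise
#'   preset unless `grain_noise_sd` is given.
#' @param grain_noise_sd noise sd in mm (0 = noiseless).
#' @param density_per_cm2 sampling density; the default 1000 points/cm^2 is
#'   a desk-scale stand-in for full photogrammetric density.
#' @param base_curvature_mm optional dome radius: the top face bulges as a
#'   spherical cap of this radius instead of being perfectly flat.
#' @param seed integer seed; identical specs with identical seeds generate
#'   bitwise-identical surfaces.
#' @param tool_id identifier.
#' @return an object of class `surface_spec`.
#' @export
surface_spec <- function(length_mm = 160, width_mm = 120, thickness_mm = 40,
                         pits = NULL, raw_material = "GD",
                         grain_noise_sd = NULL, density_per_cm2 = 1000,
                         base_curvature_mm = NULL, seed = 1L,
                         tool_id = "synthetic") {
  if (length_mm <= 0 || width_mm <= 0 || thickness_mm <= 0)
    abort("block dimensions must be positive", class = "percussr_parameter")
  if (density_per_cm2 <= 0)
    abort("density must be positive", class = "percussr_parameter")
  if (is.null(grain_noise_sd)) {
    preset <- material_noise_sd()
    if (!raw_material %in% names(preset))
      abort("unknown raw material (use GD, Q or MG, or give grain_noise_sd)",
            class = "percussr_parameter")
    grain_noise_sd <- unname(preset[raw_material])
  }
  if (grain_noise_sd < 0)
    abort("grain_noise_sd must be >= 0", class = "percussr_parameter")
  if (is.null(pits)) {
    pits <- tibble::tibble(x = numeric(), y = numeric(),
                           radius_mm = numeric(), depth_mm = numeric(),
                           profile = character())
  } else {
    pits <- tibble::as_tibble(pits)
    if (!"profile" %in% names(pits))
      pits$profile <- rep("spherical_cap", nrow(pits))
    need <- c("x", "y", "radius_mm", "depth_mm")
    if (!all(need %in% names(pits)))
      abort("pits need columns x, y, radius_mm, depth_mm",
            class = "percussr_parameter")
    if (any(pits$depth_mm <= 0) || any(pits$radius_mm <= 0))
      abort("pit radius and depth must be positive",
            class = "percussr_parameter")
    if (any(abs(pits$x) + pits$radius_mm > width_mm / 2) ||
        any(abs(pits$y) + pits$radius_mm > length_mm / 2))
      abort("pits must lie within the top face", class = "percussr_parameter")
    if (!all(pits$profile %in% c("spherical_cap", "gaussian")))
      abort("profile must be spherical_cap or gaussian",
            class = "percussr_parameter")
  }
  structure(
    list(length_mm = length_mm, width_mm = width_mm,
         thickness_mm = thickness_mm, pits = pits,
         raw_material = raw_material, grain_noise_sd = grain_noise_sd,
         density_per_cm2 = density_per_cm2,
         base_curvature_mm = base_curvature_mm,
         seed = as.integer(seed), tool_id = tool_id),
    class = "surface_spec"
  )
}

# depth of the carved surface below z = 0 at planimetric radius r from a
# pit centre (positive value = material removed)
pit_profile_depth <- function(r, radius, depth, profile) {
  out <- numeric(length(r))
  inside <- r < radius
  if (profile == "spherical_cap") {
    R <- (radius^2 + depth^2) / (2 * depth) # sphere radius through the rim
    out[inside] <- sqrt(R^2 - r[inside]^2) - (R - depth)
  } else {
    s <- radius / 2
    e2 <- exp(-2)
    out[inside] <- depth * (exp(-r[inside]^2 / (2 * s^2)) - e2) / (1 - e2)
  }
  out
}

#' Generate a synthetic tool surface
#'
#' Samples points uniformly on all six faces of the block at the requested
#' density, carves each pit by its profile (overlapping pits excavate their
#' union — merged pits are a legitimate outcome and raise a warning), and
#' adds Gaussian grain noise along each face normal. The returned model is
#' already oriented (length on Y, active face A up) with plane labels set
#' by construction.
#'
#' @param spec a [surface_spec()].
#' @return a list of class `synthetic_surface`: `model` (a
#'   `percussr_surface`), `ground_truth` (tibble: pit_id, x, y, radius_mm,
#'   depth_mm, profile, area_cm2), `spec`.
#' @export
generate_surface <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  L <- spec$length_mm; W <- spec$width_mm; TT <- spec$thickness_mm
  dens <- spec$density_per_cm2 / 100 # points per mm^2
  np <- nrow(spec$pits)
  if (np > 1) {
    dd <- as.matrix(stats::dist(cbind(spec$pits$x, spec$pits$y)))
    rr <- outer(spec$pits$radius_mm, spec$pits$radius_mm, "+")
    if (any(dd[upper.tri(dd)] < rr[upper.tri(rr)]))
      warn("pits overlap; closely located pits will merge into one region")
  }
  local_seed(spec$seed, {
    n_top <- max(20, round(L * W * dens))
    n_side_x <- max(5, round(L * TT * dens)) # C / C2
    n_side_y <- max(5, round(W * TT * dens)) # B / B2
    rxy <- function(n) cbind(runif(n, -W / 2, W / 2), runif(n, -L / 2, L / 2))
    top <- rxy(n_top)
    bot <- rxy(n_top)
    zt0 <- numeric(n_top)
    if (!is.null(spec$base_curvature_mm)) {
      # gentle spherical doming of the active face, apex at z = 0
      Rc <- spec$base_curvature_mm
      r2 <- top[, 1]^2 + top[, 2]^2
      zt0 <- sqrt(pmax(Rc^2 - r2, 0)) - Rc
    }
    zt <- zt0
    for (k in seq_len(np)) {
      r <- sqrt((top[, 1] - spec$pits$x[k])^2 + (top[, 2] - spec$pits$y[k])^2)
      carve <- pit_profile_depth(r, spec$pits$radius_mm[k],
                                 spec$pits$depth_mm[k], spec$pits$profile[k])
      zt <- pmin(zt, zt0 - carve) # overlapping pits excavate their union
    }
    sigma <- spec$grain_noise_sd
    noise <- function(n) if (sigma > 0) rnorm(n, 0, sigma) else numeric(n)
    pts_top <- cbind(top[, 1], top[, 2], zt + noise(n_top))
    pts_bot <- cbind(bot[, 1], bot[, 2], -TT + noise(n_top))
    sx1 <- cbind(W / 2 + noise(n_side_x), runif(n_side_x, -L / 2, L / 2),
                 runif(n_side_x, -TT, 0))
    sx2 <- cbind(-W / 2 + noise(n_side_x), runif(n_side_x, -L / 2, L / 2),
                 runif(n_side_x, -TT, 0))
    sy1 <- cbind(runif(n_side_y, -W / 2, W / 2), L / 2 + noise(n_side_y),
                 runif(n_side_y, -TT, 0))
    sy2 <- cbind(runif(n_side_y, -W / 2, W / 2), -L / 2 + noise(n_side_y),
                 runif(n_side_y, -TT, 0))
    pts <- rbind(pts_top, pts_bot, sx1, sx2, sy1, sy2)
    plane <- c(rep("A", n_top), rep("A2", n_top),
               rep("C", n_side_x), rep("C2", n_side_x),
               rep("B", n_side_y), rep("B2", n_side_y))
    model <- surface_model(pts, tool_id = spec$tool_id, plane = plane,
                           active_planes = "A", oriented = TRUE)
    gt <- tibble::tibble(
      pit_id = sprintf("gt_%02d", seq_len(np)),
      x = spec$pits$x, y = spec$pits$y,
      radius_mm = spec$pits$radius_mm, depth_mm = spec$pits$depth_mm,
      profile = spec$pits$profile,
      area_cm2 = pi * spec$pits$radius_mm^2 / 100
    )
    structure(list(model = model, ground_truth = gt, spec = spec),
              class = "synthetic_surface")
  })
}

#' Group effect configuration for synthetic assemblages
#'
#' Defaults mirror the contrasts reported for nut-cracking tools: anvils
#' carry more pits (Poisson mean 11.6 vs 1.3), deeper pits (lognormal
#' median 15.5 vs 4.3 mm), larger pits, and their pits are dispersed across
#' the active surface while hammerstone damage is central. Tool dimensions
#' follow the published assemblage means.
#'
#' @param pit_count_mean,depth_median_mm,depth_sdlog,radius_median_mm,
#'   radius_sdlog,placement,central_sd_frac,dims_mm,dim_cv,
#'   raw_material_prob,nut_prob see defaults.
#' @return an object of class `assemblage_effects`.
#' @export
assemblage_effects <- function(
    pit_count_mean = c(hammer = 1.3, anvil = 11.6),
    depth_median_mm = c(hammer = 4.3, anvil = 15.5),
    depth_sdlog = 0.5,
    radius_median_mm = c(hammer = 27, anvil = 38),
    radius_sdlog = 0.35,
    placement = c(hammer = "central", anvil = "dispersed"),
    central_sd_frac = 0.12,
    dims_mm = list(hammer = c(224, 178, 117), anvil = c(644, 345, 200)),
    dim_cv = 0.25,
    raw_material_prob = list(hammer = c(Q = 5, GD = 4, MG = 2) / 11,
                             anvil = c(MG = 6, GD = 1) / 7),
    nut_prob = list(hammer = c(coula = 3, panda = 6, parinari = 2) / 11,
                    anvil = c(panda = 5, parinari = 1, sacaglottis = 1) / 7)) {
  if (any(pit_count_mean < 0) || any(depth_median_mm <= 0) ||
      any(radius_median_mm <= 0) || depth_sdlog < 0 || radius_sdlog < 0 ||
      dim_cv < 0)
    abort("invalid distribution parameters", class = "percussr_parameter")
  structure(
    list(pit_count_mean = pit_count_mean,
         depth_median_mm = depth_median_mm, depth_sdlog = depth_sdlog,
         radius_median_mm = radius_median_mm, radius_sdlog = radius_sdlog,
         placement = placement, central_sd_frac = central_sd_frac,
         dims_mm = dims_mm, dim_cv = dim_cv,
         raw_material_prob = raw_material_prob, nut_prob = nut_prob),
    class = "assemblage_effects"
  )
}

#' Generate a synthetic assemblage with known group structure
#'
#' Draws per-tool metadata (dimensions, raw material, nut species) and pit
#' configurations (count, radius, depth, placement) from the effect
#' configuration, computes the per-tool use-wear summary table analytically
#' over the rectangular active face (PA from summed pit areas capped at
#' 100, DAC/DAE from pit centres), and optionally renders each tool as a
#' synthetic point-cloud surface for full-pipeline runs.
#'
#' @param n_hammers,n_anvils tool counts (>= 0).
#' @param effects an [assemblage_effects()].
#' @param seed integer seed; identical seeds give identical assemblages.
#' @param surfaces also generate point-cloud surfaces?
#' @param density_per_cm2 sampling density for surfaces.
#' @param size_scale scale factor applied to tool dimensions, pit radii and
#'   placements (not depths) when rendering surfaces — keeps full-pipeline
#'   validation desk-scale.
#' @return a list of class `synthetic_assemblage`: `tools` (per-tool
#'   metadata tibble), `wear` (per-tool use-wear summary in the
#'   [comparison_variables()] schema), `pits` (ground-truth pit table),
#'   `surfaces` (named list or NULL), `effects`, `seed`.
#' @export
generate_assemblage <- function(n_hammers = 11, n_anvils = 7,
                                effects = assemblage_effects(), seed = 1L,
                                surfaces = FALSE, density_per_cm2 = 200,
                                size_scale = 1) {
  stopifnot(inherits(effects, "assemblage_effects"))
  if (n_hammers < 0 || n_anvils < 0)
    abort("tool counts must be >= 0", class = "percussr_parameter")
  n_tot <- n_hammers + n_anvils
  if (n_tot == 0) abort("empty assemblage", class = "percussr_parameter")
  types <- c(rep("hammer", n_hammers), rep("anvil", n_anvils))
  ids <- c(sprintf("H%02d", seq_len(n_hammers)),
           sprintf("A%02d", seq_len(n_anvils)))
  sdlog_dim <- sqrt(log(1 + effects$dim_cv^2))

  local_seed(as.integer(seed), {
    tool_rows <- vector("list", n_tot)
    pit_rows <- vector("list", n_tot)
    wear_rows <- vector("list", n_tot)
    for (i in seq_len(n_tot)) {
      ty <- types[i]
      mdims <- effects$dims_mm[[ty]]
      dims <- rlnorm(3, log(mdims) - sdlog_dim^2 / 2, sdlog_dim)
      if (dims[2] > dims[1]) dims[1:2] <- dims[2:1] # length >= breadth
      L <- dims[1]; W <- dims[2]; TT <- dims[3]
      rmp <- effects$raw_material_prob[[ty]]
      rm_i <- sample(names(rmp), 1, prob = rmp)
      nutp <- effects$nut_prob[[ty]]
      nut_i <- sample(names(nutp), 1, prob = nutp)
      vol <- if (ty == "hammer") 0.45 * L * W * TT / 1000 else NA_real_
      mass <- if (ty == "hammer") 2.7 * vol else NA_real_

      k <- rpois(1, effects$pit_count_mean[[ty]])
      rad <- rlnorm(k, log(effects$radius_median_mm[[ty]]),
                    effects$radius_sdlog)
      rad <- pmin(rad, 0.4 * min(L, W) / 2)
      dep <- rlnorm(k, log(effects$depth_median_mm[[ty]]),
                    effects$depth_sdlog)
      if (k > 0) {
        mx <- pmax(W / 2 - rad, 0)
        my <- pmax(L / 2 - rad, 0)
        if (effects$placement[[ty]] == "central") {
          px <- pmax(-mx, pmin(mx, rnorm(k, 0, effects$central_sd_frac * W)))
          py <- pmax(-my, pmin(my, rnorm(k, 0, effects$central_sd_frac * L)))
        } else {
          px <- runif(k, -mx, mx)
          py <- runif(k, -my, my)
        }
      } else px <- py <- numeric(0)

      tool_rows[[i]] <- tibble::tibble(
        tool_id = ids[i], tool_type = ty, raw_material = rm_i,
        nut_species = nut_i, max_length_mm = L, max_breadth_mm = W,
        max_thickness_mm = TT, volume_cm3 = vol, mass_g = mass,
        n_discrete_use_wear = k, n_active_planes = 1L
      )
      pit_rows[[i]] <- tibble::tibble(
        tool_id = ids[i], pit_id = sprintf("%s_p%02d", ids[i], seq_len(k)),
        x = px, y = py, radius_mm = rad, depth_mm = dep
      )
      area_cm2 <- L * W / 100
      if (k > 0) {
        dac <- sqrt(px^2 + py^2)
        dae <- pmin(W / 2 - abs(px), L / 2 - abs(py))
        pa <- min(100, 100 * sum(pi * rad^2) / (L * W))
        pos <- c(min(dac), mean(dac), max(dac),
                 min(dae), mean(dae), max(dae))
      } else {
        pa <- 0
        pos <- rep(NA_real_, 6)
      }
      wear_rows[[i]] <- tibble::tibble(
        tool_id = ids[i], tool_type = ty,
        n_discrete_use_wear = k, pa_percent = pa,
        density_per_cm2 = k / area_cm2, area_cm2 = area_cm2,
        dac_min_mm = pos[1], dac_mean_mm = pos[2], dac_max_mm = pos[3],
        dae_min_mm = pos[4], dae_mean_mm = pos[5], dae_max_mm = pos[6],
        mean_depth_mm = if (k > 0) mean(dep) else NA_real_,
        max_depth_mm = if (k > 0) max(dep) else NA_real_
      )
    }
    tools <- dplyr::bind_rows(tool_rows)
    pits <- dplyr::bind_rows(pit_rows)
    wear <- dplyr::bind_rows(wear_rows)

    surf <- NULL
    if (surfaces) {
      surf <- vector("list", n_tot)
      names(surf) <- ids
      sub_seeds <- sample.int(.Machine$integer.max, n_tot)
      for (i in seq_len(n_tot)) {
        tp <- pits[pits$tool_id == ids[i], ]
        s <- size_scale
        spec <- surface_spec(
          length_mm = tools$max_length_mm[i] * s,
          width_mm = tools$max_breadth_mm[i] * s,
          thickness_mm = tools$max_thickness_mm[i] * s,
          pits = if (nrow(tp) == 0) NULL else
            tibble::tibble(x = tp$x * s, y = tp$y * s,
                           radius_mm = tp$radius_mm * s,
                           depth_mm = tp$depth_mm),
          raw_material = tools$raw_material[i],
          density_per_cm2 = density_per_cm2,
          seed = sub_seeds[i], tool_id = ids[i]
        )
        surf[[i]] <- suppressWarnings(generate_surface(spec))
      }
    }
    structure(
      list(tools = tools, wear = wear, pits = pits, surfaces = surf,
           effects = effects, seed = as.integer(seed),
           size_scale = size_scale),
      class = "synthetic_assemblage"
    )
  })
}
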