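#' Pipeline configuration
#'
#' Collects the tunable constants of the analysis: the TPI neighbourhood
#' radius (20 mm), roughness window (0.5 mm), minimum pit length (10 mm),
#' the depression threshold ("auto" = noise-adaptive), the plane-fit radius
#' for gradients, alpha-shape radii, and the significance level (0.05).
#'
#' @param tpi_radius,roughness_window,min_pit_length,depression_threshold,
#'   linkage_radius,fit_radius,alpha_outline,alpha_pit,alpha_level,seed,
#'   roughness see defaults; `NULL` alphas/linkage mean "derive from point
#'   spacing".
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(tpi_radius = 20, roughness_window = 0.5,
                            min_pit_length = 10,
                            depression_threshold = "auto",
                            linkage_radius = NULL, fit_radius = 2,
                            alpha_outline = NULL, alpha_pit = NULL,
                            alpha_level = 0.05, seed = 1L,
                            roughness = TRUE) {
  num_pos <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || x <= 0))
      abort(paste(nm, "must be a positive number"),
            class = "percussr_parameter")
  }
  num_pos(tpi_radius, "tpi_radius")
  num_pos(roughness_window, "roughness_window")
  num_pos(min_pit_length, "min_pit_length")
  num_pos(fit_radius, "fit_radius")
  num_pos(linkage_radius, "linkage_radius")
  num_pos(alpha_outline, "alpha_outline")
  num_pos(alpha_pit, "alpha_pit")
  if (!identical(depression_threshold, "auto"))
    num_pos(depression_threshold, "depression_threshold")
  if (!is.numeric(alpha_level) || alpha_level <= 0 || alpha_level >= 1)
    abort("alpha_level must be in (0, 1)", class = "percussr_parameter")
  structure(
    list(tpi_radius = tpi_radius, roughness_window = roughness_window,
         min_pit_length = min_pit_length,
         depression_threshold = depression_threshold,
         linkage_radius = linkage_radius, fit_radius = fit_radius,
         alpha_outline = alpha_outline, alpha_pit = alpha_pit,
         alpha_level = alpha_level, seed = as.integer(seed),
         roughness = roughness),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "auto (from point spacing)" else
                  paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

config_lines <- function(config) {
  vapply(names(config), function(nm) {
    v <- config[[nm]]
    sprintf("param %s = %s", nm,
            if (is.null(v)) "auto" else paste(format(v), collapse = ","))
  }, "")
}

#' Analyse one tool surface end to end
#'
#' Hull, TPI, pit detection, 3D morphometrics, planform polygons and the
#' per-surface summary in one call.
#'
#' @param model an oriented `percussr_surface`.
#' @param config a [pipeline_config()].
#' @return list with `pits` (measured tibble), `outline`, `summary`
#'   (one-row tibble).
#' @export
analyze_surface <- function(model, config = pipeline_config()) {
  stopifnot(inherits(model, "percussr_surface"))
  hull <- compute_convex_hull(model)
  tpi <- compute_tpi(model, radius = config$tpi_radius)
  pits <- detect_pit_regions(tpi, model,
                             threshold = config$depression_threshold,
                             linkage_radius = config$linkage_radius,
                             min_length = config$min_pit_length)
  pits <- measure_pit_depth(pits, hull, model)
  pits <- measure_pit_gradient(pits, model, fit_radius = config$fit_radius)
  if (isTRUE(config$roughness))
    pits <- measure_pit_roughness(pits, model,
                                  window = config$roughness_window)
  pits <- pit_planform_metrics(pits, model, alpha = config$alpha_pit)
  outline <- extract_active_outline(model, plane = model$active_planes[1],
                                    alpha = config$alpha_outline)
  pits <- pit_position_metrics(pits, outline)
  summary <- planform_summary(pits, outline)
  if (nrow(pits) > 0) {
    summary$mean_depth_mm <- mean(abs(pits$depth_max_mm))
    summary$max_depth_mm <- max(abs(pits$depth_max_mm))
    summary$mean_gradient <- mean(pits$gradient)
  } else {
    summary$mean_depth_mm <- NA_real_
    summary$max_depth_mm <- NA_real_
    summary$mean_gradient <- NA_real_
  }
  list(pits = pits, outline = outline, summary = summary)
}

#' Run the full analysis pipeline over a set of tools
#'
#' Analyses every surface, writes the per-pit table, the per-surface
#' summary table, an optional hammer-vs-anvil comparison table, and a log
#' that echoes every effective parameter value — identical inputs, config
#' and seed produce byte-identical outputs. Any stage failure is reported
#' with its stage name and tool id, and no partial outputs are left behind.
#'
#' @param models named list of oriented `percussr_surface` objects, a
#'   `synthetic_assemblage` with surfaces, or a character vector of scan
#'   file paths (read with [read_surface()] and oriented).
#' @param output_dir directory for the report bundle (created).
#' @param config a [pipeline_config()].
#' @param metadata optional tibble with `tool_id` and `tool_type` enabling
#'   the comparison stage.
#' @return invisibly, a list with `results` (per-tool), `summary` (tibble),
#'   `comparison` (or NULL) and `paths`.
#' @export
run_pipeline <- function(models, output_dir, config = pipeline_config(),
                         metadata = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(models, "synthetic_assemblage")) {
    if (is.null(models$surfaces))
      abort("assemblage has no surfaces; regenerate with surfaces = TRUE")
    metadata <- metadata %||% models$tools[, c("tool_id", "tool_type")]
    models <- lapply(models$surfaces, `[[`, "model")
  }
  if (is.character(models)) {
    missing_files <- models[!file.exists(models)]
    if (length(missing_files) > 0)
      abort(paste0("input file(s) not found: ",
                   paste(missing_files, collapse = ", ")),
            class = "percussr_io")
    models <- lapply(models, function(p) orient_model(read_surface(p)))
  }
  if (!all(vapply(models, inherits, TRUE, "percussr_surface")))
    abort("models must be percussr_surface objects")
  ids <- vapply(models, `[[`, "", "tool_id")
  if (is.null(names(models))) names(models) <- ids

  log_lines <- c(sprintf("percussr pipeline, %d tool(s)", length(models)),
                 config_lines(config))
  results <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    results[[i]] <- tryCatch(
      analyze_surface(m, config),
      error = function(e) {
        abort(sprintf("pipeline failed at stage 'analyze' for tool '%s': %s",
                      m$tool_id, conditionMessage(e)),
              class = "percussr_pipeline")
      }
    )
    log_lines <- c(log_lines,
                   sprintf("tool %s: %d pit(s), outline %.2f cm^2",
                           m$tool_id, nrow(results[[i]]$pits),
                           results[[i]]$outline$area_cm2))
  }
  summary <- dplyr::bind_rows(lapply(results, `[[`, "summary"))
  pits_all <- dplyr::bind_rows(lapply(results, function(r) {
    if (nrow(r$pits) == 0) return(NULL)
    dplyr::select(r$pits, -dplyr::any_of(c("point_idx", "polygon")))
  }))

  comparison <- NULL
  if (!is.null(metadata) && "tool_type" %in% names(metadata)) {
    st <- dplyr::left_join(summary, metadata, by = "tool_id")
    st$n_discrete_use_wear <- st$n_pits
    ty <- unique(st$tool_type)
    if (all(c("hammer", "anvil") %in% ty)) {
      vars <- intersect(comparison_variables(), names(st))
      comparison <- tryCatch(
        compare_assemblages(
          st[st$tool_type == "hammer", ], st[st$tool_type == "anvil", ],
          variables = vars, labels = c("hammer", "anvil"),
          alpha = config$alpha_level
        ),
        error = function(e) {
          log_lines <<- c(log_lines,
                          paste("comparison skipped:", conditionMessage(e)))
          NULL
        }
      )
      if (!is.null(comparison)) log_lines <- c(log_lines,
                     sprintf("comparison: %d variables, %d significant at alpha=%g",
                             nrow(comparison$tests),
                             sum(comparison$tests$significant),
                             config$alpha_level))
    }
  }

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    pits = file.path(output_dir, "pits.csv"),
    summary = file.path(output_dir, "surface_summary.csv"),
    comparison = file.path(output_dir, "comparison.csv"),
    log = file.path(output_dir, "pipeline_log.txt")
  )
  write_pit_table(pits_all, summary, paths$pits)
  utils::write.csv(summary, paths$summary, row.names = FALSE)
  if (!is.null(comparison)) {
    utils::write.csv(comparison$tests, paths$comparison, row.names = FALSE)
  } else paths$comparison <- NULL
  writeLines(log_lines, paths$log)
  invisible(list(results = results, summary = summary,
                 comparison = comparison, paths = paths))
}
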