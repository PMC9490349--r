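#' Read a 3D surface scan
#'
#' Reads PLY (ASCII or binary little-endian), OBJ, or XYZ point clouds into
#' an (unoriented) [surface_model()]. XYZ files are whitespace- or
#' comma-delimited three-column text with an optional header line, the
#' dialect common for field-collected clouds. Coordinates are taken to be
#' in mm.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"ply"`, `"obj"`, `"xyz"`; `"auto"` uses
#'   the file extension.
#' @param tool_id identifier; defaults to the file name without extension.
#' @return a `percussr_surface` (unoriented).
#' @export
read_surface <- function(path, format = c("auto", "ply", "obj", "xyz"),
                         tool_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "percussr_io")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", obj = "obj", xyz = "xyz",
                     txt = "xyz", csv = "xyz",
                     abort(paste0("cannot infer format from extension: ", ext),
                           class = "percussr_io"))
  }
  if (is.null(tool_id))
    tool_id <- tools::file_path_sans_ext(basename(path))
  parsed <- switch(format,
                   ply = read_ply(path),
                   obj = read_obj(path),
                   xyz = list(points = read_xyz(path), faces = NULL))
  surface_model(parsed$points, faces = parsed$faces, tool_id = tool_id)
}

#' Write a surface model to disk
#'
#' @param model a `percussr_surface`.
#' @param path output path.
#' @param format `"ply"` (ASCII), `"obj"`, or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(model, path, format = c("xyz", "ply", "obj")) {
  stopifnot(inherits(model, "percussr_surface"))
  format <- match.arg(format)
  pts <- model$points
  fmt_num <- function(v) formatC(v, digits = 17, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    writeLines(paste(fmt_num(pts[, 1]), fmt_num(pts[, 2]), fmt_num(pts[, 3])),
               con)
  } else if (format == "obj") {
    writeLines(paste("v", fmt_num(pts[, 1]), fmt_num(pts[, 2]),
                     fmt_num(pts[, 3])), con)
    if (!is.null(model$faces))
      writeLines(paste("f", model$faces[, 1], model$faces[, 2],
                       model$faces[, 3]), con)
  } else {
    nf <- if (is.null(model$faces)) 0L else nrow(model$faces)
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(pts)),
                 "property double x", "property double y", "property double z",
                 paste("element face", nf),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(paste(fmt_num(pts[, 1]), fmt_num(pts[, 2]), fmt_num(pts[, 3])),
               con)
    if (nf > 0)
      writeLines(paste(3L, model$faces[, 1] - 1L, model$faces[, 2] - 1L,
                       model$faces[, 3] - 1L), con)
  }
  invisible(path)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty XYZ file", class = "percussr_malformed")
  parse_line <- function(l) {
    strsplit(trimws(l), "[,;[:space:]]+")[[1]]
  }
  first <- suppressWarnings(as.numeric(parse_line(lines[1])))
  if (anyNA(first)) lines <- lines[-1] # header line
  toks <- lapply(lines, parse_line)
  if (any(vapply(toks, length, 0L) < 3))
    abort("XYZ rows must have at least 3 fields", class = "percussr_malformed")
  m <- t(vapply(toks, function(t) suppressWarnings(as.numeric(t[1:3])),
                numeric(3)))
  if (anyNA(m))
    abort("non-numeric coordinate in XYZ file", class = "percussr_malformed")
  m
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0) abort("no vertices in OBJ", class = "percussr_malformed")
  pts <- t(vapply(strsplit(trimws(sub("^v", "", vl)), "[[:space:]]+"),
                  function(t) as.numeric(t[t != ""][1:3]), numeric(3)))
  faces <- NULL
  if (length(fl) > 0) {
    fx <- lapply(strsplit(trimws(sub("^f", "", fl)), "[[:space:]]+"),
                 function(t) {
                   t <- t[t != ""]
                   as.integer(sub("/.*$", "", t))
                 })
    if (any(vapply(fx, length, 0L) != 3))
      abort("only triangular OBJ faces are supported",
            class = "percussr_malformed")
    faces <- do.call(rbind, fx)
  }
  list(points = pts, faces = faces)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    l <- readLines(con, n = 1)
    if (length(l) == 0) abort("truncated PLY header", class = "percussr_malformed")
    header <- c(header, l)
    if (trimws(l) == "end_header") break
  }
  if (!grepl("^ply", header[1]))
    abort("not a PLY file", class = "percussr_malformed")
  fmt <- header[grepl("^format", header)][1]
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    abort("unsupported PLY format (big-endian)", class = "percussr_malformed")

  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (l in header) {
    t <- strsplit(trimws(l), "[[:space:]]+")[[1]]
    if (t[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = t[2], count = as.integer(t[3]), props = list())
    } else if (t[1] == "property" && !is.null(cur)) {
      if (t[2] == "list") {
        cur$props[[t[5]]] <- list(list = TRUE, count_type = t[3], type = t[4])
      } else {
        cur$props[[t[3]]] <- list(list = FALSE, type = t[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex))
    abort("PLY has no vertex element", class = "percussr_malformed")

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_bin_scalar <- function(type, n = 1) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n = n, size = sz, endian = "little")
    else
      readBin(con, "integer", n = n, size = sz,
              signed = !(sz <= 2 && grepl("^u", type)), endian = "little")
  }

  pts <- NULL; faces <- NULL
  if (binary) {
    for (el in elements) {
      pn <- names(el$props)
      if (el$name == "vertex" && !any(vapply(el$props, `[[`, TRUE, "list"))) {
        types <- vapply(el$props, `[[`, "", "type")
        if (length(unique(types)) == 1) {
          vals <- read_bin_scalar(types[1], n = el$count * length(pn))
          m <- matrix(vals, ncol = length(pn), byrow = TRUE)
        } else {
          m <- matrix(0, el$count, length(pn))
          for (i in seq_len(el$count))
            for (j in seq_along(pn)) m[i, j] <- read_bin_scalar(types[j])
        }
        colnames(m) <- pn
        pts <- m[, c("x", "y", "z"), drop = FALSE]
      } else {
        rows <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          row <- list()
          for (j in seq_along(el$props)) {
            pr <- el$props[[j]]
            if (pr$list) {
              k <- read_bin_scalar(pr$count_type)
              row[[pn[j]]] <- read_bin_scalar(pr$type, n = k)
            } else row[[pn[j]]] <- read_bin_scalar(pr$type)
          }
          rows[[i]] <- row
        }
        if (el$name == "face" && el$count > 0) {
          key <- intersect(c("vertex_indices", "vertex_index"), pn)[1]
          fl <- lapply(rows, `[[`, key)
          if (any(vapply(fl, length, 0L) != 3))
            abort("only triangular PLY faces are supported",
                  class = "percussr_malformed")
          faces <- do.call(rbind, fl) + 1L
        }
      }
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    pos <- 0
    for (el in elements) {
      block <- body[pos + seq_len(el$count)]
      pos <- pos + el$count
      toks <- strsplit(trimws(block), "[[:space:]]+")
      if (el$name == "vertex") {
        pn <- names(el$props)
        m <- t(vapply(toks, function(t) as.numeric(t[seq_along(pn)]),
                      numeric(length(pn))))
        colnames(m) <- pn
        if (anyNA(m[, c("x", "y", "z")]))
          abort("non-numeric vertex in PLY", class = "percussr_malformed")
        pts <- m[, c("x", "y", "z"), drop = FALSE]
      } else if (el$name == "face" && el$count > 0) {
        fl <- lapply(toks, function(t) {
          k <- as.integer(t[1])
          as.integer(t[1 + seq_len(k)])
        })
        if (any(vapply(fl, length, 0L) != 3))
          abort("only triangular PLY faces are supported",
                class = "percussr_malformed")
        faces <- do.call(rbind, fl) + 1L
      }
    }
  }
  if (is.null(pts) || nrow(pts) < 4)
    abort("PLY has fewer than 4 vertices", class = "percussr_malformed")
  list(points = pts, faces = faces)
}

# fixed output schema for per-pit tables
pit_table_columns <- c("tool_id", "plane", "pit_id", "area_cm2", "length_mm",
                       "width_mm", "depth_mm", "gradient", "roughness_mm",
                       "dac_mm", "dae_mm", "pa_percent", "density_per_cm2",
                       "n_pits")

#' Write a per-pit CSV table
#'
#' One row per pit plus one summary row per active surface, in a fixed
#' 14-column schema. On summary rows `area_cm2` is the active-surface
#' outline area, `dac_mm`/`dae_mm` are the mean distances over pits, and
#' the pit-morphometry fields are empty; on pit rows the surface-level
#' fields (`pa_percent`, `density_per_cm2`, `n_pits`) are empty.
#'
#' @param pits tibble of measured pits (may have zero rows).
#' @param summary one-row-per-plane summary as from [planform_summary()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pit_table <- function(pits, summary, path) {
  if (nrow(summary) > 0 && nrow(pits) > 0 &&
      !all(pits$tool_id %in% summary$tool_id))
    abort("pits and summary refer to different tools",
          class = "percussr_pairing")
  grab <- function(df, col) {
    if (col %in% names(df)) df[[col]] else rep(NA, nrow(df))
  }
  const <- function(df, val) rep(val, nrow(df))
  pit_rows <- data.frame(
    tool_id = grab(pits, "tool_id"), plane = grab(pits, "plane"),
    pit_id = grab(pits, "pit_id"), area_cm2 = grab(pits, "area_cm2"),
    length_mm = grab(pits, "length_mm"), width_mm = grab(pits, "width_mm"),
    depth_mm = grab(pits, "depth_mm"), gradient = grab(pits, "gradient"),
    roughness_mm = grab(pits, "roughness_mm"), dac_mm = grab(pits, "dac_mm"),
    dae_mm = grab(pits, "dae_mm"), pa_percent = const(pits, NA_real_),
    density_per_cm2 = const(pits, NA_real_),
    n_pits = const(pits, NA_integer_),
    stringsAsFactors = FALSE
  )
  sum_rows <- data.frame(
    tool_id = grab(summary, "tool_id"), plane = grab(summary, "plane"),
    pit_id = const(summary, NA_character_),
    area_cm2 = grab(summary, "area_cm2"),
    length_mm = const(summary, NA_real_), width_mm = const(summary, NA_real_),
    depth_mm = const(summary, NA_real_), gradient = const(summary, NA_real_),
    roughness_mm = const(summary, NA_real_),
    dac_mm = grab(summary, "dac_mean_mm"),
    dae_mm = grab(summary, "dae_mean_mm"),
    pa_percent = grab(summary, "pa_percent"),
    density_per_cm2 = grab(summary, "density_per_cm2"),
    n_pits = grab(summary, "n_pits"),
    stringsAsFactors = FALSE
  )
  out <- rbind(pit_rows, sum_rows)[, pit_table_columns]
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE),
    error = function(e) abort(paste0("cannot write ", path),
                              class = "percussr_io")
  )
  invisible(path)
}

#' Read a per-pit CSV table written by [write_pit_table()]
#' @param path CSV path.
#' @return a tibble in the 14-column pit-table schema.
#' @export
read_pit_table <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "percussr_io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), pit_table_columns))
    abort("not a percussr pit table (wrong columns)",
          class = "percussr_malformed")
  tibble::as_tibble(df)
}
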