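#' Load the packaged Djouroutou per-tool tables
#'
#' The package ships the published per-tool records of the 11 hammerstones
#' and 7 stone anvils collected at active nut-cracking sites at Djouroutou
#' (Tai National Park): general dimensions, raw material (Q = quartzite,
#' GD = granodiorite, MG = metamorphosed granite), associated nut species,
#' and the macro use-wear overview (damage-type flags, number of discrete
#' use-wear areas, number of active planes). The two source tables are
#' joined on tool id; cells printed as em-dashes become `NA` (anvils lack
#' thickness/volume/mass), and an "indeterminate" active-plane count is
#' kept as `NA` with `planes_indeterminate = TRUE`. One tool id is printed
#' with a space in one table and an underscore in the other; ids are
#' normalised (spaces to underscores) for the join.
#'
#' @return a tibble with 18 rows (11 hammers, 7 anvils).
#' @export
load_djouroutou_tables <- function() {
  p1 <- system.file("extdata", "table1_tools.csv", package = "percussr",
                    mustWork = TRUE)
  p2 <- system.file("extdata", "table2_wear.csv", package = "percussr",
                    mustWork = TRUE)
  t1 <- utils::read.csv(p1, stringsAsFactors = FALSE)
  t2 <- utils::read.csv(p2, stringsAsFactors = FALSE)
  norm_id <- function(x) gsub("[[:space:]]+", "_", x)
  t1$tool_id <- norm_id(t1$tool_id)
  t2$tool_id <- norm_id(t2$tool_id)
  t2$tool_type <- ifelse(t2$tool_type == "hammerstone", "hammer",
                         t2$tool_type)
  yn <- function(x) x == "yes"
  t2$macro_wear <- yn(t2$macro_wear)
  t2$depressions <- yn(t2$depressions)
  t2$pitting <- yn(t2$pitting)
  t2$crushing <- yn(t2$crushing)
  t2$flake_detachment <- yn(t2$flake_detachment)
  t2$residue <- yn(t2$residue)
  t2$planes_indeterminate <- t2$n_active_planes == "indeterminate"
  t2$n_active_planes <- suppressWarnings(as.integer(t2$n_active_planes))
  out <- dplyr::left_join(tibble::as_tibble(t1),
                          tibble::as_tibble(t2[, setdiff(names(t2),
                                                         "tool_type")]),
                          by = "tool_id")
  stopifnot(nrow(out) == 18, sum(out$tool_type == "hammer") == 11,
            sum(out$tool_type == "anvil") == 7)
  out
}
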