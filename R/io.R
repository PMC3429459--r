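#' Read a road network from edge-list and node CSV files
#'
#' @param edges_csv CSV with columns `from`, `to`, `minutes`.
#' @param nodes_csv CSV with columns `node`, `x`, `y`.
#' @return Network list (`nodes`, `edges`) usable by [od_matrix()].
#' @export
read_network <- function(edges_csv, nodes_csv) {
  edges <- tibble::as_tibble(utils::read.csv(edges_csv))
  nodes <- tibble::as_tibble(utils::read.csv(nodes_csv))
  stopifnot(all(c("from", "to", "minutes") %in% names(edges)),
            all(c("node", "x", "y") %in% names(nodes)))
  list(nodes = nodes, edges = edges)
}

#' Read a long-format origin-destination travel-time CSV
#'
#' @param path CSV with columns `bg_id`, `facility_id`, `minutes`.
#' @return Long OD tibble.
#' @export
read_od <- function(path) {
  od <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("bg_id", "facility_id", "minutes") %in% names(od)))
  od$bg_id <- as.character(od$bg_id)
  od$facility_id <- as.character(od$facility_id)
  od
}

#' Write block groups as GeoJSON point features
#'
#' Each block group becomes a Point feature with its non-coordinate columns
#' as properties (coordinates are taken from `x`, `y`).
#'
#' @param blockgroups Tibble with `bg_id`, `x`, `y` and optional extra
#'   columns.
#' @param path Output `.geojson` path.
#' @return The path, invisibly.
#' @export
write_blockgroups_geojson <- function(blockgroups, path) {
  props <- setdiff(names(blockgroups), c("x", "y"))
  features <- purrr::pmap(blockgroups, function(...) {
    row <- list(...)
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(row$x, row$y)),
         properties = row[props])
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
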