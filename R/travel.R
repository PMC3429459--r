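#' Origin-destination travel-time matrix over a road network
#'
#' Computes network shortest-path travel times, in minutes, from every
#' block-group centroid to every facility. Centroids and facilities are
#' snapped to the nearest network node by Euclidean distance and the access
#' time to the snapped node is counted as zero; `t_kj` is then the
#' shortest-path time between the two snapped nodes (Dijkstra). Unreachable
#' pairs get `Inf` and a warning.
#'
#' @param network A list with `nodes` (tibble: `node`, `x`, `y`) and `edges`
#'   (tibble: `from`, `to`, `minutes`), as produced by [generate_region()] or
#'   read from edge-list CSVs.
#' @param blockgroups Tibble with `bg_id`, `x`, `y`.
#' @param facilities Tibble with `facility_id`, `x`, `y` (one row per
#'   facility; extra columns ignored).
#' @return A long tibble `bg_id`, `facility_id`, `minutes` with one row per
#'   origin-destination pair.
#' @export
od_matrix <- function(network, blockgroups, facilities) {
  stopifnot(is.list(network), !is.null(network$nodes), !is.null(network$edges))
  nodes <- network$nodes
  edges <- network$edges
  if (any(edges$minutes < 0)) stop("edge times must be non-negative", call. = FALSE)
  fac <- dplyr::distinct(facilities, .data$facility_id, .keep_all = TRUE)

  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node))
  )
  igraph::E(g)$weight <- edges$minutes

  snap <- function(px, py) {
    vapply(seq_along(px), function(i) {
      which.min((nodes$x - px[i])^2 + (nodes$y - py[i])^2)
    }, integer(1))
  }
  bg_node <- snap(blockgroups$x, blockgroups$y)
  fac_node <- snap(fac$x, fac$y)

  ubg <- unique(bg_node)
  ufac <- unique(fac_node)
  d <- igraph::distances(g, v = ubg, to = ufac, mode = "all",
                         algorithm = "dijkstra")
  tt <- d[match(bg_node, ubg), match(fac_node, ufac), drop = FALSE]
  dimnames(tt) <- list(as.character(blockgroups$bg_id),
                       as.character(fac$facility_id))
  if (any(is.infinite(tt))) {
    warning(sum(is.infinite(tt)), " unreachable origin-destination pair(s)",
            call. = FALSE)
  }
  tibble::as_tibble(tt, rownames = "bg_id") |>
    tidyr::pivot_longer(-"bg_id", names_to = "facility_id",
                        values_to = "minutes")
}

# Long OD tibble (bg_id, facility_id, minutes) -> dense matrix, preserving
# first-appearance order of ids. A matrix input passes through unchanged.
as_od_times <- function(od) {
  if (is.matrix(od)) return(od)
  stopifnot(all(c("bg_id", "facility_id", "minutes") %in% names(od)))
  bgs <- unique(od$bg_id)
  facs <- unique(od$facility_id)
  m <- matrix(Inf, length(bgs), length(facs),
              dimnames = list(as.character(bgs), as.character(facs)))
  m[cbind(match(od$bg_id, bgs), match(od$facility_id, facs))] <- od$minutes
  m
}

#' Shortest travel time to the nearest facility
#'
#' @param od A long OD tibble from [od_matrix()] or a numeric matrix (rows =
#'   block groups, columns = facilities) of minutes.
#' @return Tibble `bg_id`, `dst` (minutes to the nearest facility).
#' @export
dst <- function(od) {
  tt <- as_od_times(od)
  bad <- !apply(tt, 1, function(r) any(is.finite(r)))
  if (any(bad)) {
    stop("block group(s) with no reachable facility: ",
         paste(rownames(tt)[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(bg_id = rownames(tt), dst = unname(apply(tt, 1, min)))
}

#' Mean travel time to the five nearest facilities
#'
#' Averages the five smallest finite travel times per block group; when fewer
#' than five facilities are reachable, all reachable ones are averaged.
#'
#' @inheritParams dst
#' @return Tibble `bg_id`, `dst5` (minutes).
#' @export
dst5 <- function(od) {
  tt <- as_od_times(od)
  bad <- !apply(tt, 1, function(r) any(is.finite(r)))
  if (any(bad)) {
    stop("block group(s) with no reachable facility: ",
         paste(rownames(tt)[bad], collapse = ", "), call. = FALSE)
  }
  v <- apply(tt, 1, function(r) {
    r <- sort(r[is.finite(r)])
    mean(r[seq_len(min(5L, length(r)))])
  })
  tibble::tibble(bg_id = rownames(tt), dst5 = unname(v))
}
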