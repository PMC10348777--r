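# Directed, proportion-weighted transfer network.
#
# Nodes are hospitals; an edge sending -> receiving aggregates all re-triages
# between that ordered pair, its weight being the fraction of all re-triages
# in the selected stratum (weights sum to 1). Edge categories follow the
# usual map convention: blue-class OPTIMAL edges end at level I/II, red-class
# SUBOPT_TO_NONTRAUMA at a nontrauma center, green-class SUBOPT_TO_III_IV at
# a level III/IV center.

edge_category <- function(receiving_level) {
  ifelse(receiving_level %in% high_trauma_levels(), "OPTIMAL",
         ifelse(receiving_level == "NONTRAUMA", "SUBOPT_TO_NONTRAUMA",
                "SUBOPT_TO_III_IV"))
}

#' Build the re-triage transfer graph
#'
#' @param events Labeled events.
#' @param directory Hospital directory (node attributes).
#' @param year Optional single year; `NULL` pools the whole period. A year
#'   with zero events yields an empty graph, not an error.
#' @return A directed [igraph::igraph] with vertex attributes (`name` =
#'   facility id, `latitude`, `longitude`, `level`, `lemsa_id`, `rtcc_id`)
#'   and edge attributes (`count`, `weight`, `category`); graph attributes
#'   `total_retriage` and `year`.
#' @export
build_transfer_graph <- function(events, directory, year = NULL) {
  ev <- tibble::as_tibble(events)
  if (!is.null(year)) ev <- ev[ev$year == year, , drop = FALSE]
  if (nrow(ev) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::set_graph_attr(g, "total_retriage", 0L)
    return(g)
  }
  total <- nrow(ev)
  ev$category <- edge_category(ev$receiving_level)
  edges <- ev |>
    dplyr::count(from = .data$sending_facility_id,
                 to = .data$receiving_facility_id,
                 .data$category, name = "count") |>
    dplyr::mutate(weight = .data$count / total)

  ref_year <- if (is.null(year)) max(ev$year) else year
  ids <- unique(c(edges$from, edges$to))
  nd <- directory[directory$year == ref_year &
                    directory$facility_id %in% ids, , drop = FALSE]
  nodes <- tibble::tibble(name = nd$facility_id, latitude = nd$latitude,
                          longitude = nd$longitude, level = nd$level,
                          lemsa_id = nd$lemsa_id, rtcc_id = nd$rtcc_id)
  nodes <- nodes[match(ids, nodes$name), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  g <- igraph::set_graph_attr(g, "total_retriage", total)
  g <- igraph::set_graph_attr(g, "year",
                              if (is.null(year)) NA_integer_ else year)
  g
}

#' Node coordinates for plotting the transfer graph
#'
#' `GEOGRAPHIC` uses each hospital's longitude/latitude directly (an error
#' if any coordinate is missing); `FORCE_DIRECTED` runs the
#' Fruchterman-Reingold spring embedding with a fixed iteration count (500)
#' under `seed`, so the layout is reproducible.
#'
#' @param graph A [build_transfer_graph()] result (nonempty).
#' @param mode `"GEOGRAPHIC"` or `"FORCE_DIRECTED"`.
#' @param seed Integer seed for the force-directed layout.
#' @param niter Fruchterman-Reingold iterations, default 500.
#' @return Numeric matrix (n_nodes x 2), rownames = facility ids.
#' @export
layout_graph <- function(graph, mode = c("GEOGRAPHIC", "FORCE_DIRECTED"),
                         seed = 1L, niter = 500L) {
  mode <- match.arg(mode)
  if (igraph::vcount(graph) == 0L) stop("graph is empty", call. = FALSE)
  if (mode == "GEOGRAPHIC") {
    lon <- igraph::V(graph)$longitude
    lat <- igraph::V(graph)$latitude
    if (anyNA(lon) || anyNA(lat)) {
      stop("missing coordinates; GEOGRAPHIC layout requires node locations",
           call. = FALSE)
    }
    xy <- cbind(lon, lat)
  } else {
    set.seed(seed)
    xy <- igraph::layout_with_fr(graph, niter = niter,
                                 weights = igraph::E(graph)$weight)
  }
  rownames(xy) <- igraph::V(graph)$name
  colnames(xy) <- c("x", "y")
  xy
}

#' Export the transfer graph to GraphML
#'
#' @param graph A transfer graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transfer_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

# points along the great circle between two WGS84 points (inclusive)
great_circle_points <- function(lat1, lon1, lat2, lon2, n = 16) {
  to_rad <- pi / 180
  p1 <- c(cos(lat1 * to_rad) * cos(lon1 * to_rad),
          cos(lat1 * to_rad) * sin(lon1 * to_rad), sin(lat1 * to_rad))
  p2 <- c(cos(lat2 * to_rad) * cos(lon2 * to_rad),
          cos(lat2 * to_rad) * sin(lon2 * to_rad), sin(lat2 * to_rad))
  omega <- acos(pmin(1, pmax(-1, sum(p1 * p2))))
  t <- seq(0, 1, length.out = n)
  if (omega < 1e-12) {
    pts <- cbind(rep(lon1, n), rep(lat1, n))
  } else {
    a <- sin((1 - t) * omega) / sin(omega)
    b <- sin(t * omega) / sin(omega)
    xyz <- cbind(a * p1[1] + b * p2[1], a * p1[2] + b * p2[2],
                 a * p1[3] + b * p2[3])
    pts <- cbind(atan2(xyz[, 2], xyz[, 1]) / to_rad,
                 asin(pmin(1, pmax(-1, xyz[, 3]))) / to_rad)
  }
  pts  # columns: lon, lat
}

#' Export transfer-graph nodes and edges as GeoJSON
#'
#' Nodes become Point features; edges become LineString features sampled
#' along the great circle between the two hospitals, carrying count, weight
#' and category properties.
#'
#' @param graph A transfer graph with node coordinates.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transfer_geojson <- function(graph, path) {
  vs <- igraph::V(graph)
  node_feats <- lapply(seq_along(vs), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(vs$longitude[i], vs$latitude[i])),
         properties = list(facility_id = vs$name[i], level = vs$level[i],
                           rtcc_id = vs$rtcc_id[i]))
  })
  el <- igraph::as_edgelist(graph)
  es <- igraph::E(graph)
  idx <- match(el, vs$name)
  dim(idx) <- dim(el)
  edge_feats <- lapply(seq_len(nrow(el)), function(i) {
    pts <- great_circle_points(vs$latitude[idx[i, 1]], vs$longitude[idx[i, 1]],
                               vs$latitude[idx[i, 2]], vs$longitude[idx[i, 2]])
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(pts)),
                                              function(j) pts[j, ])),
         properties = list(from = el[i, 1], to = el[i, 2],
                           count = es$count[i], weight = es$weight[i],
                           category = es$category[i]))
  })
  fc <- list(type = "FeatureCollection", features = c(node_feats, edge_feats))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot the transfer graph
#'
#' Optimal edges are drawn blue, suboptimal re-triages to a nontrauma center
#' red, suboptimal re-triages to a level III/IV center green; edge width is
#' proportional to re-triage volume.
#'
#' @param graph A transfer graph.
#' @param layout A [layout_graph()] matrix (default geographic).
#' @param vertex_size Node size, default 4.
#' @param edge_scale Multiplier from edge weight to line width.
#' @param ... Passed to [igraph::plot.igraph()].
#' @return The graph, invisibly.
#' @export
plot_transfer_graph <- function(graph, layout = layout_graph(graph),
                                vertex_size = 4, edge_scale = 60, ...) {
  pal <- c(OPTIMAL = "#2C7FB8", SUBOPT_TO_NONTRAUMA = "#D7191C",
           SUBOPT_TO_III_IV = "#1A9641")
  igraph::plot.igraph(
    graph, layout = layout,
    vertex.size = vertex_size, vertex.label = NA,
    vertex.color = ifelse(igraph::V(graph)$level %in% high_trauma_levels(),
                          "#253494", "#BDBDBD"),
    edge.color = unname(pal[igraph::E(graph)$category]),
    edge.width = pmax(0.3, edge_scale * igraph::E(graph)$weight),
    edge.arrow.size = 0.25, ...)
  invisible(graph)
}
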