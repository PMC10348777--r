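net_events <- function() {
  # 100 re-triages in 2018 among the test directory facilities
  tibble::tibble(
    sending_facility_id = c(rep("A01", 5), rep("A02", 55), rep("A01", 40)),
    receiving_facility_id = c(rep("A03", 5), rep("B01", 55), rep("B02", 40)),
    receiving_level = c(rep("LEVEL_IV", 5), rep("LEVEL_I", 55), rep("LEVEL_II", 40)),
    optimality = c(rep("SUBOPTIMAL", 5), rep("OPTIMAL", 95)),
    year = 2018L, rtcc_id = "SOUTH_WEST", lemsa_id = "SW_L01")
}

test_that("edges carry proportion weights and level-based categories", {
  dir <- test_directory()
  g <- build_transfer_graph(net_events(), dir, year = 2018)
  e <- tibble::tibble(
    from = igraph::tail_of(g, igraph::E(g))$name,
    to = igraph::head_of(g, igraph::E(g))$name,
    count = igraph::E(g)$count, weight = igraph::E(g)$weight,
    category = igraph::E(g)$category)
  expect_equal(sum(e$count), 100)
  expect_equal(sum(e$weight), 1, tolerance = 1e-12)
  expect_equal(e$weight[e$from == "A01" & e$to == "A03"], 0.05)
  expect_equal(e$category[e$to == "B01"], "OPTIMAL")
  expect_equal(e$category[e$to == "A03"], "SUBOPT_TO_III_IV")
  # suboptimal edge-weight share equals the rate-table rate
  rt <- aggregate_rates(net_events(), "STATE")
  expect_equal(sum(e$weight[e$category != "OPTIMAL"]),
               rt$rate[rt$year == "2018"], tolerance = 1e-12)
})

test_that("a nontrauma receiver yields the nontrauma suboptimal category", {
  dir <- test_directory()
  ev <- net_events()
  ev$receiving_facility_id[1:5] <- "C01"
  ev$receiving_level[1:5] <- "NONTRAUMA"
  g <- build_transfer_graph(ev, dir, year = 2018)
  cats <- igraph::E(g)$category
  expect_true("SUBOPT_TO_NONTRAUMA" %in% cats)
})

test_that("a year with no events gives an empty graph, not an error", {
  g <- build_transfer_graph(net_events(), test_directory(), year = 2009)
  expect_equal(igraph::vcount(g), 0)
  expect_equal(igraph::graph_attr(g, "total_retriage"), 0L)
  expect_error(layout_graph(g), "empty")
})

test_that("geographic layout returns node coordinates verbatim", {
  dir <- test_directory()
  g <- build_transfer_graph(net_events(), dir, year = 2018)
  xy <- layout_graph(g, "GEOGRAPHIC")
  ids <- rownames(xy)
  d <- dir[match(ids, dir$facility_id), ]
  expect_equal(unname(xy[, "x"]), d$longitude)
  expect_equal(unname(xy[, "y"]), d$latitude)
})

test_that("force-directed layout is deterministic under a seed", {
  g <- build_transfer_graph(net_events(), test_directory(), year = 2018)
  l1 <- layout_graph(g, "FORCE_DIRECTED", seed = 11)
  l2 <- layout_graph(g, "FORCE_DIRECTED", seed = 11)
  expect_identical(l1, l2)
})

test_that("spring embedding places disconnected cliques apart", {
  dir <- test_directory()
  ev <- tibble::tibble(
    sending_facility_id = c("A01", "A02", "A03", "C01", "C02", "C03"),
    receiving_facility_id = c("A02", "A03", "A01", "C02", "C03", "C01"),
    receiving_level = "LEVEL_I", optimality = "OPTIMAL",
    year = 2018L, rtcc_id = "SOUTH_WEST", lemsa_id = "L")
  g <- build_transfer_graph(ev, dir, year = 2018)
  xy <- layout_graph(g, "FORCE_DIRECTED", seed = 2)
  grp <- substr(rownames(xy), 1, 1) %in% c("A")
  dmat <- as.matrix(stats::dist(xy))
  within <- dmat[grp, grp][upper.tri(dmat[grp, grp])]
  within <- c(within, dmat[!grp, !grp][upper.tri(dmat[!grp, !grp])])
  between <- dmat[grp, !grp]
  expect_lt(mean(within), mean(between))
})

test_that("graphml and geojson exports round-trip the structure", {
  g <- build_transfer_graph(net_events(), test_directory(), year = 2018)
  f <- tempfile(fileext = ".graphml")
  write_transfer_graphml(g, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(sort(igraph::E(g2)$weight), sort(igraph::E(g)$weight))
  fj <- tempfile(fileext = ".geojson")
  write_transfer_geojson(g, fj)
  fc <- jsonlite::read_json(fj)
  expect_equal(fc$type, "FeatureCollection")
  expect_equal(length(fc$features), igraph::vcount(g) + igraph::gsize(g))
  unlink(c(f, fj))
})
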