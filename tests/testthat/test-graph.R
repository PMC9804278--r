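test_that("graph construction honours its counting identities", {
  tri <- tibble::tibble(id = c("a", "b", "c"),
                        x = c(0, 1000, 500), y = c(0, 0, 900))
  g <- build_graph(tri, "delaunay")
  expect_equal(nrow(g$edges), 3L)

  set.seed(14)
  nodes <- tibble::tibble(id = paste0("n", 1:9),
                          x = runif(9, 0, 1e5), y = runif(9, 0, 1e5))
  gs <- build_graph(nodes, "saturated")
  expect_equal(nrow(gs$edges), 9 * 8 / 2)

  gp <- build_graph(nodes, "saturated", prune_km = 50)
  expect_true(all(gp$edges$length_m <= 50000))
  dropped <- nrow(gs$edges) - nrow(gp$edges)
  expect_equal(dropped, sum(gs$edges$length_m > 50000))

  # origin is the lower-indexed node in input order
  expect_true(all(gs$edges$origin == gs$edges$from))
})

test_that("delaunay edges satisfy the empty-circumcircle definition", {
  set.seed(8)
  for (trial in 1:25) {
    n <- sample(4:10, 1)
    x <- runif(n) * 1000
    y <- runif(n) * 1000
    g <- build_graph(tibble::tibble(id = sprintf("p%02d", 1:n), x = x, y = y),
                     "delaunay")
    got <- cbind(match(g$edges$from, sprintf("p%02d", 1:n)),
                 match(g$edges$to, sprintf("p%02d", 1:n)))
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    want <- oracle_delaunay_edges(x, y)
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
})

test_that("degenerate node sets fall back gracefully", {
  dup <- tibble::tibble(id = c("a", "b", "c", "d"),
                        x = c(0, 0, 1000, 500), y = c(0, 0, 0, 800))
  expect_warning(g <- build_graph(dup, "delaunay"), "jittered")
  expect_true(all(g$edges$length_m > 0))

  line <- tibble::tibble(id = letters[1:4], x = c(0, 100, 200, 300),
                         y = rep(5, 4))
  expect_warning(gl <- build_graph(line, "delaunay"), "collinear")
  expect_equal(nrow(gl$edges), 3L)

  expect_error(build_graph(line[1:2, ], "delaunay"), "3 nodes")
})

test_that("node metrics match closed forms on path, star and empty graphs", {
  path <- tibble::tibble(id = c("A", "B", "C"),
                         x = c(0, 100, 200), y = c(0, 1, 0))
  g <- build_graph(path, "delaunay")
  g$edges <- g$edges[g$edges$length_m < 150, ]  # strip the A-C chord
  m <- node_metrics(g)
  expect_equal(m$betweenness[m$id == "B"], 1)
  expect_equal(m$betweenness[m$id %in% c("A", "C")], c(0, 0))

  # star with 4 leaves: centre betweenness = 4 * 3 / 2 = 6
  star_nodes <- tibble::tibble(id = c("hub", paste0("leaf", 1:4)),
                               x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1))
  star <- build_graph(star_nodes, "saturated")
  star$edges <- star$edges[star$edges$from == "hub" |
                             star$edges$to == "hub", ]
  ms <- node_metrics(star)
  expect_equal(ms$betweenness[ms$id == "hub"], 6)
  expect_equal(ms$degree[ms$id == "hub"], 4L)

  # edgeless graph: alpha centrality equals the exogenous input 1
  empty <- star
  empty$edges <- empty$edges[0, ]
  me <- node_metrics(empty)
  expect_true(all(me$alpha_centrality == 1))
  expect_true(all(me$degree == 0))
})

test_that("betweenness equals exhaustive path enumeration on small graphs", {
  set.seed(77)
  for (trial in 1:30) {
    n <- sample(4:7, 1)
    nodes <- tibble::tibble(id = sprintf("v%d", 1:n),
                            x = runif(n) * 100, y = runif(n) * 100)
    g <- build_graph(nodes, "saturated")
    keep <- runif(nrow(g$edges)) < 0.5
    if (!any(keep)) keep[1] <- TRUE
    g$edges <- g$edges[keep, ]
    got <- node_metrics(g)$betweenness
    idx <- cbind(match(g$edges$from, nodes$id), match(g$edges$to, nodes$id))
    want <- oracle_betweenness(n, idx)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("edge covariate extraction summarises the raster under each edge", {
  const <- land_raster(matrix(7, 50, 50), cell = 30)
  nodes <- tibble::tibble(id = c("a", "b", "c"),
                          x = c(100, 1300, 700), y = c(100, 200, 1300))
  g <- build_graph(nodes, "saturated")
  g2 <- extract_edge_covariates(g, list(k = const))
  expect_true(all(g2$edges$k == 7))

  # east-west gradient: edge medians sit between endpoint values
  grad <- land_raster(matrix(rep(1:50, each = 50), 50, 50, byrow = FALSE),
                      cell = 30)
  grad$values <- t(grad$values)
  g3 <- extract_edge_covariates(g, list(gx = grad))
  expect_true(all(g3$edges$gx >= 1 & g3$edges$gx <= 50))

  # medians are stable across buffer widths on a smooth surface
  cfg <- sim_config(seed = 31, n_sites = 4, n_neutral = 10, n_adaptive = 0,
                    selection_strength = 0, landscape_extent = 1500)
  smooth <- make_landscape(cfg)["cti"]
  set.seed(9)
  nn <- tibble::tibble(id = paste0("w", 1:8),
                       x = runif(8, 300, 1200), y = runif(8, 300, 1200))
  gg <- build_graph(nn, "saturated")
  meds <- sapply(c(30, 90, 150, 270, 510), function(w)
    extract_edge_covariates(gg, smooth, width_m = w)$edges$cti)
  cors <- cor(meds)
  expect_true(all(cors[upper.tri(cors)] > 0.85))

  # edges leaving the raster error; nodata-only edges warn
  far <- tibble::tibble(id = c("a", "b"), x = c(100, 9999), y = c(100, 100))
  gf <- build_graph(far, "saturated")
  expect_error(extract_edge_covariates(gf, list(k = const)), "extent")
  hole <- const
  hole$values[, ] <- NA
  w <- testthat::capture_warnings(
    gh <- extract_edge_covariates(g, list(k = hole)))
  expect_true(length(w) >= 1 && all(grepl("nodata", w)))
  expect_true(all(is.na(gh$edges$k)))
})

test_that("ascii grid io round-trips a raster", {
  r <- land_raster(matrix(rnorm(30), 5, 6), xmin = 100, ymin = 200,
                   cell = 30)
  r$values[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  back <- read_ascii_grid(path)
  expect_equal(unname(back$values), unname(r$values), tolerance = 1e-6)
  expect_equal(unname(back$cell), 30)
  expect_equal(unname(back$xmin), 100)
})

test_that("node covariates and precomputed edge tables attach by id", {
  r <- land_raster(matrix(1:100, 10, 10), cell = 10)
  nodes <- tibble::tibble(id = c("a", "b", "c"),
                          x = c(5, 55, 95), y = c(5, 55, 95))
  out <- extract_node_covariates(nodes, list(v = r))
  expect_equal(out$v, raster_value_at(r, nodes$x, nodes$y))

  g <- build_graph(nodes, "saturated")
  tab <- tibble::tibble(from = c("b", "a"), to = c("a", "c"),
                        d_stream = c(10, 20))
  g2 <- attach_edge_table(g, tab, "d_stream")
  e <- g2$edges
  expect_equal(e$d_stream[e$from == "a" & e$to == "b"], 10)
  expect_equal(e$d_stream[e$from == "a" & e$to == "c"], 20)
  expect_true(is.na(e$d_stream[e$from == "b" & e$to == "c"]))
})
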