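#' Build a spatial graph over site / wetland nodes
#'
#' Constructs an undirected graph on point locations in a projected,
#' metre-unit coordinate system, either by Delaunay triangulation
#' (Bowyer-Watson) or as the saturated all-pairs graph, optionally pruned to
#' a maximum edge length. Each edge records its straight-line length and an
#' origin node (the lower-indexed endpoint in input order), the grouping
#' unit used by the singly constrained gravity model.
#'
#' Duplicate coordinates are jittered by less than a metre with a warning;
#' fully collinear inputs fall back to a nearest-neighbour chain.
#'
#' @param nodes tibble with `id`, `x`, `y` and optionally `kind`
#'   (`"genetic"`, `"occupied"`, `"wetland"`).
#' @param method `"delaunay"` or `"saturated"`.
#' @param prune_km drop edges longer than this many kilometres (optional).
#' @return a `spatial_graph`: list of `nodes`, `edges` (tibble `from`, `to`,
#'   `length_m`, `origin`), `method`, `prune_km`.
#' @export
build_graph <- function(nodes, method = c("delaunay", "saturated"),
                        prune_km = NULL) {
  method <- match.arg(method)
  nodes <- as_tibble(nodes)
  assert_that(all(c("id", "x", "y") %in% names(nodes)),
              "nodes need columns id, x, y")
  assert_that(!anyDuplicated(nodes$id), "node ids must be unique")
  assert_that(all(is.finite(nodes$x) & is.finite(nodes$y)),
              "node coordinates must be finite")
  n <- nrow(nodes)
  x <- nodes$x
  y <- nodes$y

  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    warning(sprintf("%d duplicate coordinate(s) jittered by <1 m", sum(dup)))
    set.seed(sub_seed(n, "jitter"))
    x[dup] <- x[dup] + runif(sum(dup), -0.5, 0.5)
    y[dup] <- y[dup] + runif(sum(dup), -0.5, 0.5)
  }

  if (method == "saturated") {
    idx <- pair_index(n)
  } else {
    assert_that(n >= 3, "delaunay triangulation needs at least 3 nodes")
    if (is_collinear(x, y)) {
      warning("all nodes collinear: falling back to nearest-neighbour chain")
      ord <- order_along_principal_axis(x, y)
      idx <- cbind(i = ord[-n], j = ord[-1])
      idx <- t(apply(idx, 1, sort))
      colnames(idx) <- c("i", "j")
    } else {
      idx <- delaunay_edges(x, y)
    }
  }
  len <- sqrt((x[idx[, 1]] - x[idx[, 2]])^2 + (y[idx[, 1]] - y[idx[, 2]])^2)
  edges <- tibble(
    from = nodes$id[idx[, 1]],
    to = nodes$id[idx[, 2]],
    length_m = len,
    origin = nodes$id[pmin(idx[, 1], idx[, 2])]
  )
  if (!is.null(prune_km)) {
    edges <- edges[edges$length_m <= prune_km * 1000, , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = edges, method = method,
                 prune_km = prune_km),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph:%s> %d nodes, %d edges%s\n", x$method,
              nrow(x$nodes), nrow(x$edges),
              if (!is.null(x$prune_km))
                sprintf(", pruned at %g km", x$prune_km) else ""))
  invisible(x)
}

is_collinear <- function(x, y, tol = 1e-9) {
  n <- length(x)
  if (n < 3) return(TRUE)
  d2 <- (x - x[1])^2 + (y - y[1])^2
  k <- which.max(d2)
  if (d2[k] == 0) return(TRUE)
  cross <- (x[k] - x[1]) * (y - y[1]) - (y[k] - y[1]) * (x - x[1])
  all(abs(cross) <= tol * max(d2))
}

order_along_principal_axis <- function(x, y) {
  v <- prcomp(cbind(x, y))$x[, 1]
  order(v)
}

# Bowyer-Watson incremental Delaunay triangulation; returns unique edges as
# a two-column index matrix (i < j)
delaunay_edges <- function(x, y) {
  n <- length(x)
  # normalise coordinates for numerical stability
  cx <- (x - mean(x)) / max(sd(x), sd(y), 1e-9)
  cy <- (y - mean(y)) / max(sd(x), sd(y), 1e-9)
  big <- 1e4
  px <- c(cx, 0, -3 * big, 3 * big)
  py <- c(cy, 3 * big, -big, -big)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- matrix(c(s1, s2, s3), nrow = 1)

  circum <- function(t) {
    ax <- px[t[1]]; ay <- py[t[1]]
    bx <- px[t[2]]; by <- py[t[2]]
    cx2 <- px[t[3]]; cy2 <- py[t[3]]
    d <- 2 * (ax * (by - cy2) + bx * (cy2 - ay) + cx2 * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy2) + (bx^2 + by^2) * (cy2 - ay) +
             (cx2^2 + cy2^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx2 - bx) + (bx^2 + by^2) * (ax - cx2) +
             (cx2^2 + cy2^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  cc <- matrix(circum(tris[1, ]), nrow = 1)

  for (p in seq_len(n)) {
    d2 <- (cc[, 1] - px[p])^2 + (cc[, 2] - py[p])^2
    bad <- which(d2 <= cc[, 3] * (1 + 1e-12))
    if (length(bad) == 0) bad <- which.min(d2 / cc[, 3])
    # boundary polygon: edges of bad triangles appearing exactly once
    ed <- rbind(tris[bad, c(1, 2), drop = FALSE],
                tris[bad, c(2, 3), drop = FALSE],
                tris[bad, c(1, 3), drop = FALSE])
    ed <- t(apply(ed, 1, sort))
    key <- paste(ed[, 1], ed[, 2])
    boundary <- ed[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    new_t <- cbind(boundary, p)
    tris <- rbind(tris, new_t)
    cc <- rbind(cc, t(apply(new_t, 1, circum)))
  }
  keep <- rowSums(tris > n) == 0
  tris <- tris[keep, , drop = FALSE]
  ed <- rbind(tris[, c(1, 2), drop = FALSE], tris[, c(2, 3), drop = FALSE],
              tris[, c(1, 3), drop = FALSE])
  ed <- unique(t(apply(ed, 1, sort)))
  colnames(ed) <- c("i", "j")
  ed
}

#' Node connectivity metrics
#'
#' Degree, shortest-path (Freeman/Brandes) betweenness on the unweighted
#' graph, and alpha centrality `x = (I - alpha * t(A))^-1 e` with exogenous
#' input `e = 1` and `alpha = alpha_frac / lambda_max(A)` (for an edgeless
#' graph, `x = e`).
#'
#' @param graph a [build_graph()] result.
#' @param alpha_frac fraction of the reciprocal spectral radius used for
#'   alpha centrality.
#' @return a tibble: `id`, `degree`, `betweenness`, `alpha_centrality`.
#' @export
node_metrics <- function(graph, alpha_frac = 0.85) {
  ids <- graph$nodes$id
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = ids)
  )
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)

  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(graph$edges) > 0) {
    A[cbind(graph$edges$from, graph$edges$to)] <- 1
    A[cbind(graph$edges$to, graph$edges$from)] <- 1
  }
  lam <- max(abs(eigen(A, only.values = TRUE)$values))
  if (lam < 1e-12) {
    alpha_c <- rep(1, length(ids))
  } else {
    alpha <- alpha_frac / lam
    assert_that(alpha * lam < 1, "alpha * lambda_max must be < 1")
    alpha_c <- as.vector(solve(diag(length(ids)) - alpha * t(A),
                               rep(1, length(ids))))
  }
  tibble(id = ids, degree = as.integer(deg[ids]),
         betweenness = as.numeric(btw[ids]),
         alpha_centrality = alpha_c)
}

#' Attach a precomputed pairwise table as an edge covariate
#'
#' Joins values such as stream distances, computed elsewhere, onto graph
#' edges by unordered node pair.
#'
#' @param graph a [build_graph()] result.
#' @param table tibble with `from`, `to` and one value column.
#' @param name covariate name to use on the edges.
#' @return the graph with the covariate column added.
#' @export
attach_edge_table <- function(graph, table, name) {
  val_col <- setdiff(names(table), c("from", "to"))[1]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- match(key(graph$edges$from, graph$edges$to),
             key(table$from, table$to))
  graph$edges[[name]] <- table[[val_col]][m]
  graph
}
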