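test_that("uniform-resistance cost distance equals distance times R", {
  g <- grid_geometry(3, 12, 30)
  r <- matrix(2, 3, 12)
  src <- data.frame(row = 2, col = 1)
  cd <- cost_distance(r, src, geometry = g)
  expect_equal(cd[2, 1], 0)
  expect_equal(cd[2, 11], 10 * 30 * 2)   # 10 rook steps
  # diagonal move costs sqrt(2) * cell_size * R
  g2 <- grid_geometry(5, 5, 30)
  cd2 <- cost_distance(matrix(1, 5, 5), data.frame(row = 1, col = 1),
                       geometry = g2)
  expect_equal(cd2[5, 5], 4 * sqrt(2) * 30)
})

test_that("cost distance equals the brute-force Dijkstra oracle", {
  set.seed(77)
  for (trial in 1:6) {
    nr <- sample(8:15, 1); nc <- sample(8:15, 1)
    g <- grid_geometry(nr, nc, 30)
    r <- matrix(stats::runif(nr * nc, 1, 5), nr, nc)
    src <- sample.int(nr * nc, sample(1:3, 1))
    expect_equal(cost_distance(r, src, geometry = g),
                 oracle_grid_dijkstra(r, 30, src), tolerance = 1e-9)
  }
})

test_that("resistance must be finite and positive", {
  g <- grid_geometry(4, 4, 30)
  bad <- matrix(1, 4, 4); bad[2, 2] <- 0
  expect_error(cost_graph(bad, g), "positive")
  bad2 <- matrix(1, 4, 4); bad2[2, 2] <- Inf
  expect_error(cost_graph(bad2, g), "finite")
  expect_error(cost_distance(matrix(1, 4, 4), integer(0), geometry = g),
               "empty")
})

# a patch set with blocks planted at given (rows, cols) rectangles
planted_patches <- function(nr, nc, blocks, cell_size = 30) {
  mask <- matrix(FALSE, nr, nc)
  for (b in blocks) mask[b[[1]], b[[2]]] <- TRUE
  extract_patches(mask, geometry = grid_geometry(nr, nc, cell_size))
}

test_that("corridors: one per pair, symmetric costs, paths connect patches", {
  set.seed(5)
  nr <- 30; nc <- 30
  p <- planted_patches(nr, nc, list(list(2:5, 2:5), list(25:28, 3:6),
                                    list(4:7, 24:27), list(24:27, 24:27)))
  r <- matrix(stats::runif(nr * nc, 1, 5), nr, nc)
  corr <- least_cost_corridors(r, p, source_ids = 1:4,
                               geometry = grid_geometry(nr, nc, 30))
  expect_equal(nrow(corr$table), choose(4, 2))
  # cost symmetric: recompute with reversed id order
  corr_rev <- least_cost_corridors(r, p, source_ids = 4:1,
                                   geometry = grid_geometry(nr, nc, 30))
  for (k in seq_len(nrow(corr$table))) {
    i <- corr$table$i[k]; j <- corr$table$j[k]
    m <- which((corr_rev$table$i == j & corr_rev$table$j == i) |
                 (corr_rev$table$i == i & corr_rev$table$j == j))
    expect_equal(corr$table$cost[k], corr_rev$table$cost[m], tolerance = 1e-9)
  }
  # each path starts in one patch and ends in the other
  for (k in seq_len(nrow(corr$table))) {
    path <- corr$paths[[k]]
    ends <- p$labels[path[c(1, nrow(path)), , drop = FALSE]]
    expect_setequal(ends, c(corr$table$i[k], corr$table$j[k]))
  }
})

test_that("corridor costs match the Dijkstra oracle patch-to-patch", {
  set.seed(8)
  nr <- 15; nc <- 18
  p <- planted_patches(nr, nc, list(list(2:3, 2:3), list(12:13, 14:15),
                                    list(12:14, 2:4)))
  r <- matrix(stats::runif(nr * nc, 1, 5), nr, nc)
  corr <- least_cost_corridors(r, p, source_ids = 1:3,
                               geometry = grid_geometry(nr, nc, 30))
  for (k in seq_len(nrow(corr$table))) {
    d <- oracle_grid_dijkstra(r, 30, which(p$labels == corr$table$i[k]))
    expect_equal(corr$table$cost[k],
                 min(d[p$labels == corr$table$j[k]]), tolerance = 1e-9)
  }
})

test_that("a wall with one gap routes the corridor through the gap", {
  nr <- 21; nc <- 21
  p <- planted_patches(nr, nc, list(list(9:13, 1:2), list(9:13, 20:21)))
  r <- matrix(1, nr, nc)
  r[, 11] <- 1000                   # wall
  r[3, 11] <- 1                     # gap at row 3
  corr <- least_cost_corridors(r, p, source_ids = 1:2,
                               geometry = grid_geometry(nr, nc, 30))
  path <- corr$paths[[1]]
  crossing <- path[path[, "col"] == 11, , drop = FALSE]
  expect_equal(unname(crossing[, "row"]), 3)
})

test_that("raising a cell's resistance never lowers any corridor cost", {
  set.seed(12)
  nr <- 20; nc <- 20
  p <- planted_patches(nr, nc, list(list(2:4, 2:4), list(16:18, 16:18),
                                    list(2:4, 16:18)))
  r <- matrix(stats::runif(nr * nc, 1, 5), nr, nc)
  base <- least_cost_corridors(r, p, source_ids = 1:3,
                               geometry = grid_geometry(nr, nc, 30))$table$cost
  for (trial in 1:20) {
    r2 <- r
    cell <- sample.int(nr * nc, 1)
    r2[cell] <- r2[cell] + stats::runif(1, 0.5, 3)
    pert <- least_cost_corridors(r2, p, source_ids = 1:3,
                                 geometry = grid_geometry(nr, nc, 30))$table$cost
    expect_true(all(pert >= base - 1e-9))
  }
})

test_that("gravity matrix follows the closed formula and is symmetric", {
  set.seed(19)
  nr <- 25; nc <- 25
  cell <- 500   # 25 ha cells keep ln(S) positive
  p <- planted_patches(nr, nc, list(list(2:5, 2:5), list(20:23, 2:5),
                                    list(2:5, 20:23), list(20:23, 20:23)),
                       cell_size = cell)
  r <- matrix(stats::runif(nr * nc, 1, 5), nr, nc)
  corr <- least_cost_corridors(r, p, source_ids = 1:4,
                               geometry = grid_geometry(nr, nc, cell))
  grav <- gravity_matrix(p, corr, r)
  expect_equal(grav$G, t(grav$G))
  expect_true(all(diag(grav$G) == 0))
  expect_true(all(grav$G[upper.tri(grav$G)] > 0))
  # independent evaluation of every entry
  S <- vapply(1:4, function(id) sum(p$labels == id) * cell^2 / 1e4, 0)
  P <- vapply(1:4, function(id) mean(r[p$labels == id]), 0)
  Lm <- max(corr$table$cost)
  for (k in seq_len(nrow(corr$table))) {
    i <- corr$table$i[k]; j <- corr$table$j[k]; L <- corr$table$cost[k]
    expect_equal(grav$G[i, j],
                 Lm^2 * log(S[i]) * log(S[j]) / (L^2 * P[i] * P[j]),
                 tolerance = 1e-12)
  }
})

test_that("gravity errors on sub-hectare patches and overlapping sources", {
  p <- planted_patches(20, 20, list(list(2:3, 2:3), list(15:16, 15:16)),
                       cell_size = 30)  # 4 cells of 30 m = 0.36 ha
  r <- matrix(1, 20, 20)
  corr <- least_cost_corridors(r, p, 1:2, geometry = grid_geometry(20, 20, 30))
  expect_error(gravity_matrix(p, corr, r), "1 ha")
})

test_that("corridor ranking flags top_k with deterministic tie-breaking", {
  set.seed(23)
  p <- planted_patches(30, 30, list(list(2:5, 2:5), list(25:28, 2:5),
                                    list(2:5, 25:28), list(25:28, 25:28),
                                    list(13:16, 13:16)), cell_size = 500)
  r <- matrix(stats::runif(900, 1, 5), 30, 30)
  corr <- least_cost_corridors(r, p, 1:5, geometry = grid_geometry(30, 30, 500))
  grav <- gravity_matrix(p, corr, r)
  ranked <- rank_corridors(corr, grav, top_k = 3)
  expect_equal(sum(ranked$table$important), 3)
  ord <- order(ranked$table$rank)
  expect_equal(ranked$table$G[ord], sort(ranked$table$G, decreasing = TRUE))
  # flagged corridors hold the largest G values
  expect_gte(min(ranked$table$G[ranked$table$important]),
             max(ranked$table$G[!ranked$table$important]))
  none <- rank_corridors(corr, grav, top_k = 0)
  expect_equal(sum(none$table$important), 0)
})

test_that("GeoJSON corridor export is valid and round-readable", {
  p <- planted_patches(12, 12, list(list(2:3, 2:3), list(9:10, 9:10)),
                       cell_size = 500)
  r <- matrix(1, 12, 12)
  corr <- least_cost_corridors(r, p, 1:2, geometry = grid_geometry(12, 12, 500))
  f <- tempfile(fileext = ".geojson")
  write_corridors_geojson(corr, f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 1)
  expect_equal(gj$features[[1]]$geometry$type, "LineString")
  expect_equal(length(gj$features[[1]]$geometry$coordinates),
               nrow(corr$paths[[1]]))
})
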