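test_that("patch extraction honours 8-connectivity and area units", {
  g <- grid_geometry(12, 12, 30)
  mask <- matrix(FALSE, 12, 12)
  mask[2:4, 2:4] <- TRUE          # blob 1 (9 cells)
  mask[8:10, 8:10] <- TRUE        # blob 2
  p <- extract_patches(mask, geometry = g)
  expect_equal(nrow(p$patches), 2)
  expect_equal(p$patches$area_km2, rep(9 * 900 * 1e-6, 2))
  # diagonal touch merges under 8-connectivity
  mask[5, 5] <- TRUE              # touches (4,4) diagonally
  p8 <- extract_patches(mask, geometry = g)
  expect_equal(nrow(p8$patches), 2)
  p4 <- extract_patches(mask, geometry = g, connectivity = 4)
  expect_equal(nrow(p4$patches), 3)
})

test_that("patch distances are minimum edge-to-edge centre distances", {
  g <- grid_geometry(10, 20, 30)
  mask <- matrix(FALSE, 10, 20)
  mask[5, 3] <- TRUE
  mask[5, 4] <- TRUE   # adjacent column, same patch? no - adjacent = same patch
  mask[5, 14] <- TRUE  # 10 columns from col 4
  p <- extract_patches(mask, geometry = g)
  expect_equal(nrow(p$patches), 2)
  d <- patch_distances(p)
  expect_equal(d[1, 2], 10 * 30)
  expect_equal(diag(d), c(0, 0))
  # adjacent columns: 30 m
  mask2 <- matrix(FALSE, 5, 5); mask2[3, 2] <- TRUE; mask2[3, 4] <- TRUE
  p2 <- extract_patches(mask2, geometry = grid_geometry(5, 5, 30))
  expect_equal(patch_distances(p2)[1, 2], 60)
  mask3 <- matrix(FALSE, 5, 5); mask3[3, 2] <- TRUE; mask3[3, 3] <- TRUE
  p3 <- extract_patches(mask3, geometry = grid_geometry(5, 5, 30))
  expect_equal(nrow(p3$patches), 1)
})

test_that("IIC matches hand-computed two-patch cases", {
  # two unlinked unit-area patches, AL = 4
  g <- make_test_graph(c(1, 1), matrix(c(0, 9000, 9000, 0), 2), AL = 4)
  expect_equal(iic(g), 0.125)
  # linked pair: (1 + 1 + 2 * 1/2) / 16
  g2 <- make_test_graph(c(1, 1), matrix(c(0, 3000, 3000, 0), 2), AL = 4)
  expect_equal(iic(g2), 0.1875)
  # single patch filling the landscape
  g3 <- make_test_graph(4, matrix(0, 1, 1), AL = 4)
  expect_equal(iic(g3), 1)
  expect_equal(pc(g3), 1)
})

test_that("PC matches the negative-exponential kernel at the threshold", {
  # exactly 5000 m apart: p = 0.5, PC = (1 + 1 + 2*0.5) / 16
  g <- make_test_graph(c(1, 1), matrix(c(0, 5000, 5000, 0), 2), AL = 4)
  expect_equal(pc(g), 0.1875)
  expect_equal(g$links$p_ij, 0.5)
})

test_that("p* takes a two-step path when its product beats the direct link", {
  # three collinear patches 4000 m apart: direct 1-3 link (8000 m) is
  # over threshold, so p*13 must be the product of the two 4000 m hops
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 4000
  d[2, 3] <- d[3, 2] <- 4000
  d[1, 3] <- d[3, 1] <- 8000
  g <- make_test_graph(c(1, 1, 1), d, AL = 10)
  pm <- graph_pmat(g)
  expect_equal(oracle_pstar(pm, 1, 3), exp(-log(2) / 5000 * 4000)^2)
  expect_equal(pc(g), oracle_pc(g$patches$area_km2, pm, 10))
})

test_that("IIC and PC agree with exhaustive path enumeration on random graphs", {
  set.seed(31)
  for (trial in 1:25) {
    g <- random_test_graph(6)
    adj <- graph_adj(g); pm <- graph_pmat(g)
    expect_equal(iic(g), oracle_iic(g$patches$area_km2, adj, g$AL_km2),
                 tolerance = 1e-12)
    expect_equal(pc(g), oracle_pc(g$patches$area_km2, pm, g$AL_km2),
                 tolerance = 1e-12)
    expect_gte(iic(g), 0); expect_lte(iic(g), 1)
    expect_gte(pc(g), 0); expect_lte(pc(g), 1)
  }
})

test_that("adding a link or raising the threshold never decreases the indices", {
  set.seed(57)
  for (trial in 1:10) {
    n <- 5
    areas <- stats::runif(n, 0.5, 3)
    pts <- matrix(stats::runif(2 * n, 0, 10000), n, 2)
    dmat <- as.matrix(stats::dist(pts))
    g_lo <- make_test_graph(areas, dmat, AL = 60, threshold = 4000)
    g_hi <- make_test_graph(areas, dmat, AL = 60, threshold = 7000)
    expect_gte(pc(g_hi), pc(g_lo) - 1e-12)
    expect_gte(iic(g_hi), iic(g_lo) - 1e-12)
  }
})

test_that("removal importances are positive and match brute force", {
  set.seed(101)
  for (trial in 1:10) {
    g <- random_test_graph(5)
    dpc <- delta_importance(g, "PC")
    diic <- delta_importance(g, "IIC")
    expect_true(all(dpc > 0))
    expect_true(all(diic > 0))
    # brute force: recompute the oracle on the graph minus each patch
    for (i in seq_len(nrow(g$patches))) {
      g_i <- econetr:::drop_patch(g, i)
      expect_equal(dpc[i],
                   100 * (pc(g) - oracle_pc(g_i$patches$area_km2,
                                            graph_pmat(g_i), g$AL_km2)) / pc(g),
                   tolerance = 1e-9)
    }
  }
})

test_that("a sole patch has dPC = 100", {
  g <- make_test_graph(2, matrix(0, 1, 1), AL = 4)
  expect_equal(delta_importance(g, "PC"), 100)
  expect_equal(delta_importance(g, "IIC"), 100)
})

test_that("two identical unlinked patches each carry half the index", {
  g <- make_test_graph(c(1, 1), matrix(c(0, 9000, 9000, 0), 2), AL = 4)
  expect_equal(delta_importance(g, "PC"), c(50, 50))
})

test_that("source selection ranks by dPC with area/id tie-breaks", {
  g <- random_test_graph(6)
  rep <- connectivity_report(g)
  expect_equal(rep$ranking$dPC, sort(rep$ranking$dPC, decreasing = TRUE))
  n <- nrow(rep$ranking)
  expect_equal(select_sources(rep, min(3, n)),
               rep$ranking$id[seq_len(min(3, n))])
  expect_warning(s <- select_sources(rep, n + 5), "returning all")
  expect_equal(length(s), n)
  # explicit tie: equal dPC (two identical unlinked patches), unequal area
  # cannot happen; fabricate by equal-area symmetric pair -> id tie-break
  g2 <- make_test_graph(c(1, 1), matrix(c(0, 9000, 9000, 0), 2), AL = 4)
  r2 <- connectivity_report(g2)
  expect_equal(r2$ranking$id, c(1, 2))   # equal dPC and area -> smaller id first
})

test_that("a planted dominant patch ranks first by dPC", {
  g <- grid_geometry(40, 40, 500)
  mask <- matrix(FALSE, 40, 40)
  mask[5:25, 5:25] <- TRUE      # giant
  mask[30:32, 30:32] <- TRUE
  mask[35:36, 10:11] <- TRUE
  mask[3, 35] <- TRUE
  p <- extract_patches(mask, geometry = g)
  gr <- patch_graph(p)
  rep <- connectivity_report(gr)
  giant <- p$patches$id[which.max(p$patches$cells)]
  expect_equal(rep$ranking$id[1], giant)
})
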