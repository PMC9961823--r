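# printed loading / characteristic-root table used for the coefficient
# identity checks (factor order: branch road, main road, slope, land use,
# vegetation, elevation)
PCA_TABLE <- list(
  roots = c(3.39, 2.13),
  loadings = cbind(c(0.93, 0.89, 0.82, 0.77, 0.68, 0.01),
                   c(0.27, 0.44, 0.57, 0.63, 0.44, 0.98)),
  printed_coefficients = cbind(c(0.50, 0.48, 0.45, 0.42, 0.37, 0.01),
                               c(0.19, 0.30, 0.39, 0.43, 0.30, 0.67)))

test_that("coefficient = loading / sqrt(root) reproduces all printed cells at 2 dp", {
  coef <- sweep(PCA_TABLE$loadings, 2, sqrt(PCA_TABLE$roots), "/")
  # the published loadings and roots are themselves 2-dp truncations, so the
  # recomputed cells can sit up to half a display unit (0.005) plus the
  # propagated input-rounding error (~0.003) from the printed value; the
  # observed maximum deviation is 0.0051 (branch road, first component:
  # 0.93/sqrt(3.39) = 0.5051 against printed 0.50)
  expect_lt(max(abs(coef - PCA_TABLE$printed_coefficients)), 0.0075)
  # 11 of the 12 cells do round straight to the printed value
  expect_gte(sum(round(coef, 2) == PCA_TABLE$printed_coefficients), 11)
})

test_that("reclassification reproduces the published break examples", {
  rules <- default_reclass_rules()
  g1 <- matrix(3600, 1, 1)
  expect_equal(reclassify(g1, rules$elevation)[1, 1], 2)   # 3500-4000 -> 2
  expect_equal(reclassify(matrix(0.9, 1, 1), rules$vegcover)[1, 1], 1)
  expect_equal(reclassify(matrix(350, 1, 1), rules$road_main)[1, 1], 5)
  # boundary conventions: left-closed intervals, closed top
  expect_equal(reclassify(matrix(3500, 1, 1), rules$elevation)[1, 1], 2)
  expect_equal(reclassify(matrix(5200, 1, 1), rules$elevation)[1, 1], 5)
  expect_equal(reclassify(matrix(-50, 1, 1), rules$elevation)[1, 1], 1)
  expect_equal(reclassify(matrix(1, 1, 1), rules$vegcover)[1, 1], 1)
  expect_equal(reclassify(matrix(Inf, 1, 1), rules$road_main)[1, 1], 1)
  # categorical rules
  expect_equal(reclassify(matrix("S", 1, 1), rules$aspect)[1, 1], 1)
  expect_equal(reclassify(matrix("N", 1, 1), rules$aspect)[1, 1], 5)
  expect_equal(reclassify(matrix("ice and snow", 1, 1), rules$landuse)[1, 1], 5)
  expect_equal(reclassify(matrix("bare land", 1, 1), rules$landuse)[1, 1], 5)
  expect_error(reclassify(matrix("tundra", 1, 1), rules$landuse), "tundra")
})

test_that("road distances score minimum resistance when no roads exist", {
  g <- grid_geometry(5, 5, 30)
  d <- distance_to_roads(matrix(FALSE, 5, 5), g)
  expect_true(all(d == Inf))
  score <- reclassify(d, default_reclass_rules()$road_main)
  expect_true(all(score == 1))
  # on-road and 5-cell offsets
  road <- matrix(FALSE, 5, 5); road[, 3] <- TRUE
  d2 <- distance_to_roads(road, g)
  expect_equal(d2[1, 3], 0)
  expect_equal(d2[1, 5], 60)
  g2 <- grid_geometry(3, 8, 30)
  road2 <- matrix(FALSE, 3, 8); road2[, 1] <- TRUE
  expect_equal(distance_to_roads(road2, g2)[2, 6], 150)
})

test_that("weighted sum reproduces the worked arithmetic and stays in range", {
  g <- grid_geometry(1, 1, 30)
  sc <- list(elevation = matrix(3, 1, 1), aspect = matrix(2, 1, 1),
             landuse = matrix(1, 1, 1), vegcover = matrix(4, 1, 1),
             road_main = matrix(5, 1, 1), road_branch = matrix(5, 1, 1))
  r <- weighted_sum(sc, default_weights(), g)
  expect_equal(r$values[1, 1], 3.99)
  all1 <- lapply(sc, function(x) matrix(1, 1, 1))
  all5 <- lapply(sc, function(x) matrix(5, 1, 1))
  expect_equal(weighted_sum(all1, default_weights(), g)$values[1, 1], 1)
  expect_equal(weighted_sum(all5, default_weights(), g)$values[1, 1], 5)
  bad_w <- default_weights(); names(bad_w)[1] <- "slope"
  expect_error(weighted_sum(sc, bad_w, g), "cover exactly")
})

test_that("the full surface of a synthetic landscape lies in [1, 5]", {
  st <- simulate_landscape(
    simulation_config(grid_geometry(100, 100, 500), seed = 21))
  r <- build_resistance(st)
  expect_true(all(r$values >= 1 & r$values <= 5))
  expect_true(all(is.finite(r$values)))
})

test_that("pca_weights is self-consistent and sums to one", {
  st <- simulate_landscape(
    simulation_config(grid_geometry(80, 80, 500), seed = 22))
  sc <- factor_scores(st)
  rep <- pca_weights(sc, sample_size = 3000, seed = 5)
  # coefficient * sqrt(root) returns the loading
  recon <- sweep(rep$coefficients, 2, sqrt(rep$roots), "*")
  expect_equal(recon, rep$loadings, tolerance = 1e-9)
  expect_equal(sum(rep$weights), 1, tolerance = 1e-9)
  comp <- as.vector(rep$coefficients %*% rep$variance_share) /
    sum(rep$variance_share)
  expect_equal(unname(rep$composite), comp, tolerance = 1e-12)
})

test_that("two perfectly correlated factors get equal weights", {
  set.seed(3)
  base <- matrix(stats::rnorm(400), 20, 20)
  rep <- pca_weights(list(a = base, b = base * 2 + 1), sample_size = 400,
                     seed = 1, n_components = 1)
  expect_equal(unname(rep$weights), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("constant factors raise a degenerate-correlation error", {
  expect_error(
    pca_weights(list(a = matrix(1, 5, 5), b = matrix(stats::rnorm(25), 5, 5)),
                sample_size = 25, seed = 1),
    "constant")
})

test_that("resistance is monotone in every factor score", {
  g <- grid_geometry(1, 1, 30)
  w <- default_weights()
  base <- lapply(w, function(x) matrix(3, 1, 1))
  r0 <- weighted_sum(base, w, g)$values[1, 1]
  for (f in names(w)) {
    up <- base; up[[f]] <- matrix(4, 1, 1)
    expect_gt(weighted_sum(up, w, g)$values[1, 1], r0)
  }
})
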