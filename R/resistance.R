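#' Default reclassification rules for the six resistance factors
#'
#' Each factor is mapped to an ordinal resistance score 1 (least) to 5
#' (greatest). Numeric rules use ascending breaks with left-closed /
#' right-open intervals; categorical rules map class names to scores.
#' Defaults:
#'
#' * elevation (m): `<3500` 1, `3500-4000` 2, `4000-4500` 3, `4500-5000` 4,
#'   `>=5000` 5;
#' * aspect: S 1; SW/SE 2; E/W 3; NW/NE 4; N 5; flat 1 (south-facing and
#'   level ground are the easiest terrain);
#' * land use: cultivated/shrub/grassland/forest 1, water 2, wetland 3,
#'   construction 4, ice and snow 5, bare land 5;
#' * vegetation cover (fraction): `>=0.8` 1 down to `<0.2` 5;
#' * distance from main road (m): `<400` 5 up to `>=1300` 1;
#' * distance from branch road (m): `<100` 5 up to `>=400` 1.
#'
#' Distances beyond the largest break score 1 (farther from a road is less
#' resistance), so an empty road layer (infinite distances) contributes the
#' minimum score everywhere.
#'
#' @return named list of reclass rules (one per factor).
#' @export
default_reclass_rules <- function() {
  list(
    elevation = numeric_rule("elevation",
                             breaks = c(-Inf, 3500, 4000, 4500, 5000, Inf),
                             scores = c(1, 2, 3, 4, 5)),
    aspect = categorical_rule("aspect", c(
      S = 1, SW = 2, SE = 2, E = 3, W = 3, NW = 4, NE = 4, N = 5, flat = 1)),
    landuse = categorical_rule("landuse", c(
      "cultivated land" = 1, "shrub" = 1, "grassland" = 1, "forest land" = 1,
      "water area" = 2, "wetland" = 3, "construction land" = 4,
      "ice and snow" = 5, "bare land" = 5)),
    vegcover = numeric_rule("vegcover",
                            breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
                            scores = c(5, 4, 3, 2, 1)),
    road_main = numeric_rule("road_main",
                             breaks = c(0, 400, 700, 1000, 1300, Inf),
                             scores = c(5, 4, 3, 2, 1)),
    road_branch = numeric_rule("road_branch",
                               breaks = c(0, 100, 200, 300, 400, Inf),
                               scores = c(5, 4, 3, 2, 1)))
}

#' Build a numeric reclassification rule
#'
#' @param factor factor name.
#' @param breaks ascending breaks delimiting `length(breaks) - 1`
#'   left-closed / right-open intervals.
#' @param scores integer scores in 1..5, one per interval.
#' @export
numeric_rule <- function(factor, breaks, scores) {
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be ascending")
  if (length(scores) != length(breaks) - 1L)
    stop("need one score per interval")
  if (any(!scores %in% 1:5)) stop("scores must lie in 1..5")
  structure(list(factor = factor, type = "numeric",
                 breaks = breaks, scores = as.numeric(scores)),
            class = "reclass_rule")
}

#' Build a categorical reclassification rule
#'
#' @param factor factor name.
#' @param map named numeric vector: category -> score in 1..5.
#' @export
categorical_rule <- function(factor, map) {
  if (is.null(names(map)) || any(!map %in% 1:5))
    stop("map must be a named vector of scores in 1..5")
  structure(list(factor = factor, type = "categorical", map = map),
            class = "reclass_rule")
}

#' Reclassify a factor raster to 1-5 resistance scores
#'
#' Numeric rules assign by left-closed / right-open interval membership on
#' the ascending breaks; categorical rules look category names up in the
#' rule's map (an uncovered category is a configuration error). `Inf`
#' values (e.g. distance to an absent road network) fall in the last
#' interval.
#'
#' @param raster numeric or character matrix.
#' @param rule a [numeric_rule()] or [categorical_rule()].
#' @return numeric matrix of scores in 1..5.
#' @export
reclassify <- function(raster, rule) {
  stopifnot(inherits(rule, "reclass_rule"))
  if (rule$type == "numeric") {
    idx <- findInterval(raster, rule$breaks, left.open = FALSE,
                        rightmost.closed = TRUE)
    if (any(idx < 1L | idx > length(rule$scores)))
      stop(sprintf("values outside the '%s' rule's breaks", rule$factor))
    out <- rule$scores[idx]
  } else {
    miss <- setdiff(unique(as.vector(raster)), names(rule$map))
    if (length(miss) > 0L)
      stop(sprintf("categories not covered by the '%s' rule: %s",
                   rule$factor, paste(miss, collapse = ", ")))
    out <- unname(rule$map[as.vector(raster)])
  }
  matrix(out, nrow(raster), ncol(raster))
}

#' Euclidean distance to the nearest road cell
#'
#' Thin wrapper over [distance_transform()]: metres to the nearest road
#' cell centre, 0 on road cells, `Inf` when the layer is empty (which the
#' default rules score as minimum resistance).
#'
#' @param road logical matrix.
#' @param geometry a [grid_geometry()].
#' @return numeric matrix (m).
#' @export
distance_to_roads <- function(road, geometry) {
  distance_transform(road == TRUE, geometry)
}

#' Default factor weights
#'
#' The weight column of the shipped configuration: elevation 0.16,
#' aspect 0.08, land use 0.06, vegetation 0.21, main road 0.26,
#' branch road 0.23 (sums to 1).
#'
#' @return named numeric vector.
#' @export
default_weights <- function() {
  c(elevation = 0.16, aspect = 0.08, landuse = 0.06,
    vegcover = 0.21, road_main = 0.26, road_branch = 0.23)
}

#' Factor weights by principal component analysis
#'
#' Reproduces the classical composite-score PCA weighting chain on a seeded sample
#' of cells: standardize the sampled factor scores, eigendecompose their
#' correlation matrix, retain `n_components` components, and derive
#'
#' * loadings: `eigenvector * sqrt(eigenvalue)`;
#' * linear-combination coefficients: `loading / sqrt(eigenvalue)`
#'   (i.e. the eigenvector entries);
#' * composite coefficients: variance-share-weighted mean of the
#'   per-component coefficients;
#' * weights: composite coefficients normalised to sum 1.
#'
#' Eigenvector signs are fixed so each component's loading sum is
#' positive.
#'
#' @param scores named list of score matrices (all same shape).
#' @param sample_size number of cells sampled (capped at the cell count).
#' @param seed sampling seed.
#' @param n_components components retained (default 2).
#' @return an object of class `pca_weight_report`: `loadings`,
#'   `coefficients` (factors x components), `roots` (eigenvalues),
#'   `variance_share` (percent), `composite`, `weights`.
#' @export
pca_weights <- function(scores, sample_size = 5000, seed = 1L,
                        n_components = 2L) {
  if (length(scores) < 2L) stop("need at least two factors")
  dims <- dim(scores[[1]])
  ncell <- prod(dims)
  if (sample_size < length(scores))
    stop("sample_size must be at least the number of factors")
  set.seed(seed)
  idx <- sample.int(ncell, min(sample_size, ncell))
  X <- vapply(scores, function(m) as.vector(m)[idx], numeric(length(idx)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant factor(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
         " (degenerate correlation matrix)")
  ev <- eigen(stats::cor(X), symmetric = TRUE)
  n_components <- min(n_components, ncol(X))
  roots <- ev$values[seq_len(n_components)]
  vecs <- ev$vectors[, seq_len(n_components), drop = FALSE]
  flip <- ifelse(colSums(vecs) < 0, -1, 1)
  vecs <- sweep(vecs, 2, flip, "*")
  loadings <- sweep(vecs, 2, sqrt(roots), "*")
  coefficients <- vecs                     # loading / sqrt(root)
  varshare <- 100 * roots / ncol(X)
  composite <- as.vector(coefficients %*% varshare) / sum(varshare)
  rownames(loadings) <- rownames(coefficients) <- names(scores)
  names(composite) <- names(scores)
  structure(
    list(loadings = loadings, coefficients = coefficients, roots = roots,
         variance_share = varshare, composite = composite,
         weights = composite / sum(composite), n_sampled = length(idx)),
    class = "pca_weight_report")
}

#' @export
print.pca_weight_report <- function(x, ...) {
  cat(sprintf("<pca_weight_report> %d components, %d cells sampled\n",
              length(x$roots), x$n_sampled))
  cat("roots:", sprintf("%.3f", x$roots), "| variance share (%):",
      sprintf("%.2f", x$variance_share), "\n")
  print(round(cbind(x$loadings, composite = x$composite,
                    weight = x$weights), 3))
  invisible(x)
}

#' Weighted-sum resistance surface
#'
#' The comprehensive weighted index sum: `R(cell) = sum_f w_f score_f(cell)`.
#' As a convex combination of 1-5 scores the surface lies in `[1, 5]`.
#'
#' @param scores named list of score matrices.
#' @param weights named weights covering exactly the factors in `scores`
#'   and summing to 1.
#' @param geometry a [grid_geometry()].
#' @return an object of class `resistance_surface`: `geometry` plus
#'   numeric `values` matrix.
#' @export
weighted_sum <- function(scores, weights, geometry) {
  if (!setequal(names(scores), names(weights)))
    stop("weights must cover exactly the provided factors; got [",
         paste(names(weights), collapse = ", "), "] for factors [",
         paste(names(scores), collapse = ", "), "]")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  vals <- matrix(0, geometry$n_rows, geometry$n_cols)
  for (f in names(scores)) {
    check_layer(scores[[f]], geometry, f)
    vals <- vals + weights[[f]] * scores[[f]]
  }
  structure(list(geometry = geometry, values = vals),
            class = "resistance_surface")
}

#' @export
print.resistance_surface <- function(x, ...) {
  cat(sprintf("<resistance_surface> %d x %d, range [%.3f, %.3f]\n",
              x$geometry$n_rows, x$geometry$n_cols,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Factor score stack from a landscape
#'
#' Computes the six factor rasters (elevation, aspect, land use,
#' vegetation cover, distance from main and branch roads) from a
#' [landscape_stack()] and reclassifies each to 1-5 scores.
#'
#' @param stack a [landscape_stack()].
#' @param rules reclass rules, as [default_reclass_rules()].
#' @return named list of six score matrices.
#' @export
factor_scores <- function(stack, rules = default_reclass_rules()) {
  stopifnot(inherits(stack, "landscape_stack"))
  g <- stack$geometry
  list(
    elevation = reclassify(stack$dem, rules$elevation),
    aspect = reclassify(aspect_from_dem(stack$dem, g), rules$aspect),
    landuse = reclassify(stack$landuse, rules$landuse),
    vegcover = reclassify(stack$vegcover, rules$vegcover),
    road_main = reclassify(distance_to_roads(stack$road_main, g),
                           rules$road_main),
    road_branch = reclassify(distance_to_roads(stack$road_branch, g),
                             rules$road_branch))
}

#' Build the resistance surface of a landscape
#'
#' Convenience chain: [factor_scores()] then [weighted_sum()] with the
#' default (or supplied) weights.
#'
#' @param stack a [landscape_stack()].
#' @param rules reclass rules.
#' @param weights factor weights (default [default_weights()]).
#' @return a `resistance_surface`.
#' @export
build_resistance <- function(stack, rules = default_reclass_rules(),
                             weights = default_weights()) {
  weighted_sum(factor_scores(stack, rules), weights, stack$geometry)
}
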