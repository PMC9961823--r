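#' Land-use classes of the study system
#'
#' The nine categorical land-use classes carried by every synthetic or
#' loaded landscape, in the fixed code order 1..9 used by the ASCII-grid
#' representation. Grassland is the MSPA foreground by default.
#'
#' @export
LANDUSE_CLASSES <- c("grassland", "construction land", "cultivated land",
                     "shrub", "wetland", "forest land", "ice and snow",
                     "water area", "bare land")

# Background class mixture for cells that are not grassland. Chosen once to
# emulate an alpine source basin: bare ground and water-linked classes
# dominate the non-grass matrix, built-up land is marginal.
BACKGROUND_PROPS <- c("bare land" = 0.40, "water area" = 0.15,
                      "wetland" = 0.15, "forest land" = 0.08,
                      "shrub" = 0.08, "cultivated land" = 0.08,
                      "ice and snow" = 0.04, "construction land" = 0.02)

#' Configuration of the synthetic landscape generator
#'
#' Bundles the grid geometry and the stochastic-model parameters. The
#' defaults describe the stated world the rest of the package is tested
#' against: a 200 x 200 grid of 500 m cells (a 100 km regional window)
#' whose grassland foreground covers 80\% of the landscape, with a smooth
#' (contiguous) eastern half and a rougher, sparser (fragmented) western
#' half, a smooth high-altitude DEM, vegetation cover correlated with
#' grassland, and sparse main/branch road networks.
#'
#' @param geometry a [grid_geometry()].
#' @param foreground_fraction target grassland share of the landscape,
#'   in (0, 1).
#' @param n_blobs number of habitat nuclei seeding the grassland field.
#' @param fragmentation smoothness scale of the noise field in cells;
#'   larger values give smoother fields and fewer, larger patches.
#' @param east_west_gradient if `TRUE`, the western half uses a rougher
#'   field so its grassland patches are smaller on average.
#' @param n_roads_main,n_roads_branch number of main / branch roads.
#' @param seed integer seed fixing all randomness.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = grid_geometry(200, 200, 500),
                              foreground_fraction = 0.80,
                              n_blobs = 12,
                              fragmentation = 3,
                              east_west_gradient = TRUE,
                              n_roads_main = 2,
                              n_roads_branch = 8,
                              seed = 1L) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (!(foreground_fraction > 0 && foreground_fraction < 1))
    stop("foreground_fraction must lie strictly between 0 and 1")
  if (fragmentation <= 0) stop("fragmentation must be positive")
  structure(
    list(geometry = geometry,
         foreground_fraction = foreground_fraction,
         n_blobs = as.integer(n_blobs),
         fragmentation = fragmentation,
         east_west_gradient = isTRUE(east_west_gradient),
         n_roads_main = as.integer(n_roads_main),
         n_roads_branch = as.integer(n_roads_branch),
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Aligned stack of landscape rasters
#'
#' @param geometry a [grid_geometry()].
#' @param landuse character matrix over [LANDUSE_CLASSES].
#' @param dem numeric matrix, elevation in metres.
#' @param vegcover numeric matrix, fractional vegetation cover in `[0, 1]`.
#' @param road_main,road_branch logical matrices, rasterized road presence.
#' @return an object of class `landscape_stack`.
#' @export
landscape_stack <- function(geometry, landuse, dem, vegcover,
                            road_main, road_branch) {
  stopifnot(inherits(geometry, "grid_geometry"))
  for (nm in c("landuse", "dem", "vegcover", "road_main", "road_branch"))
    check_layer(get(nm), geometry, nm)
  bad <- setdiff(unique(as.vector(landuse)), LANDUSE_CLASSES)
  if (length(bad) > 0L)
    stop("landuse holds classes outside the declared set: ",
         paste(bad, collapse = ", "))
  if (any(vegcover < 0 | vegcover > 1, na.rm = TRUE))
    stop("vegcover must lie in [0, 1]")
  if (any(!is.finite(dem))) stop("dem must be finite")
  structure(
    list(geometry = geometry, landuse = landuse, dem = dem,
         vegcover = vegcover,
         road_main = road_main == TRUE, road_branch = road_branch == TRUE),
    class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<landscape_stack> %d x %d @ %g m\n", g$n_rows, g$n_cols, g$cell_size))
  cat(sprintf("  grassland share: %.3f | dem range: %.0f-%.0f m | road cells: %d main, %d branch\n",
              mean(x$landuse == "grassland"), min(x$dem), max(x$dem),
              sum(x$road_main), sum(x$road_branch)))
  invisible(x)
}

# seeded standard-normal field, smoothed and standardized
smooth_noise <- function(nr, nc, sigma) {
  f <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  (f - mean(f)) / stats::sd(f)
}

# random-walk polyline across the grid; returns a logical raster with an
# 8-connected path. Horizontal roads run the full east-west extent.
rasterize_road <- function(nr, nc, horizontal = TRUE, full_span = TRUE) {
  mask <- matrix(FALSE, nr, nc)
  if (horizontal) {
    span <- if (full_span) nc else max(2L, round(nc / 2))
    start_col <- if (full_span) 1L else sample.int(nc - span + 1L, 1L)
    r <- sample.int(nr, 1L)
    for (cc in start_col:(start_col + span - 1L)) {
      r <- min(nr, max(1L, r + sample(c(-1L, 0L, 1L), 1L)))
      mask[r, cc] <- TRUE
    }
  } else {
    span <- if (full_span) nr else max(2L, round(nr / 2))
    start_row <- if (full_span) 1L else sample.int(nr - span + 1L, 1L)
    cc <- sample.int(nc, 1L)
    for (r in start_row:(start_row + span - 1L)) {
      cc <- min(nc, max(1L, cc + sample(c(-1L, 0L, 1L), 1L)))
      mask[r, cc] <- TRUE
    }
  }
  mask
}

#' Simulate a synthetic landscape stack
#'
#' Generates a seeded, fully reproducible landscape with the statistical
#' structure the analysis pipeline assumes. Grassland arises by
#' thresholding a field that superposes `n_blobs` radial habitat nuclei on
#' Gaussian-smoothed white noise at the quantile delivering the target
#' foreground fraction; when `east_west_gradient` is set, the western half
#' uses a rougher noise field so its patches are smaller (a fragmented
#' west against a contiguous east). Non-grass cells are assigned to the
#' other eight classes by a secondary smoothed field with fixed
#' proportions. The DEM is a smooth high-altitude surface rising westward;
#' vegetation cover is positively tied to grassland presence; roads are
#' connected random-walk polylines.
#'
#' @param config a [simulation_config()].
#' @return a [landscape_stack()].
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$geometry
  nr <- g$n_rows; nc <- g$n_cols
  if (nr * nc < 25L * max(1L, config$n_blobs))
    stop(sprintf("geometry too small to host %d blobs: need >= %d cells, have %d",
                 config$n_blobs, 25L * config$n_blobs, nr * nc))
  set.seed(config$seed)

  # --- grassland field -----------------------------------------------------
  sigma_smooth <- config$fragmentation
  trend <- 0
  if (config$east_west_gradient) {
    rough <- smooth_noise(nr, nc, max(1, sigma_smooth / 3))
    smooth <- smooth_noise(nr, nc, sigma_smooth)
    w <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc) # 0 west, 1 east
    noise <- (1 - w) * rough + w * smooth
    # habitat suitability falls toward the west: western grassland survives
    # only as isolated noise peaks, giving the fragmented western half
    trend <- 0.6 * (w - 0.5)
  } else {
    noise <- smooth_noise(nr, nc, sigma_smooth)
  }
  bumps <- matrix(0, nr, nc)
  if (config$n_blobs > 0L) {
    rows <- matrix(rep(seq_len(nr), nc), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    radius <- min(nr, nc) / (2 * sqrt(config$n_blobs))
    margin <- max(2L, round(radius / 2))
    cr <- sample(seq(margin, nr - margin + 1L), config$n_blobs, replace = TRUE)
    cc <- sample(seq(margin, nc - margin + 1L), config$n_blobs, replace = TRUE)
    for (b in seq_len(config$n_blobs))
      bumps <- pmax(bumps, exp(-((rows - cr[b])^2 + (cols - cc[b])^2) /
                                 (2 * radius^2)))
  }
  field <- bumps + 0.55 * noise + trend
  thr <- stats::quantile(field, 1 - config$foreground_fraction, names = FALSE)
  grass <- field > thr

  # --- background classes --------------------------------------------------
  landuse <- matrix(LANDUSE_CLASSES[1], nr, nc)
  bg_idx <- which(!grass)
  if (length(bg_idx) > 0L) {
    bg_field <- smooth_noise(nr, nc, max(2, sigma_smooth / 2))[bg_idx]
    qs <- stats::quantile(bg_field, cumsum(BACKGROUND_PROPS), names = FALSE)
    cls <- names(BACKGROUND_PROPS)[findInterval(bg_field, qs[-length(qs)]) + 1L]
    landuse[bg_idx] <- cls
  }

  # --- DEM: smooth, high altitude, rising toward the west ------------------
  colfrac <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  dem <- 4200 + 700 * (1 - colfrac) + 250 * smooth_noise(nr, nc, max(8, sigma_smooth * 2))
  dem <- pmax(dem, 3600)

  # --- vegetation cover, positively tied to grassland ----------------------
  veg <- 0.30 + 0.45 * grass + 0.15 * smooth_noise(nr, nc, max(3, sigma_smooth))
  veg <- pmin(pmax(veg, 0), 1)

  # --- roads ---------------------------------------------------------------
  road_main <- matrix(FALSE, nr, nc)
  for (i in seq_len(config$n_roads_main))
    road_main <- road_main | rasterize_road(nr, nc, horizontal = TRUE, full_span = TRUE)
  road_branch <- matrix(FALSE, nr, nc)
  for (i in seq_len(config$n_roads_branch))
    road_branch <- road_branch |
      rasterize_road(nr, nc, horizontal = (i %% 2 == 0L), full_span = FALSE)

  landscape_stack(g, landuse, dem, veg, road_main, road_branch)
}

#' Aspect classification from a DEM
#'
#' Labels each cell with the compass direction of steepest descent from
#' Horn's 3 x 3 finite-difference gradient; cells with zero gradient are
#' `flat`. Border cells inherit the value of the nearest interior cell.
#' Aspect is one of the six resistance factors entering the resistance
#' surface.
#'
#' @param dem numeric matrix of elevations (m).
#' @param geometry a [grid_geometry()].
#' @return character matrix over `N, NE, E, SE, S, SW, W, NW, flat`.
#' @export
aspect_from_dem <- function(dem, geometry) {
  check_layer(dem, geometry, "dem")
  if (any(!is.finite(dem))) stop("dem must be finite")
  nr <- nrow(dem); nc <- ncol(dem)
  if (nr < 3L || nc < 3L)
    stop("aspect needs at least a 3 x 3 grid")
  cs <- geometry$cell_size
  # Horn's method on the 3x3 window:
  #   a b c      gx = ((c+2f+i) - (a+2d+g)) / (8*cs)   (eastward)
  #   d e f      gy = ((a+2b+c) - (g+2h+i)) / (8*cs)   (northward; row 1 is north)
  #   g h i
  sh <- function(dr, dc) dem[(2:(nr - 1)) + dr, (2:(nc - 1)) + dc]
  a <- sh(-1, -1); b <- sh(-1, 0); cc <- sh(-1, 1)
  d <- sh(0, -1);                  f <- sh(0, 1)
  gg <- sh(1, -1); h <- sh(1, 0);  i <- sh(1, 1)
  gx <- ((cc + 2 * f + i) - (a + 2 * d + gg)) / (8 * cs)
  gy <- ((a + 2 * b + cc) - (gg + 2 * h + i)) / (8 * cs)
  lab <- matrix("flat", nr - 2L, nc - 2L)
  nz <- gx != 0 | gy != 0
  # downslope direction: -(gx, gy); compass bearing clockwise from north
  bearing <- (atan2(-gx[nz], -gy[nz]) * 180 / pi) %% 360
  sectors <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  lab[nz] <- sectors[(floor((bearing + 22.5) / 45) %% 8) + 1L]
  # border cells inherit the nearest interior value
  out <- matrix("flat", nr, nc)
  out[2:(nr - 1), 2:(nc - 1)] <- lab
  out[1, ] <- out[2, ]; out[nr, ] <- out[nr - 1L, ]
  out[, 1] <- out[, 2]; out[, nc] <- out[, nc - 1L]
  out
}

# ---------------------------------------------------------------------------
# Stack I/O: one ASCII grid per layer plus a YAML sidecar for the land-use
# class codes (1..9 in LANDUSE_CLASSES order).

#' Write a landscape stack to a directory
#'
#' Each layer becomes a single-band Esri ASCII grid (`landuse.asc` holds
#' integer class codes, keyed in `landuse_classes.yaml`).
#'
#' @param stack a [landscape_stack()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_landscape_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "landscape_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- stack$geometry
  codes <- matrix(match(stack$landuse, LANDUSE_CLASSES), g$n_rows, g$n_cols)
  write_ascii_grid(codes, g, file.path(dir, "landuse.asc"))
  write_ascii_grid(stack$dem, g, file.path(dir, "dem.asc"))
  write_ascii_grid(stack$vegcover, g, file.path(dir, "vegcover.asc"))
  write_ascii_grid(stack$road_main * 1, g, file.path(dir, "road_main.asc"))
  write_ascii_grid(stack$road_branch * 1, g, file.path(dir, "road_branch.asc"))
  yaml::write_yaml(as.list(stats::setNames(seq_along(LANDUSE_CLASSES),
                                           LANDUSE_CLASSES)),
                   file.path(dir, "landuse_classes.yaml"))
  invisible(dir)
}

#' Read a landscape stack from a directory
#'
#' @param dir directory written by [write_landscape_stack()].
#' @return a [landscape_stack()].
#' @export
read_landscape_stack <- function(dir) {
  need <- c("landuse.asc", "dem.asc", "vegcover.asc",
            "road_main.asc", "road_branch.asc")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0L)
    stop("missing layer file(s): ", paste(missing, collapse = ", "))
  lu <- read_ascii_grid(file.path(dir, "landuse.asc"))
  g <- lu$geometry
  landuse <- matrix(LANDUSE_CLASSES[as.integer(lu$values)], g$n_rows, g$n_cols)
  landscape_stack(
    g, landuse,
    dem = read_ascii_grid(file.path(dir, "dem.asc"))$values,
    vegcover = read_ascii_grid(file.path(dir, "vegcover.asc"))$values,
    road_main = read_ascii_grid(file.path(dir, "road_main.asc"))$values == 1,
    road_branch = read_ascii_grid(file.path(dir, "road_branch.asc"))$values == 1)
}
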