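#' Grid geometry of an aligned raster stack
#'
#' All rasters handled by econetr are plain R matrices indexed `[row, col]`
#' with row 1 at the northern edge. A `grid_geometry` records the grid
#' dimensions, the square cell size in metres and the map coordinate of the
#' north-west corner, so that cell centres, areas and inter-cell distances
#' are well defined.
#'
#' Cell centres are at
#' `x = origin[1] + (col - 0.5) * cell_size`,
#' `y = origin[2] - (row - 0.5) * cell_size`
#' (projected map units, metres).
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param cell_size side length of a square cell in metres (> 0).
#' @param origin numeric length-2, map coordinate (x, y) of the north-west
#'   corner of cell `[1, 1]`.
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(n_rows, n_cols, cell_size = 30, origin = c(0, 0)) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L) stop("n_rows must be >= 1")
  if (is.na(n_cols) || n_cols < 1L) stop("n_cols must be >= 1")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive number (metres)")
  if (!is.numeric(origin) || length(origin) != 2L)
    stop("origin must be a numeric (x, y) pair")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
    class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d cells, %g m cells, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

n_cells <- function(geometry) geometry$n_rows * geometry$n_cols

#' Total landscape area in km^2
#'
#' The quantity `AL` entering the connectivity indices: the full raster
#' extent, `n_rows * n_cols * cell_size^2`, converted to km^2.
#'
#' @param geometry a [grid_geometry()].
#' @return area in km^2.
#' @export
landscape_area_km2 <- function(geometry) {
  n_cells(geometry) * geometry$cell_size^2 * 1e-6
}

cell_area_km2 <- function(geometry) geometry$cell_size^2 * 1e-6

# Map-coordinate centres of given cells (row/col vectors), in metres.
cell_centers <- function(geometry, row, col) {
  list(x = geometry$origin[1] + (col - 0.5) * geometry$cell_size,
       y = geometry$origin[2] - (row - 0.5) * geometry$cell_size)
}

check_layer <- function(mat, geometry, name) {
  if (!is.matrix(mat) || nrow(mat) != geometry$n_rows || ncol(mat) != geometry$n_cols)
    stop(sprintf("layer '%s' must be a %d x %d matrix matching the geometry",
                 name, geometry$n_rows, geometry$n_cols))
  invisible(mat)
}

# ---------------------------------------------------------------------------
# Neighbourhood helpers shared by the morphology, patch and corridor code.
# Offsets are (drow, dcol); rook moves first, then diagonals.

neighbor_offsets <- function(connectivity = 8) {
  if (connectivity == 4) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8) {
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  } else stop("connectivity must be 4 or 8")
}

# Shift a matrix by (dr, dc), filling exposed cells with `fill`.
shift_matrix <- function(mat, dr, dc, fill) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) > 0L && length(sc) > 0L)
    out[sr, sc] <- mat[sr - dr, sc - dc]
  out
}

# Binary erosion by one step of the chosen connectivity; cells outside the
# raster count as background. Iterating w times erodes by chessboard
# (8-conn) or Manhattan (4-conn) radius w.
erode_mask <- function(mask, steps = 1L, connectivity = 8) {
  off <- neighbor_offsets(connectivity)
  for (s in seq_len(steps)) {
    out <- mask
    for (k in seq_len(nrow(off)))
      out <- out & shift_matrix(mask, off[k, 1], off[k, 2], FALSE)
    mask <- out
  }
  mask
}

# Binary dilation by `steps` of the chosen connectivity.
dilate_mask <- function(mask, steps = 1L, connectivity = 8) {
  off <- neighbor_offsets(connectivity)
  for (s in seq_len(steps)) {
    out <- mask
    for (k in seq_len(nrow(off)))
      out <- out | shift_matrix(mask, off[k, 1], off[k, 2], FALSE)
    mask <- out
  }
  mask
}

#' Label connected components of a binary raster
#'
#' Components of `TRUE` cells under 4- or 8-connectivity. Used for habitat
#' patch extraction and throughout the MSPA segmentation.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape; 0 for `FALSE` cells, components
#'   numbered from 1 in order of their first cell (column-major scan).
#' @export
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  if (length(idx) == 1L) { lab[idx] <- 1L; return(lab) }
  # vertex ids = positions within idx
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  off <- neighbor_offsets(connectivity)
  # only "forward" half of the offsets to avoid duplicate edges
  keep <- off[, 1] > 0L | (off[, 1] == 0L & off[, 2] > 0L)
  off <- off[keep, , drop = FALSE]
  ee <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    r2 <- row + off[k, 1]; c2 <- col + off[k, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    j <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- mask[j]
    if (!any(ok2)) next
    ee[[k]] <- rbind(pos[idx[ok]][ok2], pos[j][ok2])
  }
  edges <- do.call(cbind, ee)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && ncol(edges) > 0L)
    g <- igraph::add_edges(g, as.vector(edges))
  memb <- igraph::components(g)$membership
  # renumber in first-appearance order
  first <- !duplicated(memb)
  ren <- integer(max(memb))
  ren[memb[first]] <- seq_len(sum(first))
  lab[idx] <- ren[memb]
  lab
}

# ---------------------------------------------------------------------------
# Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
# separable lower-envelope algorithm. Distances in cell units, squared.

dt_1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  if (n > 1L) for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance to the nearest marked cell
#'
#' Exact Euclidean distance (between cell centres, in metres) from every
#' cell to the nearest `TRUE` cell, via the separable lower-envelope squared
#' distance transform. Marked cells get 0; if no cell is marked, all
#' distances are `Inf`.
#'
#' @param mask logical matrix (e.g. a rasterized road layer).
#' @param geometry a [grid_geometry()].
#' @return numeric matrix of distances in metres.
#' @export
distance_transform <- function(mask, geometry) {
  check_layer(mask, geometry, "mask")
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  # large finite sentinel: Inf would give NaN in the envelope intersections
  f <- ifelse(mask, 0, 1e12)
  # pass 1: down each column; pass 2: across each row
  for (j in seq_len(ncol(f))) f[, j] <- dt_1d(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- dt_1d(f[i, ])
  sqrt(f) * geometry$cell_size
}

# ---------------------------------------------------------------------------
# Separable Gaussian smoothing with reflective padding (synthetic fields).

gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_reflect <- function(m, r) {
    nr <- nrow(m)
    top <- m[pmin(nr, pmax(1L, r:1)), , drop = FALSE]
    bot <- m[pmin(nr, pmax(1L, nr:(nr - r + 1L))), , drop = FALSE]
    rbind(top, m, bot)
  }
  conv_cols <- function(m) {
    p <- pad_reflect(m, r)
    out <- stats::filter(p, k, sides = 2)
    out[(r + 1L):(r + nrow(m)), , drop = FALSE]
  }
  m <- conv_cols(mat)
  m <- t(conv_cols(t(m)))
  unname(as.matrix(m))
}

# ---------------------------------------------------------------------------
# Esri ASCII grid I/O: the plain-text raster interchange format used for all
# raster artifacts. Values are written row by row from the northern edge.

#' Write a raster matrix as an Esri ASCII grid
#'
#' @param mat numeric, integer or logical matrix.
#' @param geometry a [grid_geometry()].
#' @param file output path (conventionally `.asc`).
#' @param nodata value standing for missing cells (default -9999).
#' @export
write_ascii_grid <- function(mat, geometry, file, nodata = -9999) {
  check_layer(mat, geometry, "raster")
  vals <- mat
  storage.mode(vals) <- "double"
  vals[is.na(vals)] <- nodata
  xll <- geometry$origin[1]
  yll <- geometry$origin[2] - geometry$n_rows * geometry$cell_size
  hdr <- c(
    sprintf("ncols %d", geometry$n_cols),
    sprintf("nrows %d", geometry$n_rows),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", geometry$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read an Esri ASCII grid
#'
#' @param file path to a `.asc` file written by [write_ascii_grid()] or any
#'   conforming tool.
#' @return a list with elements `values` (numeric matrix, `NA` where the
#'   grid holds its NODATA value) and `geometry` (a [grid_geometry()]).
#' @export
read_ascii_grid <- function(file) {
  lines <- readLines(file, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                         tolower(vapply(kv, `[`, "", 1)))
  nc <- as.integer(hdr[["ncols"]]); nr <- as.integer(hdr[["nrows"]])
  geometry <- grid_geometry(
    nr, nc, hdr[["cellsize"]],
    origin = c(hdr[["xllcorner"]], hdr[["yllcorner"]] + nr * hdr[["cellsize"]]))
  vals <- utils::read.table(file, skip = 6L)
  vals <- as.matrix(vals)
  dimnames(vals) <- NULL
  if (nrow(vals) != nr || ncol(vals) != nc)
    stop("ASCII grid body does not match its declared dimensions")
  if ("nodata_value" %in% names(hdr)) vals[vals == hdr[["nodata_value"]]] <- NA
  list(values = vals, geometry = geometry)
}
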