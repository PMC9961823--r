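#' Extract habitat patches from an MSPA map
#'
#' One patch per 8-connected (or 4-connected) component of the chosen MSPA
#' class — by default the core class, the basis for ecological source
#' selection. Patch areas are in km^2; boundary cells are patch cells with
#' at least one neighbour outside the patch (or on the raster border).
#'
#' @param map an `mspa_map` from [mspa_classify()], or an integer/logical
#'   matrix (with `geometry`).
#' @param source_class MSPA class name to extract (default `"core"`).
#' @param geometry required when `map` is a bare matrix.
#' @param connectivity 4 or 8.
#' @return an object of class `patch_set`: list with `geometry`, integer
#'   `labels` matrix (0 = no patch), and data.frame `patches`
#'   (`id`, `cells`, `area_km2`).
#' @export
extract_patches <- function(map, source_class = "core", geometry = NULL,
                            connectivity = 8) {
  if (inherits(map, "mspa_map")) {
    mask <- map$label == MSPA_CLASSES[[source_class]]
    geometry <- map$geometry
  } else {
    mask <- map == TRUE
    if (is.null(geometry)) stop("geometry must be supplied with a bare mask")
    check_layer(mask, geometry, "mask")
  }
  labels <- label_components(mask, connectivity)
  n <- max(labels)
  cells <- if (n > 0L) tabulate(labels[labels > 0L], n) else integer(0)
  structure(
    list(geometry = geometry, labels = labels,
         patches = data.frame(id = seq_len(n), cells = cells,
                              area_km2 = cells * cell_area_km2(geometry))),
    class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, %.4g km2 total\n",
              nrow(x$patches), sum(x$patches$area_km2)))
  invisible(x)
}

# boundary cells (row/col) of each patch: cells with a neighbour outside
# the patch or on the raster border
patch_boundary_cells <- function(patch_set) {
  labels <- patch_set$labels
  nr <- nrow(labels); nc <- ncol(labels)
  inside <- labels > 0L
  interior <- erode_mask(inside, 1L, 8)
  # a cell is interior to ITS patch only if all neighbours share its label
  same <- interior
  off <- neighbor_offsets(8)
  for (k in seq_len(nrow(off)))
    same <- same & (shift_matrix(labels, off[k, 1], off[k, 2], 0L) == labels)
  boundary <- inside & !same
  idx <- which(boundary)
  data.frame(id = labels[idx],
             row = ((idx - 1L) %% nr) + 1L,
             col = ((idx - 1L) %/% nr) + 1L)
}

#' Pairwise edge-to-edge patch distances
#'
#' Minimum Euclidean distance (metres, between cell centres) over all
#' boundary-cell pairs of each patch pair; 0 on the diagonal.
#'
#' @param patch_set a [extract_patches()] result.
#' @return symmetric numeric matrix (m).
#' @export
patch_distances <- function(patch_set) {
  stopifnot(inherits(patch_set, "patch_set"))
  n <- nrow(patch_set$patches)
  d <- matrix(0, n, n)
  if (n < 2L) return(d)
  b <- patch_boundary_cells(patch_set)
  xy <- cell_centers(patch_set$geometry, b$row, b$col)
  pts <- split(data.frame(x = xy$x, y = xy$y), factor(b$id, levels = seq_len(n)))
  for (i in seq_len(n - 1L)) {
    pi <- pts[[i]]
    for (j in (i + 1L):n) {
      pj <- pts[[j]]
      # chunk the outer product to bound memory on large boundaries
      best <- Inf
      step <- 2000L
      for (s in seq(1L, nrow(pi), by = step)) {
        e <- min(nrow(pi), s + step - 1L)
        dx <- outer(pi$x[s:e], pj$x, "-")
        dy <- outer(pi$y[s:e], pj$y, "-")
        best <- min(best, sqrt(min(dx * dx + dy * dy)))
      }
      d[i, j] <- d[j, i] <- best
    }
  }
  d
}

#' Build the thresholded habitat patch graph
#'
#' Links every patch pair whose edge-to-edge distance is within the
#' dispersal threshold; link (direct dispersal) probabilities follow the
#' negative-exponential kernel `p_ij = exp(-k d_ij)` calibrated so that
#' `p(threshold) = p_threshold` (defaults: 0.5 at 5000 m, i.e.
#' `k = ln 2 / 5000` per metre).
#'
#' @param patch_set a [extract_patches()] result.
#' @param AL_km2 total landscape area in km^2 (default: the full raster
#'   extent of the patch set's geometry).
#' @param threshold link distance threshold in metres.
#' @param p_threshold direct dispersal probability at the threshold.
#' @param distances optional precomputed distance matrix (m) from
#'   [patch_distances()].
#' @return an object of class `patch_graph`: patches data.frame, `AL_km2`,
#'   `dist` matrix, `links` (i, j, dist_m, p_ij data.frame), `threshold`,
#'   `p_threshold`.
#' @export
patch_graph <- function(patch_set, AL_km2 = NULL, threshold = 5000,
                        p_threshold = 0.5, distances = NULL) {
  stopifnot(inherits(patch_set, "patch_set"))
  if (is.null(AL_km2)) AL_km2 <- landscape_area_km2(patch_set$geometry)
  if (AL_km2 < sum(patch_set$patches$area_km2) - 1e-9)
    stop("AL_km2 smaller than the summed patch area")
  if (is.null(distances)) distances <- patch_distances(patch_set)
  n <- nrow(patch_set$patches)
  k <- -log(p_threshold) / threshold
  links <- data.frame(i = integer(0), j = integer(0),
                      dist_m = numeric(0), p_ij = numeric(0))
  if (n >= 2L) {
    ut <- which(upper.tri(distances) & distances <= threshold, arr.ind = TRUE)
    if (nrow(ut) > 0L)
      links <- data.frame(i = ut[, 1], j = ut[, 2],
                          dist_m = distances[ut],
                          p_ij = exp(-k * distances[ut]))
  }
  structure(
    list(patches = patch_set$patches, AL_km2 = AL_km2, dist = distances,
         links = links, threshold = threshold, p_threshold = p_threshold),
    class = "patch_graph")
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("<patch_graph> %d patches, %d links (<= %g m, p %.2f), AL %.4g km2\n",
              nrow(x$patches), nrow(x$links), x$threshold, x$p_threshold,
              x$AL_km2))
  invisible(x)
}

# igraph of the thresholded links (unweighted)
link_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = nrow(graph$patches), directed = FALSE)
  if (nrow(graph$links) > 0L)
    g <- igraph::add_edges(g, rbind(graph$links$i, graph$links$j))
  g
}

# topological link counts nl_ij (shortest path in links); Inf if unreachable
nl_matrix <- function(graph) {
  igraph::distances(link_igraph(graph), weights = NA)
}

# maximum-product path probabilities p*_ij via shortest paths on -log p
pstar_matrix <- function(graph) {
  g <- link_igraph(graph)
  w <- -log(graph$links$p_ij)
  d <- igraph::distances(g, weights = if (length(w)) w else NULL)
  p <- exp(-d)            # unreachable: exp(-Inf) = 0
  diag(p) <- 1
  p
}

#' Integral index of connectivity (IIC)
#'
#' `IIC = sum_ij a_i a_j / (1 + nl_ij) / AL^2` over all ordered patch
#' pairs including `i = j` (`nl_ii = 0`), where `nl_ij` is the number of
#' links on the shortest topological path in the thresholded patch graph;
#' unreachable pairs contribute 0. Lies in `[0, 1]`; equals 1 when a
#' single patch fills the landscape.
#'
#' @param graph a [patch_graph()].
#' @return IIC value.
#' @export
iic <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"))
  if (graph$AL_km2 <= 0) stop("AL must be positive")
  a <- graph$patches$area_km2
  if (length(a) == 0L) return(0)
  nl <- nl_matrix(graph)
  contrib <- outer(a, a) / (1 + nl)   # unreachable: /Inf -> 0
  sum(contrib) / graph$AL_km2^2
}

#' Probability of connectivity (PC)
#'
#' `PC = sum_ij a_i a_j p*_ij / AL^2` over all ordered pairs including
#' `i = j` (`p*_ii = 1`), where `p*_ij` is the maximum product of direct
#' link probabilities over paths in the thresholded graph; unreachable
#' pairs contribute 0.
#'
#' @param graph a [patch_graph()].
#' @return PC value in `[0, 1]`.
#' @export
pc <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"))
  if (graph$AL_km2 <= 0) stop("AL must be positive")
  a <- graph$patches$area_km2
  if (length(a) == 0L) return(0)
  sum(outer(a, a) * pstar_matrix(graph)) / graph$AL_km2^2
}

# drop patch i (and its links) from a graph; AL unchanged
drop_patch <- function(graph, i) {
  keep <- setdiff(seq_len(nrow(graph$patches)), i)
  links <- graph$links[graph$links$i != i & graph$links$j != i, , drop = FALSE]
  remap <- match(seq_len(nrow(graph$patches)), keep)
  links$i <- remap[links$i]; links$j <- remap[links$j]
  structure(
    list(patches = graph$patches[keep, , drop = FALSE],
         AL_km2 = graph$AL_km2,
         dist = graph$dist[keep, keep, drop = FALSE],
         links = links, threshold = graph$threshold,
         p_threshold = graph$p_threshold),
    class = "patch_graph")
}

#' Patch importance by removal (dIIC / dPC)
#'
#' `d_i = 100 (M - M_remove(i)) / M` where `M_remove(i)` recomputes the
#' index with patch `i` and its links deleted (AL unchanged). Positive for
#' every patch with positive area.
#'
#' @param graph a [patch_graph()].
#' @param metric `"PC"` (default) or `"IIC"`.
#' @return numeric vector of d-values in percent, one per patch.
#' @export
delta_importance <- function(graph, metric = c("PC", "IIC")) {
  metric <- match.arg(metric)
  fn <- if (metric == "PC") pc else iic
  m <- fn(graph)
  if (m <= 0) stop("global ", metric, " is zero; importances undefined")
  n <- nrow(graph$patches)
  vapply(seq_len(n), function(i) 100 * (m - fn(drop_patch(graph, i))) / m, 0)
}

#' Connectivity report with source ranking
#'
#' Computes global IIC and PC plus per-patch dIIC and dPC, ranked by dPC
#' descending (ties: larger area, then smaller id) — the ranking used to
#' pick ecological sources.
#'
#' @param graph a [patch_graph()].
#' @return an object of class `connectivity_report`: data.frame `ranking`
#'   (`rank`, `id`, `dPC`, `dIIC`, `area_km2`) plus `IIC`, `PC`.
#' @export
connectivity_report <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"))
  dpc <- delta_importance(graph, "PC")
  diic <- delta_importance(graph, "IIC")
  ord <- order(-dpc, -graph$patches$area_km2, graph$patches$id)
  ranking <- data.frame(rank = seq_along(ord),
                        id = graph$patches$id[ord],
                        dPC = dpc[ord], dIIC = diic[ord],
                        area_km2 = graph$patches$area_km2[ord],
                        row.names = NULL)
  structure(list(ranking = ranking, IIC = iic(graph), PC = pc(graph)),
            class = "connectivity_report")
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat(sprintf("<connectivity_report> IIC %.6g, PC %.6g\n", x$IIC, x$PC))
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Select ecological source patches
#'
#' The `top_n` patches by dPC (ties: larger area, then smaller id). Warns
#' and returns all patches when fewer than `top_n` exist.
#'
#' @param report a [connectivity_report()].
#' @param top_n number of sources (default 10).
#' @return integer vector of patch ids, in rank order.
#' @export
select_sources <- function(report, top_n = 10) {
  stopifnot(inherits(report, "connectivity_report"))
  n <- nrow(report$ranking)
  if (n < top_n) {
    warning(sprintf("only %d patches available (requested %d); returning all",
                    n, top_n))
    top_n <- n
  }
  report$ranking$id[seq_len(top_n)]
}
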