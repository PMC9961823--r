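# Cells are addressed by their column-major linear index; the cell graph
# has one vertex per cell and 8-neighbour edges weighted by
# cell_size * move_length * (R_u + R_v) / 2 (move_length 1 for rook moves,
# sqrt(2) for diagonal moves).

#' Build the weighted cell graph of a resistance surface
#'
#' Precomputes the 8-connected (or 4-connected) cell graph used by
#' [cost_distance()] and [least_cost_corridors()]; build it once when
#' running several corridor extractions on the same surface.
#'
#' @param resistance a `resistance_surface` (from [weighted_sum()] /
#'   [build_resistance()]), or a plain positive numeric matrix with
#'   `geometry`.
#' @param geometry required when `resistance` is a bare matrix.
#' @param connectivity 8 (default) or 4.
#' @return an object of class `cost_graph`.
#' @export
cost_graph <- function(resistance, geometry = NULL, connectivity = 8) {
  r <- as_resistance(resistance, geometry)
  geometry <- r$geometry
  vals <- r$values
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("resistance must be finite and positive everywhere")
  nr <- geometry$n_rows; nc <- geometry$n_cols
  off <- neighbor_offsets(connectivity)
  off <- off[off[, 1] > 0L | (off[, 1] == 0L & off[, 2] > 0L), , drop = FALSE]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  row <- rep(seq_len(nr), nc)
  col <- rep(seq_len(nc), each = nr)
  idx <- seq_len(nr * nc)
  for (k in seq_len(nrow(off))) {
    r2 <- row + off[k, 1]; c2 <- col + off[k, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    i <- idx[ok]
    mlen <- if (off[k, 1] != 0L && off[k, 2] != 0L) sqrt(2) else 1
    from <- c(from, i); to <- c(to, j)
    w <- c(w, geometry$cell_size * mlen * (vals[i] + vals[j]) / 2)
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  structure(list(graph = g, geometry = geometry, values = vals,
                 connectivity = connectivity),
            class = "cost_graph")
}

as_resistance <- function(resistance, geometry) {
  if (inherits(resistance, "resistance_surface")) return(resistance)
  if (is.null(geometry)) stop("geometry must be supplied with a bare matrix")
  check_layer(resistance, geometry, "resistance")
  structure(list(geometry = geometry, values = resistance),
            class = "resistance_surface")
}

# attach a virtual vertex tied by zero-weight edges to the given cells
with_virtual_source <- function(cg, cells) {
  n <- n_cells(cg$geometry)
  g <- igraph::add_vertices(cg$graph, 1)
  g <- igraph::add_edges(g, rbind(rep(n + 1L, length(cells)), cells),
                         weight = rep(0, length(cells)))
  g
}

#' Accumulated cost distance from a source cell set
#'
#' Dijkstra shortest-path cost over the weighted cell graph from a set of
#' source cells (multi-source: each cell's cost is the minimum over the
#' set). Source cells have cost 0.
#'
#' @param resistance a `resistance_surface` or positive matrix.
#' @param source_cells data.frame with `row`, `col` columns, or a vector
#'   of column-major linear cell indices.
#' @param geometry required for a bare matrix.
#' @param graph optional precomputed [cost_graph()].
#' @return numeric matrix of accumulated costs.
#' @export
cost_distance <- function(resistance, source_cells, geometry = NULL,
                          graph = NULL) {
  if (is.null(graph)) graph <- cost_graph(resistance, geometry)
  cells <- as_cell_index(source_cells, graph$geometry)
  if (length(cells) == 0L) stop("source cell set is empty")
  g2 <- with_virtual_source(graph, cells)
  n <- n_cells(graph$geometry)
  d <- igraph::distances(g2, v = n + 1L, algorithm = "dijkstra")[1, seq_len(n)]
  matrix(d, graph$geometry$n_rows, graph$geometry$n_cols)
}

as_cell_index <- function(source_cells, geometry) {
  if (is.data.frame(source_cells))
    (source_cells$col - 1L) * geometry$n_rows + source_cells$row
  else as.integer(source_cells)
}

#' Least-cost corridors between all source pairs
#'
#' One corridor per unordered pair of source patches: the minimum
#' cumulative resistance path between the two patches' cell sets, found by
#' multi-source Dijkstra from each patch and predecessor backtracking to
#' the minimising cell of the partner patch. Corridors may pass through
#' intermediate sources.
#'
#' @param resistance a `resistance_surface` or positive matrix.
#' @param patch_set the [extract_patches()] result holding the sources.
#' @param source_ids patch ids acting as sources (>= 2).
#' @param geometry required for a bare matrix.
#' @param graph optional precomputed [cost_graph()].
#' @return an object of class `corridor_set`: `geometry`, data.frame
#'   `table` (`i`, `j`, `cost`), and `paths` — a list of 2-column
#'   (row, col) matrices, one per table row.
#' @export
least_cost_corridors <- function(resistance, patch_set, source_ids,
                                 geometry = NULL, graph = NULL) {
  stopifnot(inherits(patch_set, "patch_set"))
  source_ids <- as.integer(source_ids)
  if (length(source_ids) < 2L) stop("need at least two sources")
  if (anyDuplicated(source_ids)) stop("duplicate source ids")
  if (is.null(graph)) graph <- cost_graph(resistance, geometry)
  geometry <- graph$geometry
  nrr <- geometry$n_rows
  n <- n_cells(geometry)
  cells_of <- lapply(source_ids, function(id) which(patch_set$labels == id))
  empty <- lengths(cells_of) == 0L
  if (any(empty))
    stop("source id(s) absent from the patch set: ",
         paste(source_ids[empty], collapse = ", "))
  k <- length(source_ids)
  tab <- data.frame(i = integer(0), j = integer(0), cost = numeric(0))
  paths <- list()
  for (a in seq_len(k - 1L)) {
    g2 <- with_virtual_source(graph, cells_of[[a]])
    d <- igraph::distances(g2, v = n + 1L, algorithm = "dijkstra")[1, ]
    targets <- integer(k)
    for (b in (a + 1L):k) {
      cb <- cells_of[[b]]
      targets[b] <- cb[which.min(d[cb])]
    }
    vp <- igraph::shortest_paths(g2, from = n + 1L,
                                 to = targets[(a + 1L):k],
                                 output = "vpath")$vpath
    for (b in (a + 1L):k) {
      cells <- as.integer(vp[[b - a]])
      cells <- cells[cells <= n]          # strip the virtual vertex
      paths[[length(paths) + 1L]] <-
        cbind(row = ((cells - 1L) %% nrr) + 1L,
              col = ((cells - 1L) %/% nrr) + 1L)
      tab <- rbind(tab, data.frame(i = source_ids[a], j = source_ids[b],
                                   cost = unname(d[targets[b]])))
    }
  }
  structure(list(geometry = geometry, table = tab, paths = paths),
            class = "corridor_set")
}

#' @export
print.corridor_set <- function(x, ...) {
  imp <- if ("important" %in% names(x$table)) sum(x$table$important) else NA
  cat(sprintf("<corridor_set> %d corridors%s, cost range [%.4g, %.4g]\n",
              nrow(x$table),
              if (!is.na(imp)) sprintf(" (%d important)", imp) else "",
              min(x$table$cost), max(x$table$cost)))
  invisible(x)
}

#' Gravity-model interaction matrix
#'
#' Interaction strength between source patches i and j:
#' `G_ij = Lmax^2 ln(S_i) ln(S_j) / (L_ij^2 P_i P_j)` with `S_i` the patch
#' area in hectares (must exceed 1 ha so the log is positive), `P_i` the
#' mean resistance over the patch's cells, `L_ij` the corridor's
#' cumulative cost and `Lmax` the largest corridor cost.
#'
#' @param patch_set the [extract_patches()] result holding the sources.
#' @param corridors a [least_cost_corridors()] result.
#' @param resistance the `resistance_surface` the corridors were traced on
#'   (or matrix with the patch set's geometry).
#' @param patch_resistance `"mean"` (default) or `"sum"` aggregation for
#'   `P_i`.
#' @return an object of class `gravity_matrix`: symmetric `G` (named by
#'   patch id, zero diagonal), plus the inputs `S_ha`, `P`, `L`, `L_max`.
#' @export
gravity_matrix <- function(patch_set, corridors, resistance,
                           patch_resistance = c("mean", "sum")) {
  stopifnot(inherits(patch_set, "patch_set"),
            inherits(corridors, "corridor_set"))
  patch_resistance <- match.arg(patch_resistance)
  r <- as_resistance(resistance, patch_set$geometry)
  ids <- sort(unique(c(corridors$table$i, corridors$table$j)))
  k <- length(ids)
  cs <- patch_set$geometry$cell_size
  S <- vapply(ids, function(id) sum(patch_set$labels == id) * cs^2 / 1e4, 0)
  if (any(S <= 1))
    stop("patch area(s) <= 1 ha make ln(S) non-positive: ",
         paste(ids[S <= 1], collapse = ", "),
         "; supply larger patches or coarser area units")
  agg <- if (patch_resistance == "mean") mean else sum
  P <- vapply(ids, function(id) agg(r$values[patch_set$labels == id]), 0)
  L <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(L) <- 0
  ii <- match(corridors$table$i, ids); jj <- match(corridors$table$j, ids)
  L[cbind(ii, jj)] <- L[cbind(jj, ii)] <- corridors$table$cost
  if (any(is.na(L))) stop("corridor table does not cover all source pairs")
  if (any(L[upper.tri(L)] == 0))
    stop("zero corridor cost (overlapping sources?)")
  L_max <- max(L)
  G <- matrix(0, k, k, dimnames = list(ids, ids))
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
    G[a, b] <- G[b, a] <-
      L_max^2 * log(S[a]) * log(S[b]) / (L[a, b]^2 * P[a] * P[b])
  structure(list(G = G, S_ha = stats::setNames(S, ids),
                 P = stats::setNames(P, ids), L = L, L_max = L_max,
                 area_unit = "ha"),
            class = "gravity_matrix")
}

#' @export
print.gravity_matrix <- function(x, ...) {
  cat(sprintf("<gravity_matrix> %d patches, L_max %.4g\n", nrow(x$G), x$L_max))
  print(round(x$G, 2))
  invisible(x)
}

#' Rank corridors by gravity-model importance
#'
#' Sorts corridors by interaction strength `G_ij` descending (ties: smaller
#' cumulative cost, then i/j order) and flags the `top_k` as important.
#'
#' @param corridors a [least_cost_corridors()] result.
#' @param gravity the matching [gravity_matrix()].
#' @param top_k number of corridors to flag (default 15).
#' @return the `corridor_set` with `G`, `rank` and `important` columns
#'   added to its table.
#' @export
rank_corridors <- function(corridors, gravity, top_k = 15) {
  stopifnot(inherits(corridors, "corridor_set"),
            inherits(gravity, "gravity_matrix"))
  tab <- corridors$table
  if (top_k > nrow(tab)) stop("top_k exceeds the number of corridors")
  gi <- match(as.character(tab$i), rownames(gravity$G))
  gj <- match(as.character(tab$j), rownames(gravity$G))
  tab$G <- gravity$G[cbind(gi, gj)]
  ord <- order(-tab$G, tab$cost, tab$i, tab$j)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  tab$important <- tab$rank <= top_k
  corridors$table <- tab
  corridors
}

#' Write corridors as GeoJSON LineStrings
#'
#' Vertices are cell centres in map coordinates; properties carry the
#' endpoint ids, cumulative cost and (when ranked) gravity score, rank and
#' importance flag.
#'
#' @param corridors a `corridor_set`.
#' @param file output path.
#' @export
write_corridors_geojson <- function(corridors, file) {
  stopifnot(inherits(corridors, "corridor_set"))
  g <- corridors$geometry
  feats <- lapply(seq_len(nrow(corridors$table)), function(r) {
    p <- corridors$paths[[r]]
    xy <- cell_centers(g, p[, "row"], p[, "col"])
    props <- as.list(corridors$table[r, , drop = FALSE])
    props <- lapply(props, unname)
    list(type = "Feature", properties = props,
         geometry = list(type = "LineString",
                         coordinates = mapply(c, xy$x, xy$y, SIMPLIFY = FALSE)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
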