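# Independent brute-force oracles. These deliberately share no code with the
# package internals: Dijkstra is a plain O(V^2) array scan over an explicit
# edge list; path-based quantities come from exhaustive simple-path
# enumeration (feasible for graphs of <= 8 nodes).

# --- exhaustive simple-path enumeration on an adjacency matrix --------------
# adj: logical/0-1 symmetric matrix. Returns a list of integer paths i -> j.
enumerate_simple_paths <- function(adj, i, j) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == j) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (adj[last, v] && !(v %in% path)) walk(c(path, v))
    }
  }
  walk(i)
  paths
}

# shortest topological link count between i and j; Inf if unreachable
oracle_nl <- function(adj, i, j) {
  if (i == j) return(0)
  paths <- enumerate_simple_paths(adj, i, j)
  if (length(paths) == 0L) return(Inf)
  min(lengths(paths)) - 1
}

# maximum product of link probabilities over all simple paths; pmat holds
# the direct probability for linked pairs and 0 elsewhere
oracle_pstar <- function(pmat, i, j) {
  if (i == j) return(1)
  adj <- pmat > 0
  paths <- enumerate_simple_paths(adj, i, j)
  if (length(paths) == 0L) return(0)
  max(vapply(paths, function(p) {
    prod(pmat[cbind(p[-length(p)], p[-1])])
  }, 0))
}

oracle_iic <- function(areas, adj, AL) {
  n <- length(areas)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    nl <- oracle_nl(adj, i, j)
    if (is.finite(nl)) tot <- tot + areas[i] * areas[j] / (1 + nl)
  }
  tot / AL^2
}

oracle_pc <- function(areas, pmat, AL) {
  n <- length(areas)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    tot <- tot + areas[i] * areas[j] * oracle_pstar(pmat, i, j)
  tot / AL^2
}

# Freeman betweenness normalised by (N-1)(N-2)/2, by path enumeration
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
    paths <- enumerate_simple_paths(adj, j, k)
    if (length(paths) == 0L) next
    len <- min(lengths(paths))
    shortest <- paths[lengths(paths) == len]
    for (i in seq_len(n)) {
      if (i == j || i == k) next
      through <- sum(vapply(shortest, function(p) i %in% p, TRUE))
      bc[i] <- bc[i] + through / length(shortest)
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# --- brute-force Dijkstra on the 8-connected cell grid ----------------------
# Step cost: cell_size * move_length * (R_u + R_v) / 2. Returns the full
# accumulated-cost matrix from a set of source linear indices.
oracle_grid_dijkstra <- function(resistance, cell_size, source_idx) {
  nr <- nrow(resistance); nc <- ncol(resistance)
  n <- nr * nc
  dist <- rep(Inf, n)
  dist[source_idx] <- 0
  done <- rep(FALSE, n)
  moves <- cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
                 dc = c(0, 0, -1, 1, -1, 1, -1, 1),
                 len = c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2)))
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    ur <- ((u - 1) %% nr) + 1; uc <- ((u - 1) %/% nr) + 1
    for (m in seq_len(nrow(moves))) {
      vr <- ur + moves[m, "dr"]; vc <- uc + moves[m, "dc"]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      v <- (vc - 1) * nr + vr
      w <- cell_size * moves[m, "len"] * (resistance[u] + resistance[v]) / 2
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  matrix(dist, nr, nc)
}

# --- brute-force chessboard erosion check -----------------------------------
# core oracle: every cell of the (2w+1)^2 window (clipped cells count as
# background) is foreground
oracle_core <- function(mask, w) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!mask[r, cc]) next
    rs <- (r - w):(r + w); cs <- (cc - w):(cc + w)
    if (any(rs < 1 | rs > nr) || any(cs < 1 | cs > nc)) next
    out[r, cc] <- all(mask[rs, cs])
  }
  out
}

# --- helpers to fabricate patch graphs without rasters ----------------------
# areas in km^2; dist in metres (symmetric, 0 diagonal)
make_test_graph <- function(areas, dist, AL, threshold = 5000,
                            p_threshold = 0.5) {
  n <- length(areas)
  k <- -log(p_threshold) / threshold
  links <- data.frame(i = integer(0), j = integer(0),
                      dist_m = numeric(0), p_ij = numeric(0))
  if (n >= 2) {
    ut <- which(upper.tri(dist) & dist <= threshold, arr.ind = TRUE)
    if (nrow(ut) > 0)
      links <- data.frame(i = ut[, 1], j = ut[, 2], dist_m = dist[ut],
                          p_ij = exp(-k * dist[ut]))
  }
  structure(
    list(patches = data.frame(id = seq_len(n), cells = NA_integer_,
                              area_km2 = areas),
         AL_km2 = AL, dist = dist, links = links,
         threshold = threshold, p_threshold = p_threshold),
    class = "patch_graph")
}

# adjacency and direct-probability matrices of a patch_graph (for oracles)
graph_adj <- function(graph) {
  n <- nrow(graph$patches)
  adj <- matrix(FALSE, n, n)
  if (nrow(graph$links) > 0)
    adj[cbind(graph$links$i, graph$links$j)] <-
      adj[cbind(graph$links$j, graph$links$i)] <- TRUE
  adj
}

graph_pmat <- function(graph) {
  n <- nrow(graph$patches)
  p <- matrix(0, n, n)
  if (nrow(graph$links) > 0)
    p[cbind(graph$links$i, graph$links$j)] <-
      p[cbind(graph$links$j, graph$links$i)] <- graph$links$p_ij
  p
}

# random patch graph on <= n_max nodes (distances drawn so some pairs link)
random_test_graph <- function(n_max = 7, threshold = 5000) {
  n <- sample(2:n_max, 1)
  areas <- stats::runif(n, 0.5, 5)
  pts <- matrix(stats::runif(2 * n, 0, 12000), n, 2)
  dist <- as.matrix(stats::dist(pts))
  make_test_graph(areas, dist, AL = sum(areas) + stats::runif(1, 1, 50),
                  threshold = threshold)
}
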