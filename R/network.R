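#' Betweenness centrality of habitat patches
#'
#' Freeman betweenness on the thresholded (unweighted) patch link graph:
#' for node i, the sum over unordered pairs \{j, k\} (both different from
#' i) of the fraction of shortest j-k paths passing through i, normalised
#' by the pair count `(N - 1)(N - 2) / 2` so the middle node of a path
#' graph scores 1. Disconnected pairs contribute 0.
#'
#' @param graph a [patch_graph()] with at least 3 patches.
#' @return an object of class `betweenness_report`: data.frame `ranking`
#'   (`rank`, `id`, `BC`, `area_km2`) sorted by BC descending (ties:
#'   larger area, then smaller id).
#' @export
betweenness_report <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"))
  n <- nrow(graph$patches)
  if (n < 3L) stop("betweenness normalisation needs at least 3 patches")
  bc <- igraph::betweenness(link_igraph(graph), directed = FALSE,
                            weights = NA) / ((n - 1) * (n - 2) / 2)
  ord <- order(-bc, -graph$patches$area_km2, graph$patches$id)
  structure(
    list(ranking = data.frame(rank = seq_len(n),
                              id = graph$patches$id[ord],
                              BC = unname(bc[ord]),
                              area_km2 = graph$patches$area_km2[ord],
                              row.names = NULL)),
    class = "betweenness_report")
}

#' @export
print.betweenness_report <- function(x, ...) {
  cat("<betweenness_report>\n")
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Select stepping-stone patches
#'
#' The `top_n` non-source patches by betweenness centrality (ties: larger
#' area, then smaller id) — intermediate patches that relay movement
#' between ecological sources.
#'
#' Candidate stones must exceed `min_area_km2` (default 1 ha): the planned
#' network scores corridors with the gravity model, whose `ln(S)` patch
#' mass is non-positive for patches of 1 ha or less, so smaller patches
#' cannot participate.
#'
#' @param report a [betweenness_report()].
#' @param sources patch ids already serving as sources (excluded).
#' @param top_n number of stones (default 10).
#' @param min_area_km2 minimum stone area (default 0.01 km2 = 1 ha).
#' @return integer vector of patch ids in rank order.
#' @export
select_stepping_stones <- function(report, sources, top_n = 10,
                                   min_area_km2 = 0.01) {
  stopifnot(inherits(report, "betweenness_report"))
  pool <- report$ranking[!report$ranking$id %in% sources &
                           report$ranking$area_km2 > min_area_km2, ,
                         drop = FALSE]
  if (top_n == 0L) return(integer(0))
  if (nrow(pool) < top_n) {
    warning(sprintf("only %d non-source patches available (requested %d); returning all",
                    nrow(pool), top_n))
    top_n <- nrow(pool)
  }
  pool$id[seq_len(top_n)]
}

#' Planned corridor network over sources plus stepping stones
#'
#' Rebuilds least-cost corridors between all unordered pairs of the union
#' of sources and stones (`C(|sources| + |stones|, 2)` corridors), scores
#' them with the gravity model and flags the `top_k_important`.
#'
#' @param resistance a `resistance_surface` or positive matrix.
#' @param patch_set the patch set holding sources and stones.
#' @param sources,stones disjoint patch id vectors.
#' @param top_k_important corridors to flag (default 8).
#' @param geometry required for a bare matrix.
#' @param graph optional precomputed [cost_graph()].
#' @return a ranked `corridor_set` (see [rank_corridors()]) with a
#'   `gravity` attribute.
#' @export
planned_network <- function(resistance, patch_set, sources, stones,
                            top_k_important = 8, geometry = NULL,
                            graph = NULL) {
  if (length(intersect(sources, stones)) > 0L)
    stop("sources and stones must be disjoint")
  nodes <- c(sources, stones)
  corr <- least_cost_corridors(resistance, patch_set, nodes,
                               geometry = geometry, graph = graph)
  grav <- gravity_matrix(patch_set, corr, resistance)
  out <- rank_corridors(corr, grav, top_k = top_k_important)
  attr(out, "gravity") <- grav
  out
}

#' Network structure quality indices
#'
#' The planar-network indices of quantitative geography for a network of
#' `V` nodes and `L` links: closure `alpha = (L - V + 1) / (2V - 5)`
#' (share of realised independent cycles), line-point rate
#' `beta = L / V`, and connectivity rate `gamma = L / (3 (V - 2))`
#' (share of the maximal planar link count). `alpha` and `gamma` require
#' `V >= 3`.
#'
#' @param V node count (>= 3).
#' @param L link count (>= 0).
#' @return an object of class `network_quality`: `V`, `L`, `alpha`,
#'   `beta`, `gamma`.
#' @export
network_quality <- function(V, L) {
  V <- as.integer(V); L <- as.integer(L)
  if (is.na(V) || V < 3L) stop("network indices need V >= 3 nodes")
  if (is.na(L) || L < 0L) stop("L must be non-negative")
  structure(list(V = V, L = L,
                 alpha = (L - V + 1) / (2 * V - 5),
                 beta = L / V,
                 gamma = L / (3 * (V - 2))),
            class = "network_quality")
}

#' @export
print.network_quality <- function(x, ...) {
  cat(sprintf("<network_quality> V = %d, L = %d | alpha %.3f, beta %.3f, gamma %.3f\n",
              x$V, x$L, x$alpha, x$beta, x$gamma))
  invisible(x)
}
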