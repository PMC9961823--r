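#' Pipeline configuration
#'
#' Bundles every stage's parameters with the field defaults: MSPA on the
#' grassland foreground with edge width 1 and the 8-neighbourhood; patch
#' links within 5000 m at probability 0.5; the 10 top-dPC patches as
#' sources; the shipped reclass rules and weights; 15 important potential
#' corridors; 10 stepping stones and 8 important planned corridors.
#'
#' @param simulation a [simulation_config()] (used when `input_dir` is
#'   `NULL`).
#' @param input_dir optional directory of a saved [landscape_stack()];
#'   when given, simulation is skipped.
#' @param foreground_classes MSPA foreground classes.
#' @param edge_width,connectivity MSPA parameters.
#' @param threshold,p_threshold patch-link distance (m) and probability.
#' @param top_n_sources ecological sources to select.
#' @param rules,weights resistance reclass rules and factor weights.
#' @param top_k_corridors important potential corridors to flag.
#' @param n_stones stepping stones to add.
#' @param top_k_planned important planned corridors to flag.
#' @param seed seed (overrides the simulation config's seed).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input_dir = NULL,
                            foreground_classes = "grassland",
                            edge_width = 1L, connectivity = 8,
                            threshold = 5000, p_threshold = 0.5,
                            top_n_sources = 10L,
                            rules = default_reclass_rules(),
                            weights = default_weights(),
                            top_k_corridors = 15L,
                            n_stones = 10L,
                            top_k_planned = 8L,
                            seed = NULL) {
  if (!is.null(seed)) simulation$seed <- as.integer(seed)
  structure(
    list(simulation = simulation, input_dir = input_dir,
         foreground_classes = foreground_classes,
         edge_width = as.integer(edge_width), connectivity = connectivity,
         threshold = threshold, p_threshold = p_threshold,
         top_n_sources = as.integer(top_n_sources),
         rules = rules, weights = weights,
         top_k_corridors = as.integer(top_k_corridors),
         n_stones = as.integer(n_stones),
         top_k_planned = as.integer(top_k_planned)),
    class = "pipeline_config")
}

config_as_list <- function(config) {
  g <- config$simulation$geometry
  list(
    simulation = list(
      n_rows = g$n_rows, n_cols = g$n_cols, cell_size = g$cell_size,
      origin = g$origin,
      foreground_fraction = config$simulation$foreground_fraction,
      n_blobs = config$simulation$n_blobs,
      fragmentation = config$simulation$fragmentation,
      east_west_gradient = config$simulation$east_west_gradient,
      n_roads_main = config$simulation$n_roads_main,
      n_roads_branch = config$simulation$n_roads_branch,
      seed = config$simulation$seed),
    input_dir = config$input_dir,
    mspa = list(foreground_classes = config$foreground_classes,
                edge_width = config$edge_width,
                connectivity = config$connectivity),
    connectivity = list(threshold = config$threshold,
                        p_threshold = config$p_threshold,
                        top_n_sources = config$top_n_sources),
    weights = as.list(config$weights),
    corridors = list(top_k = config$top_k_corridors),
    optimization = list(n_stones = config$n_stones,
                        top_k_important = config$top_k_planned))
}

#' Read a pipeline configuration from YAML
#'
#' Understands the layout written by [run_pipeline()]'s resolved-config
#' file; absent fields fall back to the defaults of [pipeline_config()].
#'
#' @param file YAML path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  y <- yaml::read_yaml(file)
  sim <- y$simulation
  simulation <- simulation_config(
    geometry = grid_geometry(sim$n_rows %||% 200, sim$n_cols %||% 200,
                             sim$cell_size %||% 30,
                             origin = unlist(sim$origin) %||% c(0, 0)),
    foreground_fraction = sim$foreground_fraction %||% 0.80,
    n_blobs = sim$n_blobs %||% 12,
    fragmentation = sim$fragmentation %||% 6,
    east_west_gradient = sim$east_west_gradient %||% TRUE,
    n_roads_main = sim$n_roads_main %||% 2,
    n_roads_branch = sim$n_roads_branch %||% 8,
    seed = sim$seed %||% 1L)
  weights <- if (!is.null(y$weights)) unlist(y$weights) else default_weights()
  pipeline_config(
    simulation = simulation,
    input_dir = y$input_dir,
    foreground_classes = y$mspa$foreground_classes %||% "grassland",
    edge_width = y$mspa$edge_width %||% 1L,
    connectivity = y$mspa$connectivity %||% 8,
    threshold = y$connectivity$threshold %||% 5000,
    p_threshold = y$connectivity$p_threshold %||% 0.5,
    top_n_sources = y$connectivity$top_n_sources %||% 10L,
    weights = weights,
    top_k_corridors = y$corridors$top_k %||% 15L,
    n_stones = y$optimization$n_stones %||% 10L,
    top_k_planned = y$optimization$top_k_important %||% 8L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full ecological-network pipeline
#'
#' Executes simulate (or load) -> MSPA -> connectivity-based source
#' selection -> resistance surface -> potential corridors + gravity
#' ranking -> stepping stones + planned network -> network quality, and
#' writes every stage artifact plus a JSON run manifest (per stage:
#' outputs, md5 hashes, wall time). Identical config and seed give
#' identical artifact hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the manifest, invisibly; all artifacts are under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(stages = list())
  stage_files <- character(0)
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    list(result = res, wall_s = proc.time()[["elapsed"]] - t0)
  }
  record <- function(name, wall, files) {
    manifest$stages[[name]] <<- list(
      stage = name, wall_s = round(wall, 3),
      outputs = basename(files),
      md5 = unname(tools::md5sum(files)))
  }

  yaml::write_yaml(config_as_list(config), file.path(out_dir, "config.yaml"))

  # 1. simulate or load ----------------------------------------------------
  st <- t_stage("simulate", {
    if (is.null(config$input_dir)) simulate_landscape(config$simulation)
    else read_landscape_stack(config$input_dir)
  })
  stack <- st$result
  stack_dir <- file.path(out_dir, "stack")
  write_landscape_stack(stack, stack_dir)
  record("simulate", st$wall_s, list.files(stack_dir, full.names = TRUE))

  # 2. MSPA -----------------------------------------------------------------
  st <- t_stage("mspa", {
    bin <- binarize(stack$landuse, stack$geometry, config$foreground_classes)
    mspa_classify(bin, edge_width = config$edge_width,
                  connectivity = config$connectivity)
  })
  mspa <- st$result
  f1 <- file.path(out_dir, "mspa.asc"); write_mspa_map(mspa, f1)
  f2 <- file.path(out_dir, "mspa_stats.csv")
  utils::write.csv(mspa_stats(mspa), f2, row.names = FALSE)
  record("mspa", st$wall_s, c(f1, f2))

  # 3. connectivity ---------------------------------------------------------
  st <- t_stage("connectivity", {
    patches <- extract_patches(mspa, "core",
                               connectivity = config$connectivity)
    graph <- patch_graph(patches, threshold = config$threshold,
                         p_threshold = config$p_threshold)
    report <- connectivity_report(graph)
    list(patches = patches, graph = graph, report = report,
         sources = select_sources(report, config$top_n_sources))
  })
  conn <- st$result
  f1 <- file.path(out_dir, "patch_links.csv")
  utils::write.csv(conn$graph$links, f1, row.names = FALSE)
  f2 <- file.path(out_dir, "connectivity_report.csv")
  utils::write.csv(conn$report$ranking, f2, row.names = FALSE)
  f3 <- file.path(out_dir, "sources.csv")
  utils::write.csv(data.frame(source_rank = seq_along(conn$sources),
                              id = conn$sources), f3, row.names = FALSE)
  record("connectivity", st$wall_s, c(f1, f2, f3))

  # 4. resistance -----------------------------------------------------------
  st <- t_stage("resistance", build_resistance(stack, config$rules,
                                               config$weights))
  resistance <- st$result
  f1 <- file.path(out_dir, "resistance.asc")
  write_ascii_grid(resistance$values, stack$geometry, f1)
  record("resistance", st$wall_s, f1)

  # 5. potential corridors --------------------------------------------------
  st <- t_stage("corridors", {
    cg <- cost_graph(resistance, connectivity = 8)
    corr <- least_cost_corridors(resistance, conn$patches, conn$sources,
                                 graph = cg)
    grav <- gravity_matrix(conn$patches, corr, resistance)
    list(graph = cg,
         corridors = rank_corridors(corr, grav,
                                    top_k = config$top_k_corridors),
         gravity = grav)
  })
  corr <- st$result
  f1 <- file.path(out_dir, "corridors.geojson")
  write_corridors_geojson(corr$corridors, f1)
  f2 <- file.path(out_dir, "gravity.csv")
  utils::write.csv(corr$gravity$G, f2)
  record("corridors", st$wall_s, c(f1, f2))

  # 6. optimization ---------------------------------------------------------
  st <- t_stage("optimize", {
    bc <- betweenness_report(conn$graph)
    stones <- select_stepping_stones(bc, conn$sources, config$n_stones)
    planned <- planned_network(resistance, conn$patches, conn$sources,
                               stones, top_k_important = config$top_k_planned,
                               graph = corr$graph)
    before <- network_quality(length(conn$sources),
                              nrow(corr$corridors$table))
    after <- network_quality(length(conn$sources) + length(stones),
                             nrow(planned$table))
    list(bc = bc, stones = stones, planned = planned,
         before = before, after = after)
  })
  opt <- st$result
  f1 <- file.path(out_dir, "stepping_stones.csv")
  utils::write.csv(
    opt$bc$ranking[opt$bc$ranking$id %in% opt$stones, , drop = FALSE],
    f1, row.names = FALSE)
  f2 <- file.path(out_dir, "planned_network.geojson")
  write_corridors_geojson(opt$planned, f2)
  f3 <- file.path(out_dir, "network_quality.csv")
  utils::write.csv(data.frame(
    index = c("V", "L", "alpha", "beta", "gamma"),
    before = unlist(opt$before[c("V", "L", "alpha", "beta", "gamma")]),
    after = unlist(opt$after[c("V", "L", "alpha", "beta", "gamma")])),
    f3, row.names = FALSE)
  record("optimize", st$wall_s, c(f1, f2, f3))

  manifest$n_potential_corridors <- nrow(corr$corridors$table)
  manifest$n_planned_corridors <- nrow(opt$planned$table)
  manifest$sources <- conn$sources
  manifest$stones <- opt$stones
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
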