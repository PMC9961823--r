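#' MSPA class codes
#'
#' Integer codes used by the MSPA raster representation (and its ASCII-grid
#' export): 0 background, 1 core, 2 islet, 3 perforation, 4 edge, 5 loop,
#' 6 bridge, 7 branch.
#'
#' @export
MSPA_CLASSES <- c(background = 0L, core = 1L, islet = 2L, perforation = 3L,
                  edge = 4L, loop = 5L, bridge = 6L, branch = 7L)

#' Binarize a categorical land-use raster
#'
#' Marks the MSPA foreground: cells whose land-use class belongs to
#' `foreground_classes` (by default grassland, the habitat of interest;
#' everything else is background).
#'
#' @param landuse character matrix over [LANDUSE_CLASSES] (or any declared
#'   class set).
#' @param foreground_classes non-empty character vector of class names.
#' @param geometry a [grid_geometry()].
#' @param classes the declared class universe used for validation.
#' @return an object of class `binary_landscape`: list of `geometry` and
#'   logical `mask`.
#' @export
binarize <- function(landuse, geometry, foreground_classes = "grassland",
                     classes = LANDUSE_CLASSES) {
  check_layer(landuse, geometry, "landuse")
  if (length(foreground_classes) == 0L)
    stop("foreground_classes must be non-empty")
  unknown <- setdiff(foreground_classes, classes)
  if (length(unknown) > 0L)
    stop("unknown foreground class(es): ", paste(unknown, collapse = ", "))
  structure(list(geometry = geometry,
                 mask = matrix(landuse %in% foreground_classes,
                               geometry$n_rows, geometry$n_cols)),
            class = "binary_landscape")
}

#' Morphological spatial pattern analysis
#'
#' Segments a binary foreground/background raster into the seven MSPA
#' structural classes. Semantics on the 8-neighbourhood grid:
#'
#' * **core** — foreground whose chessboard distance to the nearest
#'   background cell (cells beyond the raster count as background) exceeds
#'   `edge_width`;
#' * **islet** — foreground components containing no core;
#' * background components not connected to the raster border are *holes*;
#'   non-core foreground within `edge_width` of a core cell is
#'   **perforation** when a hole lies within `edge_width` (ties with the
#'   outer boundary go to perforation), otherwise **edge**;
#' * the remaining non-core foreground (farther than `edge_width` from any
#'   core) forms connector components, classed by the core cells within
#'   chessboard distance `edge_width + 1` (their contact set): contacts on
#'   two or more distinct core components make a **bridge**; two or more
#'   spatially disjoint contact groups on a single core component make a
#'   **loop**; a single contact group makes a **branch**; no contact at
#'   all leaves the connector as edge.
#'
#' The seven foreground classes partition the foreground exactly;
#' background is never labelled.
#'
#' @param binary a `binary_landscape` from [binarize()], or a logical
#'   matrix (then `geometry` must be given).
#' @param edge_width buffer width in cells (>= 1).
#' @param connectivity neighbourhood for components and morphology
#'   (8, the default, or 4).
#' @param geometry required when `binary` is a bare matrix.
#' @return an object of class `mspa_map`: list of `geometry`, integer
#'   `label` matrix coded as [MSPA_CLASSES], `edge_width`, `connectivity`.
#' @export
mspa_classify <- function(binary, edge_width = 1L, connectivity = 8,
                          geometry = NULL) {
  if (inherits(binary, "binary_landscape")) {
    mask <- binary$mask
    geometry <- binary$geometry
  } else {
    mask <- binary == TRUE
    if (is.null(geometry)) stop("geometry must be supplied with a bare mask")
    check_layer(mask, geometry, "mask")
  }
  edge_width <- as.integer(edge_width)
  if (edge_width < 1L) stop("edge_width must be >= 1")
  lab <- matrix(MSPA_CLASSES[["background"]], nrow(mask), ncol(mask))
  if (!any(mask)) return(new_mspa_map(lab, geometry, edge_width, connectivity))

  core <- erode_mask(mask, steps = edge_width, connectivity = connectivity)
  comp <- label_components(mask, connectivity)
  core_comps <- unique(comp[core])
  islet <- mask & !(comp %in% core_comps)
  lab[islet] <- MSPA_CLASSES[["islet"]]
  lab[core] <- MSPA_CLASSES[["core"]]

  # split background into holes and outside (components touching the border)
  bg_comp <- label_components(!mask, connectivity)
  border_ids <- unique(c(bg_comp[1, ], bg_comp[nrow(mask), ],
                         bg_comp[, 1], bg_comp[, ncol(mask)]))
  border_ids <- border_ids[border_ids != 0L]
  hole <- !mask & !(bg_comp %in% border_ids)

  remaining <- mask & !core & !islet
  near_core <- dilate_mask(core, steps = edge_width, connectivity = connectivity)
  near_hole <- dilate_mask(hole, steps = edge_width, connectivity = connectivity)
  boundary_band <- remaining & near_core
  lab[boundary_band & near_hole] <- MSPA_CLASSES[["perforation"]]
  lab[boundary_band & !near_hole] <- MSPA_CLASSES[["edge"]]

  # connectors: non-core foreground beyond the edge band
  connector <- remaining & !near_core
  if (any(connector)) {
    core_lab <- label_components(core, connectivity)
    conn_lab <- label_components(connector, connectivity)
    for (id in seq_len(max(conn_lab))) {
      cmask <- conn_lab == id
      contact <- core &
        dilate_mask(cmask, steps = edge_width + 1L, connectivity = connectivity)
      if (!any(contact)) {
        lab[cmask] <- MSPA_CLASSES[["edge"]]
        next
      }
      n_core_comps <- length(unique(core_lab[contact]))
      if (n_core_comps >= 2L) {
        lab[cmask] <- MSPA_CLASSES[["bridge"]]
      } else {
        n_groups <- max(label_components(contact, connectivity))
        lab[cmask] <- if (n_groups >= 2L) MSPA_CLASSES[["loop"]]
                      else MSPA_CLASSES[["branch"]]
      }
    }
  }
  new_mspa_map(lab, geometry, edge_width, connectivity)
}

new_mspa_map <- function(label, geometry, edge_width, connectivity) {
  structure(list(geometry = geometry, label = label,
                 edge_width = edge_width, connectivity = connectivity),
            class = "mspa_map")
}

#' @export
print.mspa_map <- function(x, ...) {
  cat(sprintf("<mspa_map> %d x %d, edge_width %d, %d-neighbourhood\n",
              x$geometry$n_rows, x$geometry$n_cols, x$edge_width,
              x$connectivity))
  tab <- table(factor(x$label, levels = MSPA_CLASSES,
                      labels = names(MSPA_CLASSES)))
  print(tab)
  invisible(x)
}

#' Tabulate MSPA class areas
#'
#' Per-class area and shares, mirroring the usual MSPA area table: area in
#' km^2 (`cells * cell_size^2 * 1e-6`), share of the foreground and share
#' of the whole landscape, both in percent.
#'
#' @param map an `mspa_map` from [mspa_classify()].
#' @return a data.frame with columns `class`, `cells`, `area_km2`,
#'   `share_of_foreground`, `share_of_total`.
#' @export
mspa_stats <- function(map) {
  stopifnot(inherits(map, "mspa_map"))
  cellarea <- cell_area_km2(map$geometry)
  fg_classes <- setdiff(names(MSPA_CLASSES), "background")
  cells <- vapply(fg_classes,
                  function(cl) sum(map$label == MSPA_CLASSES[[cl]]), 0L)
  n_fg <- sum(cells)
  n_tot <- n_cells(map$geometry)
  data.frame(
    class = fg_classes,
    cells = as.integer(cells),
    area_km2 = cells * cellarea,
    share_of_foreground = if (n_fg > 0) 100 * cells / n_fg else rep(0, length(cells)),
    share_of_total = 100 * cells / n_tot,
    row.names = NULL)
}

#' Write an MSPA map as an 8-bit ASCII grid
#'
#' Uses the [MSPA_CLASSES] code table.
#'
#' @param map an `mspa_map`.
#' @param file output path.
#' @export
write_mspa_map <- function(map, file) {
  stopifnot(inherits(map, "mspa_map"))
  write_ascii_grid(map$label, map$geometry, file)
}
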