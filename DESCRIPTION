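Package: econetr
Title: Ecological Network Construction and Optimization on Raster Landscapes
Version: 0.1.0
Authors@R:
    person("Econetr", "Developers", email = "econetr@example.org", role = c("aut", "cre"))
Description: Builds and optimizes ecological networks from categorical
    land-cover rasters. Implements morphological spatial pattern analysis
    (MSPA) to segment habitat into core, islet, perforation, edge, loop,
    bridge and branch classes; graph-theoretic landscape connectivity
    indices (IIC, PC and their patch-removal importances dIIC/dPC) for
    ecological source selection; PCA-weighted multi-factor resistance
    surfaces; least-cost (minimum cumulative resistance) corridor
    extraction on the eight-connected cell graph; gravity-model corridor
    importance ranking; betweenness-centrality stepping-stone selection;
    and alpha/beta/gamma network structure indices. A seeded synthetic
    landscape generator emulating a grassland-dominated alpine basin makes
    the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
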