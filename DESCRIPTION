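Package: tunneldim
Title: Molecular Tunnel Dimensions in Enzymes Across Growth Temperatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures molecular channels (tunnels) in protein structures from
    centerline sphere profiles using the cylinder/truncated-cone (frustum)
    section model: total channel length, lateral surface and volume are sums
    over consecutive-sphere sections. Includes a grid-clearance channel tracer
    that extracts a widest-bottleneck centerline from a PDB structure, readers
    and writers for a channel-profile interchange dialect compatible with
    tunnel-detection tool exports, and the statistical analysis used to relate
    tunnel dimensions to microbial optimum growth temperature: temperature-class
    binning, within-class amplitude (range) summaries, variance-ratio F tests
    with Bonferroni correction, and linear trend fits. Seeded synthetic
    generators for dimension-versus-temperature tables and channel-bearing toy
    structures make the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
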