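Package: omicanvas
Title: Paint Multi-Omics Data onto Organism-Scale Metabolic Network Diagrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds organism-scale metabolic network diagrams laid out by
    textbook pathway conventions (biosynthesis left, degradation right,
    downward flow, class-specific metabolite node shapes, semantic zoom
    tiers) and paints up to four single-omics datasets onto four
    independent visual channels: reaction-edge color, reaction-edge
    thickness, metabolite-node color, and metabolite-node thickness.
    Values are mapped through binned color scales with draggable
    breakpoints and linear thickness scales, with histogram legends,
    time-course animation frame sets, and per-entity omics popup plots,
    all emitted as SVG. Reads metabolic networks from SBML (core plus
    optional groups and fbc packages) or a flat tab-delimited fixture
    format, and multi-omics experiments from a single-file or master-file
    tab-delimited format. Includes a deterministic fixture generator and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
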