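# omicanvas

Paint up to four single-omics datasets onto an organism-scale metabolic
network diagram, each on its own visual channel — reaction-edge color,
reaction-edge thickness, metabolite-node color, metabolite-node thickness —
with histogram-controlled value binning, semantic zoom tiers, time-course
animation frames and per-entity omics popup plots, all emitted as SVG.

It is aimed at systems biologists who have, say, a transcriptomics time
course plus proteomics plus metabolomics for one organism and want to *see*
where in metabolism the coordinated changes are, rather than scanning gene
lists.

## What it computes

* **Network model** — compounds, reactions and pathways with gene and
  compound lookup indexes, read from SBML (L3/L2 core + `groups` + `fbc`)
  or a flat tab-delimited fixture format (exact round trip).
* **Multi-omics experiments** — 1–4 typed tables (gene/protein/reaction →
  edge channels, compound → node channels; no channel shared), read from a
  single file or a master file + per-dataset tables. Preprocessing:
  log2 fold changes relative to a reference column (n columns → n−1) and
  gene essentiality = 1 − normalized knockout growth yield.
* **Value mapping** — discrete k-bin color scales (default 5 bins,
  green→red diverging) over breakpoints that default to a symmetric range
  `[-M, M]` for signed data; linear thickness scales; half-open bins with
  clamping; interactive-style breakpoint dragging with affine side
  rescaling; histogram summaries whose counts conserve the data.
* **Layout** — biosynthesis left, degradation right, orphan reactions in a
  far-right zone, downward pathway flow, class-specific node shapes
  (triangle = amino acid, square = carbohydrate, diamond = nucleotide,
  shaded = phosphorylated), membrane frame, zoom tiers 0–3 (tier 3 swaps
  node shapes for omics-colored metabolite names). Deterministic.
* **Rendering** — SVG frames with exact painted styles, per-frame animation
  + JSON index (geometry identical across frames), histogram legends, and
  popup charts plotting every contributing row as its own series.
* **Fixtures + CLI** — a seeded generator for toy networks and experiments,
  including `synechocystis-like` (5 time points: 1 h, 3 h, 11.75 h, 13 h,
  15 h) and `abaylyi-like` (three one-column datasets) presets, and an
  `oc_cli()` entry point (`validate`, `paint`, `animate`, `popup`, `synth`,
  `transform`) wrapped by `inst/cli/omicanvas`.

## Worked example

```r
library(omicanvas)

net <- toy_quinate_network()
net
#> <metabolic_network> 11 compounds, 9 reactions (3 orphan), 2 pathways

exp <- generate_experiment("abaylyi-like", net, seed = 1)
exp
#> <multi_omics_experiment> 3 dataset(s), 1 frame(s)
#>   ds1 'gene (edge_color)': gene -> edge_color, 11 rows x 1 column(s), signed
#>   ds2 'gene (edge_thickness)': gene -> edge_thickness, 11 rows x 1 column(s)
#>   ds3 'compound (node_color)': compound -> node_color, 11 rows x 1 column(s), signed

diagram <- layout_network(net)
diagram
#> <diagram> 630x274 units, 52 glyphs, 3 regions

states <- default_channel_states(exp, net)
frames <- build_frames(diagram, exp, states, net)
svg <- render_frame(diagram, frames$frames[[1]], tier = 2)
```

`states$edge_color` is a 5-bin green-to-red scale over a symmetric range
determined by the largest absolute log2 fold change; `svg` is a complete
SVG document in which each reaction edge's `stroke` is the bin color of its
most extreme contributing gene value, each edge's `stroke-width` encodes
the second dataset, and each metabolite node's `fill` the third. Unmeasured
entities stay neutral grey; missing values use the scale's missing color at
minimum width.

The same pipeline from a shell:

```sh
Rscript inst/cli/omicanvas synth --preset synechocystis-like --seed 1 --out fx
Rscript inst/cli/omicanvas transform --omics fx/omics.tsv --fold-change --reference 1 --log2 --out fx/omics_fc.tsv
Rscript inst/cli/omicanvas paint --network fx/network.tsv --omics fx/omics_fc.tsv --tier 2 --out painted
# painted/frame_001.svg ... frame_004.svg, index.json, legend_*.svg, channels.yaml, layout.json
```

## Package layout

```
R/                network-model, omics-format, channel-mapping, layout,
                  render, fixtures, cli
inst/extdata/     shipped toy network (flat format, with count manifest)
inst/cli/         Rscript CLI wrapper
tests/testthat/   unit + property + acceptance suites
vignettes/        methods vignette
scripts/          acceptance.R
```
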