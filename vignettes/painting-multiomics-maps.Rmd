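---
title: "Painting multi-omics data onto organism-scale metabolic maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Painting multi-omics data onto organism-scale metabolic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicanvas)
```

## The problem omicanvas addresses

A multi-omics experiment — say transcript abundances, protein abundances and
metabolite changes measured over a light-to-dark time course in a
cyanobacterium — is hard to interpret gene by gene. A metabolic map view
turns the question around: draw the organism's entire metabolic network once,
then *paint* each omics dataset onto an independent visual property of that
drawing, so coordinated changes across a pathway stand out at a glance.

omicanvas implements that painting layer for R. A multi-omics experiment is a
collection of one to four single-omics datasets, each a table of entity
tokens (gene, protein, reaction or compound identifiers) by numeric columns
(time points or conditions). Each dataset is routed to one of four **visual
channels**:

| channel          | carries                  | typical dataset   |
|------------------|--------------------------|-------------------|
| `edge_color`     | reaction-edge stroke     | transcriptomics   |
| `edge_thickness` | reaction-edge width      | proteomics, gene essentiality, flux |
| `node_color`     | metabolite-node fill     | metabolomics      |
| `node_thickness` | metabolite-node outline  | a second metabolomics technology |

Gene, protein and reaction data paint edges; compound data paint nodes. No
two datasets may share a channel, and an experiment holds at most four
datasets — one per channel.

## The network model and its file formats

The network is a set of compounds, reactions and pathways with two derived
indexes: gene → catalyzed reactions, and case-folded compound id/name/synonym
→ compound id. Networks load from SBML (Level 3 or 2 core, with pathway
membership from the `groups` package and gene links from `fbc` gene-product
associations) or from a small flat tab-delimited format that round-trips
exactly and is convenient for fixtures. Boundary species are kept as
compounds so currency metabolites remain paintable.

Token resolution is deliberately conservative: case-insensitive *exact*
matching, primary identifiers before names and synonyms, and no fuzzy
matching, so every painted element can be traced back to an input row. A
token that matches nothing produces a warning and is counted, never guessed
at. Because a string like `"atp"` could name both a gene and a compound, the
dataset's declared data type always decides which index is consulted.

## Omics file formats

Experiments are read from a single file (header section declaring the
dataset count and per-dataset parameters, then one tab-delimited table
section per dataset) or from a master file plus one table file per dataset;
both parse to identical objects. The header grammar used here
(`!NUM-DATASETS`, `!DATASET`, `!LABELS`, `>DATASET`) is this package's own
line-oriented dialect: it captures exactly the per-dataset parameters the
painting layer needs (identifier, label, data type, target channel, column
selection, signedness) in a diff-friendly form. Empty cells, `NA` and `NaN`
are missing values, never zero. Duplicate tokens within a table are kept —
replicate measurements are real data — and combined only at painting time.

Two preprocessing transforms ship with the package because time-course data
usually arrive as raw abundances:

* `fold_change_transform()` divides every column by a reference column and
  drops it (optionally log2), so a five-time-point series referenced to its
  first time point becomes four fold-change columns. Rows with a missing or
  zero reference become missing, with a warning — they carry no ratio
  information.
* `essentiality_transform()` converts knockout growth yields normalized to
  wild type into an essentiality score, `1 - yield`, so the most essential
  genes get the *thickest* edges when routed to `edge_thickness`.

## Value-to-style mapping

Colors are **binned**, not continuously interpolated, because the histogram
legend is drawn as discrete color regions with a countable number of data
points per region. The default scale has 5 bins over a green-to-red
diverging palette; blue-red diverging and white-red/white-blue sequential
palettes are also shipped, and any scale interpolates to any bin count.

Default breakpoints depend on whether the dataset is *signed* (centered on
zero, like log2 fold changes): signed data get equal bins over `[-M, M]`
with `M` the largest absolute value — so data reaching −7.72 map over a
symmetric −7.72 to 7.72 axis — while unsigned data get equal bins over
`[min(0, min), max]`. Binning uses half-open intervals `[b_i, b_{i+1})`; a
value equal to an interior boundary falls in the upper bin, the global
maximum falls in the last bin, and out-of-range values always clamp into the
extreme bins rather than erroring (dragging a breakpoint can legitimately
push values outside the interior bins).

`drag_breakpoint()` reproduces the histogram control's axis-label drag in
batch form: the chosen interior boundary moves, and the boundaries on each
side are affinely rescaled within `[lo, moved]` and `[moved, hi]`. This
interpretation — all other regions shrink or grow proportionally while the
outer limits, bin count and ordering are preserved — is this package's
design choice; it is the simplest rescaling with those invariants.

Thickness channels use a linear map from the breakpoint range onto
`[min_px, max_px]` (default 1–10 px), clamped, with missing values drawn at
the minimum width so absent data never dominate the picture.

When several rows resolve to one target (two genes catalyzing one reaction,
or replicate rows), per-frame values are combined by an aggregation policy.
The default, `max_magnitude`, keeps the value of largest absolute magnitude
(ties to the first occurrence); it surfaces the strongest signal, which
suits exploratory scanning of a whole-network map. `mean` and `first` are
available where a neutral summary or a bijective mapping is wanted.

## Layout

The layout honors textbook pathway-drawing conventions rather than
reproducing any published layout engine: this package's contribution is the
painting layer, and the diagram only needs to be *conventional* —
biosynthetic pathway glyphs packed on the left, degradative on the right,
energy/other in the center, orphan reactions (reactions in no pathway)
gridded alphabetically in a dedicated far-right zone, and a membrane border
framing everything. Pathways flow downward: reactions are ordered by
substrate-to-product chaining where detectable (Kahn's algorithm preferring
the stored order; cycles are broken at the stored order, so a two-reaction
cycle still terminates), successive reactions sit at strictly increasing y,
and shared intermediates are drawn once. Within each side, pathway glyphs
are shelf-packed into columns, tallest first — deterministic, so two runs on
the same network are byte-identical.

Node shapes communicate compound class: triangles for amino acids, squares
for carbohydrates, diamonds for nucleotides, circles otherwise; shaded nodes
are phosphorylated. Currency metabolites (ATP, ADP, NAD(P)(H), water,
phosphate, … — configurable) are drawn as small side nodes rather than chain
nodes, keeping the main flows legible.

Semantic zoom is expressed as four tiers rather than live magnification:
tier 0 shows regions and membrane, tier 1 adds pathway names, tier 2 adds
node shapes and edge detail, and tier 3 *replaces* node shapes with
metabolite names — colored with the node's omics data — and adds gene
labels. `zoom_tier_for_scale()` maps a magnification factor onto a tier via
thresholds (defaults 0.25, 1.0, 3.0; unstated by any convention, hence
exposed in configuration). Because tier 3 replaces shapes, glyphs carry
both a minimum and a maximum visibility tier; the maximum defaults to
unbounded and is 2 for node shapes, 3+ for name labels.

A reaction belonging to several pathways is drawn once per pathway
occurrence but carries a single painted value; in SVG, later occurrences
get an `__<n>` id suffix (element ids must be unique) while all occurrences
share the same `data-ref` and style.

## Rendering

Frames are SVG 1.1 documents. A `frame_set` holds one style map per
animation frame (the experiment's frame count is the *maximum* selected
column count across datasets; shorter datasets hold their last value, so a
one-time-point metabolomics dataset stays static while the transcriptome
animates). Animation is emitted as one SVG per frame plus a JSON index —
geometry byte-identical across frames, only presentation attributes change —
which makes frame-exact assertions possible; a single self-playing SVG with
declarative `<animate>` elements is available as a convenience wrapper.
Tooltips are `<title>` children; omics popups are per-entity line-and-marker
charts showing every contributing row as its own series, pre-aggregation,
with raw values recoverable from `data-value` attributes.

## The fixture generator

`generate_toy_network()` and `generate_experiment()` produce deterministic,
seeded fixtures: chained pathways alternating between biosynthesis and
degradation categories, 1–3 genes per reaction, optional currency
participants, and omics tables drawn from normal, lognormal or uniform
distributions with configurable missing-cell and unmatched-token fractions.
Two presets emulate the shapes of the case studies that motivated the tool:

* `"synechocystis-like"` — a light-to-dark transition time course:
  transcriptomics and proteomics with five raw columns at 1 h, 3 h, 11.75 h,
  13 h and 15 h (log-normal abundances; after fold-change preprocessing
  relative to 1 h these become four signed columns), plus one-column
  metabolomics scores. Defaults: 2% missing cells and 5% unmatched tokens in
  transcriptomics, 10% missing in proteomics (protein coverage is always
  sparser), metabolomics scores ~ N(0, 2).
* `"abaylyi-like"` — a single-time-point carbon-source comparison: signed
  expression log2 fold changes (N(0, 2.5)) to edge color, knockout growth
  yields (U(0, 1), to be converted with `essentiality_transform()`) to edge
  thickness, and signed metabolite changes to node color.

The generator emulates the *shape* of real experiments — dimensions,
channels, signedness, missingness, unmatched identifiers — not their
biology: values are independent draws, so painted maps show no pathway-level
correlation structure, and identifier mismatches are synthetic tokens rather
than real nomenclature drift. Passing tests therefore demonstrate the
mechanics of parsing, mapping, layout and rendering, not biological
recovery.

## A worked example

```{r example, warning = FALSE}
net <- toy_quinate_network()
net

exp <- generate_experiment("abaylyi-like", net, seed = 1)
exp

diagram <- layout_network(net)
states <- default_channel_states(exp, net)
frames <- build_frames(diagram, exp, states, net)
svg <- render_frame(diagram, frames$frames[[1]], tier = 2)
substr(svg, 1, 120)
```

The histogram legend for the edge-color channel:

```{r histogram, warning = FALSE}
series <- resolve_targets(exp$datasets[[1]], net)
hist <- compute_histogram(series, 1, states$edge_color$breakpoints)
tidy(hist)
```

`autoplot(hist, states$edge_color)` draws the same summary with ggplot2.

## Numerical choices and degenerate inputs

* Default bin count 5; bin membership by `findInterval` with the rightmost
  boundary closed, matching the half-open convention above.
* A signed dataset whose only value is 0 gets the degenerate symmetric range
  `[-1, 1]`; an unsigned constant dataset gets `[lo, lo + 1]` — breakpoints
  must be strictly increasing.
* `drag_breakpoint` pins the outer boundaries exactly (no floating-point
  drift at the ends) and rejects targets outside the open interval.
* Empty pathways lay out as a label with a warning; an empty network still
  renders its membrane.
* Ties in `max_magnitude` aggregation go to the first contributing row, so
  results are independent of hash ordering.
* All generators draw from a locally seeded RNG and restore the caller's
  RNG state.

## Problem sizes used in the shipped checks

The test suite exercises format round-trips on 100 randomized experiments,
histogram equivalence on 1,000 values against a sort-and-count oracle,
10,000 random breakpoint drags, layout on generated networks of up to 500
reactions, and one full-scale paint with two 3,209-row reaction datasets and
two 1,796-row compound datasets across 20 time-point columns — the largest
configuration the package is routinely validated at.

## Known limitations

* The layout is a deliberate simplification: shelf-packed linear pathway
  chains honoring the stated conventions, not a reproduction of the
  published organism-map layout algorithms. Branched pathways render as a
  main chain plus side nodes.
* SBML compound classes default to `other` (core SBML does not carry them),
  so class-specific node shapes require the flat format or post-editing.
* Interactivity (live dragging, mouse-wheel zoom, hover popups) lives in the
  viewer of the emitted SVG; this package emits documents and exposes the
  equivalent operations as functions.
* One file format dialect: the header directives documented here, not the
  directive names of any external tool's user guide.
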