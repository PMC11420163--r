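DEFAULT_TIER_THRESHOLDS <- c(0.25, 1.0, 3.0)

#' Default currency metabolite identifiers
#'
#' Compounds treated as currency (drawn as small side nodes rather than chain
#' nodes, so pathway flows stay legible). Matched case-insensitively against
#' compound ids.
#' @export
oc_currency_metabolites <- c(
  "atp", "adp", "amp", "nad", "nadh", "nadp", "nadph",
  "water", "h2o", "phosphate", "pi", "ppi", "proton", "h+"
)

# layout geometry constants (abstract diagram units; y grows downward)
LY <- list(
  step = 40,          # vertical distance between chained reactions
  pw_width = 100,     # width of one pathway glyph column
  main_x = 50,        # x of the main compound chain within a pathway glyph
  side_dx = 28,       # currency / side node offset from the chain
  node_size = 6,
  side_node_size = 3,
  col_gap = 20,       # gap between packed pathway columns
  region_gap = 40,    # gap between diagram regions
  margin = 30,
  label_h = 24,       # space reserved for the pathway label
  shelf_height = 640  # greedy packing column height limit
)

#' Diagram side for a pathway category
#'
#' Pathways are grouped by the first element of their category path:
#' biosynthetic pathways go to the left portion of the pathway area,
#' degradative (catabolic) pathways to the right, and energy/other pathways
#' to the center. Orphan reactions live in a dedicated far-right zone.
#'
#' @param category_path character vector; first element one of biosynthesis,
#'   degradation, energy, other.
#' @return One of `"left_biosynthesis"`, `"right_catabolism"`,
#'   `"center_other"`.
#' @export
categorize_pathway <- function(category_path) {
  if (length(category_path) == 0) abort("empty category path")
  switch(category_path[[1]],
         biosynthesis = "left_biosynthesis",
         degradation = "right_catabolism",
         "center_other")
}

#' Node shape for a compound
#'
#' Diagram convention: triangles are amino acids, squares are carbohydrates,
#' diamonds are nucleotides, circles everything else; shaded nodes are
#' phosphorylated compounds.
#'
#' @param compound_class one of the compound class enum values.
#' @param phosphorylated logical.
#' @return List with `shape` and `shaded`.
#' @export
compound_glyph_shape <- function(compound_class, phosphorylated = FALSE) {
  shape <- switch(compound_class,
                  amino_acid = "triangle",
                  carbohydrate = "square",
                  nucleotide = "diamond",
                  "circle")
  list(shape = shape, shaded = isTRUE(phosphorylated))
}

#' Semantic zoom tier for a magnification scale
#'
#' Tier 0 shows regions and the membrane only; tier 1 adds pathway names;
#' tier 2 adds metabolite node shapes and reaction edge detail; tier 3
#' replaces node shapes with metabolite names (colored with the node's omics
#' data) and adds gene/enzyme labels. The tier is monotone nondecreasing in
#' the scale.
#'
#' @param scale positive magnification factor.
#' @param thresholds increasing vector of 3 scale thresholds.
#' @return Integer tier in 0..3.
#' @export
zoom_tier_for_scale <- function(scale, thresholds = DEFAULT_TIER_THRESHOLDS) {
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    abort("zoom_tier_for_scale: scale must be positive")
  }
  findInterval(scale, thresholds)
}

empty_glyphs <- function() {
  tibble(kind = character(), ref_id = character(), shape = character(),
         shaded = logical(), x = numeric(), y = numeric(),
         x2 = numeric(), y2 = numeric(), size = numeric(),
         text = character(), min_tier = integer(), max_tier = integer())
}

glyph_row <- function(kind, ref_id = NA_character_, shape = "circle",
                      shaded = FALSE, x = 0, y = 0, x2 = NA_real_,
                      y2 = NA_real_, size = LY$node_size,
                      text = NA_character_, min_tier = 2L, max_tier = 99L) {
  tibble(kind = kind, ref_id = ref_id, shape = shape, shaded = shaded,
         x = x, y = y, x2 = x2, y2 = y2, size = size, text = text,
         min_tier = as.integer(min_tier), max_tier = as.integer(max_tier))
}

# stable chaining order: Kahn's algorithm over the substrate->product
# precedence graph, preferring stored order; cycles are broken by promoting
# the earliest-stored remaining reaction
chain_order <- function(rids, network) {
  n <- length(rids)
  if (n <= 1) return(rids)
  rx <- network$reactions[match(rids, network$reactions$id), ]
  prods <- rx$products; subs <- rx$substrates
  edges <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && length(intersect(prods[[i]], subs[[j]]))) {
        edges[i, j] <- TRUE
      }
    }
  }
  indeg <- colSums(edges)
  placed <- logical(n)
  order <- integer(0)
  while (length(order) < n) {
    avail <- which(!placed & indeg == 0)
    nxt <- if (length(avail)) avail[[1]] else which(!placed)[[1]]  # cycle guard
    placed[[nxt]] <- TRUE
    order <- c(order, nxt)
    indeg <- indeg - edges[nxt, ]
  }
  rids[order]
}

main_compound <- function(ids, currency) {
  noncur <- ids[!tolower(ids) %in% currency]
  if (length(noncur)) noncur[[1]] else if (length(ids)) ids[[1]] else NA_character_
}

#' Lay out one pathway as a vertical glyph chain
#'
#' Reactions are ordered by substrate-to-product chaining where detectable
#' (cycles broken at the stored order) and placed at strictly increasing y,
#' so the pathway flows downward. Each reaction contributes one edge glyph
#' plus node glyphs for its main substrate and product; shared intermediates
#' are drawn once; currency metabolites become small side nodes. Metabolite
#' name labels (zoom tier 3) replace the node shapes (tiers up to 2).
#' Coordinates are local to the pathway glyph (origin top-left).
#'
#' @param pathway one row of a network's `pathways` tibble (as a list), or a
#'   pathway id.
#' @param network the `metabolic_network`.
#' @param currency character vector of currency compound ids (lower case).
#' @return Tibble of glyphs in local coordinates (may be empty, with a
#'   warning, for an empty pathway).
#' @export
layout_pathway <- function(pathway, network,
                           currency = oc_currency_metabolites) {
  if (is.character(pathway)) {
    i <- match(pathway, network$pathways$id)
    if (is.na(i)) abort(sprintf("unknown pathway '%s'", pathway))
    pathway <- as.list(network$pathways[i, ])
    pathway$category <- pathway$category[[1]]
    pathway$reactions <- pathway$reactions[[1]]
  }
  rids <- pathway$reactions
  glyphs <- list(glyph_row("pathway_label", ref_id = pathway$id, shape = "text",
                           x = LY$main_x, y = 12, text = pathway$name,
                           min_tier = 1L))
  if (length(rids) == 0) {
    warn(sprintf("pathway '%s' has no reactions", pathway$id))
    return(bind_rows(glyphs))
  }
  rids <- chain_order(rids, network)
  rx <- network$reactions
  cp <- network$compounds
  placed <- list()   # compound id -> c(x, y)
  used_y <- numeric(0)   # occupied chain positions, to keep nodes distinct
  free_y <- function(y) {
    while (any(abs(used_y - y) < 1)) y <- y + LY$step
    y
  }
  next_y <- LY$label_h + 10

  node_glyphs <- function(cid, x, y, size) {
    row <- cp[match(cid, cp$id), ]
    gs <- compound_glyph_shape(row$compound_class, row$phosphorylated)
    bind_rows(
      glyph_row("compound_node", ref_id = cid, shape = gs$shape,
                shaded = gs$shaded, x = x, y = y, size = size,
                min_tier = 2L, max_tier = 2L),
      glyph_row("compound_label", ref_id = cid, shape = "text",
                x = x + size + 3, y = y, text = row$name, min_tier = 3L)
    )
  }

  for (rid in rids) {
    r <- as.list(rx[match(rid, rx$id), ])
    subs <- r$substrates[[1]]; prods <- r$products[[1]]
    ms <- main_compound(subs, currency)
    mp <- main_compound(prods, currency)

    if (!is.na(ms) && !is.null(placed[[ms]])) {
      ps <- placed[[ms]]
    } else {
      ps <- c(LY$main_x, free_y(next_y))
      if (!is.na(ms)) {
        placed[[ms]] <- ps
        used_y <- c(used_y, ps[2])
        glyphs[[length(glyphs) + 1]] <- node_glyphs(ms, ps[1], ps[2], LY$node_size)
      }
    }
    yp <- max(ps[2], next_y) + LY$step
    if (!is.na(mp) && !is.null(placed[[mp]])) {
      pp <- placed[[mp]]
    } else {
      pp <- c(LY$main_x, free_y(yp))
      if (!is.na(mp)) {
        placed[[mp]] <- pp
        used_y <- c(used_y, pp[2])
        glyphs[[length(glyphs) + 1]] <- node_glyphs(mp, pp[1], pp[2], LY$node_size)
      }
    }

    glyphs[[length(glyphs) + 1]] <- glyph_row(
      "reaction_edge", ref_id = rid, shape = "line",
      x = ps[1], y = ps[2], x2 = pp[1], y2 = pp[2], min_tier = 2L)
    genes <- r$genes[[1]]
    if (length(genes)) {
      glyphs[[length(glyphs) + 1]] <- glyph_row(
        "gene_label", ref_id = rid, shape = "text",
        x = (ps[1] + pp[1]) / 2 + 8, y = (ps[2] + pp[2]) / 2,
        text = paste(genes, collapse = ","), min_tier = 3L)
    }

    # currency + secondary participants as small side nodes
    mid_y <- (ps[2] + pp[2]) / 2
    side_s <- setdiff(subs, ms); side_p <- setdiff(prods, mp)
    if (length(side_s)) {
      for (k in seq_along(side_s)) {
        glyphs[[length(glyphs) + 1]] <- node_glyphs(
          side_s[[k]], LY$main_x - LY$side_dx, mid_y - 6 - 8 * (k - 1),
          LY$side_node_size)
      }
    }
    if (length(side_p)) {
      for (k in seq_along(side_p)) {
        glyphs[[length(glyphs) + 1]] <- node_glyphs(
          side_p[[k]], LY$main_x + LY$side_dx, mid_y + 6 + 8 * (k - 1),
          LY$side_node_size)
      }
    }
    next_y <- max(yp, pp[2])
  }
  bind_rows(glyphs)
}

shift_glyphs <- function(g, dx, dy) {
  g$x <- g$x + dx; g$y <- g$y + dy
  g$x2 <- g$x2 + dx; g$y2 <- g$y2 + dy
  g
}

glyph_height <- function(g) {
  if (nrow(g) == 0) return(LY$label_h)
  max(c(g$y, g$y2), na.rm = TRUE) + LY$step / 2
}

# greedy shelf packing of pathway glyph blocks into columns, tallest first
pack_column_blocks <- function(blocks, heights, shelf_height) {
  ord <- order(-heights, names(blocks))
  col <- 1L; ycur <- 0
  placement <- list()
  for (i in ord) {
    h <- heights[[i]]
    if (ycur > 0 && ycur + h > shelf_height) {
      col <- col + 1L; ycur <- 0
    }
    placement[[names(blocks)[i]]] <- list(col = col, y = ycur)
    ycur <- ycur + h + LY$col_gap
  }
  placement
}

#' Lay out the full network as an organism-scale diagram
#'
#' Pathway glyphs are packed into columns within their side's region
#' (biosynthesis left, energy/other center, degradation right; greedy shelf
#' packing, tallest first, deterministic), orphan reactions are gridded
#' alphabetically in a dedicated far-right zone, and a membrane border frames
#' all content. Every reaction gets at least one edge glyph (one per pathway
#' occurrence; a reaction in several pathways is drawn in each but carries a
#' single painted value).
#'
#' @param network a validated `metabolic_network`.
#' @param currency currency compound ids (lower case), drawn as side nodes.
#' @param tier_thresholds zoom-scale thresholds for tiers 1..3.
#' @return A `diagram`: list with `glyphs` (tibble, global coordinates,
#'   y down), `regions` (tibble of bounding boxes), `extent` (width, height)
#'   and `tier_thresholds`.
#' @export
layout_network <- function(network, currency = oc_currency_metabolites,
                           tier_thresholds = DEFAULT_TIER_THRESHOLDS) {
  pw <- network$pathways
  sides <- c("left_biosynthesis", "center_other", "right_catabolism")
  blocks <- list(); heights <- numeric(0); block_side <- character(0)
  if (nrow(pw)) {
    for (i in seq_len(nrow(pw))) {
      p <- list(id = pw$id[[i]], name = pw$name[[i]],
                category = pw$category[[i]], reactions = pw$reactions[[i]])
      g <- suppressWarnings(layout_pathway(p, network, currency))
      blocks[[p$id]] <- g
      heights[p$id] <- glyph_height(g)
      block_side[p$id] <- categorize_pathway(p$category)
    }
  }

  glyphs <- list()
  regions <- list()
  xcur <- LY$margin
  for (side in sides) {
    ids <- names(blocks)[block_side == side]
    if (!length(ids)) next
    placement <- pack_column_blocks(blocks[ids], heights[ids], LY$shelf_height)
    ncols <- max(vapply(placement, `[[`, integer(1), "col"))
    x0 <- xcur; y0 <- LY$margin
    hmax <- 0
    for (id in ids) {
      pl <- placement[[id]]
      dx <- x0 + (pl$col - 1) * (LY$pw_width + LY$col_gap)
      dy <- y0 + pl$y
      glyphs[[length(glyphs) + 1]] <- shift_glyphs(blocks[[id]], dx, dy)
      hmax <- max(hmax, pl$y + heights[[id]])
    }
    w <- ncols * (LY$pw_width + LY$col_gap)
    regions[[length(regions) + 1]] <- tibble(
      side = side, x0 = x0 - 10, y0 = y0 - 10,
      x1 = x0 + w + 10, y1 = y0 + hmax + 10)
    glyphs[[length(glyphs) + 1]] <- glyph_row(
      "region_label", shape = "text", x = x0, y = LY$margin - 14,
      text = sub("_", " ", side), min_tier = 0L)
    xcur <- x0 + w + LY$region_gap
  }

  orphans <- orphan_reactions(network)
  if (length(orphans)) {
    x0 <- xcur; y0 <- LY$margin
    ncols <- max(1L, ceiling(sqrt(length(orphans))))
    cell_h <- LY$step + 30
    rx <- network$reactions
    for (k in seq_along(orphans)) {
      rid <- orphans[[k]]
      colk <- (k - 1L) %% ncols
      rowk <- (k - 1L) %/% ncols
      p <- list(id = paste0("orphan_", rid), name = "",
                category = "other", reactions = rid)
      g <- layout_pathway(p, network, currency)
      g <- g[g$kind != "pathway_label", ]
      g <- shift_glyphs(g, 0, -LY$label_h)
      glyphs[[length(glyphs) + 1]] <- shift_glyphs(
        g, x0 + colk * (LY$pw_width + LY$col_gap), y0 + rowk * cell_h)
    }
    nrows <- ceiling(length(orphans) / ncols)
    regions[[length(regions) + 1]] <- tibble(
      side = "far_right_orphans", x0 = x0 - 10, y0 = y0 - 10,
      x1 = x0 + ncols * (LY$pw_width + LY$col_gap) + 10,
      y1 = y0 + nrows * cell_h + 10)
    glyphs[[length(glyphs) + 1]] <- glyph_row(
      "region_label", shape = "text", x = x0, y = LY$margin - 14,
      text = "individual reactions", min_tier = 0L)
    xcur <- x0 + ncols * (LY$pw_width + LY$col_gap) + LY$region_gap
  }

  glyphs <- if (length(glyphs)) bind_rows(glyphs) else empty_glyphs()
  regions <- if (length(regions)) bind_rows(regions) else
    tibble(side = character(), x0 = numeric(), y0 = numeric(),
           x1 = numeric(), y1 = numeric())

  wd <- max(xcur, LY$margin * 2 + 100)
  ht <- if (nrow(regions)) max(regions$y1) + LY$margin else LY$margin * 2 + 60
  membrane <- glyph_row(
    "membrane", shape = "polyline",
    x = 8, y = 8, x2 = wd - 8, y2 = ht - 8, min_tier = 0L)
  glyphs <- bind_rows(membrane, glyphs)

  structure(
    list(glyphs = glyphs, regions = regions,
         extent = c(width = wd, height = ht),
         tier_thresholds = tier_thresholds),
    class = "diagram")
}

#' @export
print.diagram <- function(x, ...) {
  cat(sprintf("<diagram> %.0fx%.0f units, %d glyphs, %d regions\n",
              x$extent[["width"]], x$extent[["height"]],
              nrow(x$glyphs), nrow(x$regions)))
  invisible(x)
}

#' @export
tidy.diagram <- function(x, ...) x$glyphs

#' @export
glance.diagram <- function(x, ...) {
  tibble(width = x$extent[["width"]], height = x$extent[["height"]],
         n_glyphs = nrow(x$glyphs),
         n_edges = sum(x$glyphs$kind == "reaction_edge"),
         n_nodes = sum(x$glyphs$kind == "compound_node"),
         n_regions = nrow(x$regions))
}

#' Serialize a diagram to JSON
#'
#' Lets painting be re-run without re-computing the layout.
#' @param diagram a `diagram`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(diagram, path) {
  jsonlite::write_json(
    list(glyphs = diagram$glyphs, regions = diagram$regions,
         extent = as.list(diagram$extent),
         tier_thresholds = diagram$tier_thresholds),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a diagram back from JSON
#' @param path file written by [write_layout_json()].
#' @return A `diagram`.
#' @export
read_layout_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- as_tibble(d$glyphs)
  for (cc in c("x", "y", "x2", "y2", "size")) g[[cc]] <- as.numeric(g[[cc]])
  g$min_tier <- as.integer(g$min_tier); g$max_tier <- as.integer(g$max_tier)
  structure(
    list(glyphs = g, regions = as_tibble(d$regions),
         extent = c(width = d$extent$width, height = d$extent$height),
         tier_thresholds = as.numeric(d$tier_thresholds)),
    class = "diagram")
}
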