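test_that("pathway categories map to diagram sides", {
  expect_equal(categorize_pathway(c("biosynthesis", "cofactor")),
               "left_biosynthesis")
  expect_equal(categorize_pathway(c("degradation", "carbohydrate")),
               "right_catabolism")
  expect_equal(categorize_pathway("other"), "center_other")
  expect_equal(categorize_pathway("energy"), "center_other")
  expect_error(categorize_pathway(character()), "empty")
})

test_that("compound node shapes follow the drawing conventions", {
  expect_equal(compound_glyph_shape("amino_acid")$shape, "triangle")
  sq <- compound_glyph_shape("carbohydrate", phosphorylated = TRUE)
  expect_equal(sq$shape, "square")
  expect_true(sq$shaded)
  expect_equal(compound_glyph_shape("nucleotide")$shape, "diamond")
  other <- compound_glyph_shape("other")
  expect_equal(other$shape, "circle")
  expect_false(other$shaded)
})

test_that("a linear chain lays out downward in topological order", {
  net <- toy_net()
  g <- layout_pathway("pwy-quinate-deg", net)
  nodes <- g[g$kind == "compound_node", ]
  edges <- g[g$kind == "reaction_edge", ]
  expect_equal(nrow(nodes), 5L)   # quinate..beta-ketoadipate, drawn once each
  expect_equal(nrow(edges), 4L)
  expect_true(all(diff(nodes$y) > 0))
  # topological oracle: substrate of each edge sits above its product
  expect_true(all(edges$y < edges$y2))
  # chained order: rxn-quiA before rxn-quiB before rxn-quiC before rxn-pcaGH
  expect_equal(edges$ref_id,
               c("rxn-quiA", "rxn-quiB", "rxn-quiC", "rxn-pcaGH"))
})

test_that("a single-reaction pathway is two nodes plus one edge", {
  net <- metabolic_network(
    compounds = tibble::tibble(
      id = c("a", "b"), name = c("a", "b"), compound_class = "other",
      phosphorylated = FALSE, synonyms = list(character(), character())),
    reactions = tibble::tibble(
      id = "r1", substrates = list("a"), products = list("b"),
      genes = list("g1"), enzymes = list(character()), reversible = FALSE),
    pathways = tibble::tibble(
      id = "p1", name = "p", category = list("other"),
      reactions = list("r1")))
  g <- layout_pathway("p1", net)
  expect_equal(sum(g$kind == "compound_node"), 2L)
  expect_equal(sum(g$kind == "reaction_edge"), 1L)
})

test_that("a 2-reaction cycle terminates and keeps stored order", {
  net <- metabolic_network(
    compounds = tibble::tibble(
      id = c("a", "b"), name = c("a", "b"), compound_class = "other",
      phosphorylated = FALSE, synonyms = list(character(), character())),
    reactions = tibble::tibble(
      id = c("r1", "r2"), substrates = list("a", "b"),
      products = list("b", "a"), genes = list(character(), character()),
      enzymes = list(character(), character()), reversible = FALSE),
    pathways = tibble::tibble(
      id = "p1", name = "p", category = list("other"),
      reactions = list(c("r1", "r2"))))
  g <- layout_pathway("p1", net)
  edges <- g[g$kind == "reaction_edge", ]
  expect_equal(edges$ref_id, c("r1", "r2"))
  expect_equal(sum(g$kind == "compound_node"), 2L)
})

test_that("empty pathway warns and yields no geometry", {
  net <- toy_net()
  expect_warning(
    g <- layout_pathway(list(id = "px", name = "px", category = "other",
                             reactions = character()), net),
    "no reactions")
  expect_equal(sum(g$kind == "reaction_edge"), 0L)
})

test_that("toy network regions are ordered and every glyph is contained", {
  net <- toy_net()
  d <- layout_network(net)
  rg <- d$regions
  bio <- rg[rg$side == "left_biosynthesis", ]
  cat <- rg[rg$side == "right_catabolism", ]
  orp <- rg[rg$side == "far_right_orphans", ]
  expect_equal(nrow(bio), 1L)
  expect_equal(nrow(cat), 1L)
  expect_equal(nrow(orp), 1L)
  # degradation box right of biosynthesis; orphan zone rightmost
  expect_gt(cat$x0, bio$x1)
  expect_gt(orp$x0, cat$x1)
  # 3 orphan edge glyphs in the orphan zone (box containment)
  edges <- d$glyphs[d$glyphs$kind == "reaction_edge", ]
  orphan_edges <- edges[edges$ref_id %in% orphan_reactions(net), ]
  expect_equal(nrow(orphan_edges), 3L)
  expect_true(all(orphan_edges$x >= orp$x0 & orphan_edges$x2 <= orp$x1 &
                    orphan_edges$y >= orp$y0 & orphan_edges$y2 <= orp$y1))
  # pathway edges inside their side's box
  pw_edges <- edges[edges$ref_id %in%
                      net$pathways$reactions[[1]], ]  # degradation pathway
  expect_true(all(pw_edges$x >= cat$x0 & pw_edges$x <= cat$x1))
})

test_that("layout is complete and deterministic on generated networks", {
  for (seed in c(2, 8)) {
    net <- generate_toy_network(
      fixture_spec(n_pathways = 6, reactions_per_pathway = 5,
                   n_orphan_reactions = 7, seed = seed))
    d1 <- layout_network(net)
    d2 <- layout_network(net)
    expect_identical(d1$glyphs, d2$glyphs)
    # completeness: every reaction has >= 1 edge glyph
    edge_ids <- unique(d1$glyphs$ref_id[d1$glyphs$kind == "reaction_edge"])
    expect_setequal(edge_ids, net$reactions$id)
    # every compound participating in a placed reaction has >= 1 node glyph
    node_ids <- unique(d1$glyphs$ref_id[d1$glyphs$kind == "compound_node"])
    participating <- unique(unlist(c(net$reactions$substrates,
                                     net$reactions$products)))
    expect_true(all(participating %in% node_ids))
    # no region boxes overlap
    rg <- d1$regions
    if (nrow(rg) > 1) {
      for (i in seq_len(nrow(rg) - 1)) {
        for (j in seq((i + 1), nrow(rg))) {
          disjoint <- rg$x1[i] <= rg$x0[j] || rg$x1[j] <= rg$x0[i] ||
            rg$y1[i] <= rg$y0[j] || rg$y1[j] <= rg$y0[i]
          expect_true(disjoint)
        }
      }
    }
  }
})

test_that("an empty network still draws the membrane", {
  d <- layout_network(metabolic_network())
  expect_equal(nrow(d$regions), 0L)
  expect_equal(d$glyphs$kind, "membrane")
})

test_that("zoom tier is monotone in scale with documented extremes", {
  expect_equal(zoom_tier_for_scale(0.1), 0L)
  expect_equal(zoom_tier_for_scale(0.5), 1L)
  expect_equal(zoom_tier_for_scale(2), 2L)
  expect_equal(zoom_tier_for_scale(10), 3L)
  expect_error(zoom_tier_for_scale(0), "positive")
  set.seed(31)
  scales <- sort(stats::rlnorm(100, 0, 1.5))
  tiers <- zoom_tier_for_scale(scales)
  expect_true(all(diff(tiers) >= 0))
  expect_true(all(tiers %in% 0:3))
})

test_that("layout serializes to JSON and back", {
  d <- layout_network(toy_net())
  f <- withr::local_tempfile(fileext = ".json")
  write_layout_json(d, f)
  d2 <- read_layout_json(f)
  expect_equal(d$glyphs, d2$glyphs)
  expect_equal(d$regions, d2$regions)
  expect_equal(d$extent, d2$extent)
})
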