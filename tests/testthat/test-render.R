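paint_toy <- function() {
  net <- toy_net()
  exp <- tiny_experiment()
  d <- layout_network(net)
  states <- suppressWarnings(default_channel_states(exp, net))
  fs <- suppressWarnings(build_frames(d, exp, states, net))
  list(net = net, exp = exp, diagram = d, states = states, frames = fs)
}

test_that("frame sets follow the experiment's frame count and hold statics", {
  p <- paint_toy()
  expect_equal(p$frames$n_frames, 2L)
  expect_equal(p$frames$frame_labels, c("1 h", "3 h"))
  # node colors identical across frames (one-column metabolomics held)
  n1 <- p$frames$frames[[1]]
  n2 <- p$frames$frames[[2]]
  nodes1 <- n1[n1$kind == "node", c("target_id", "fill")]
  nodes2 <- n2[n2$kind == "node", c("target_id", "fill")]
  expect_equal(nodes1, nodes2)
  # single dataset, one column -> one frame
  single <- multi_omics_experiment(list(p$exp$datasets[[2]]))
  st <- suppressWarnings(default_channel_states(single, p$net))
  fs1 <- suppressWarnings(build_frames(p$diagram, single, st, p$net))
  expect_equal(fs1$n_frames, 1L)
})

test_that("frame styles equal independent recomputation per target", {
  p <- paint_toy()
  nf <- experiment_n_frames(p$exp)
  for (d in p$exp$datasets) {
    series <- suppressWarnings(resolve_targets(d, p$net, n_frames = nf))
    st <- p$states[[d$spec$target_channel]]
    for (f in seq_len(nf)) {
      frame <- p$frames$frames[[f]]
      for (i in seq_len(nrow(series))) {
        tid <- series$target_id[[i]]
        v <- series$values[[i]][[f]]
        row <- frame[frame$target_id == tid, ]
        if (nrow(row) == 0) next
        if (d$spec$target_channel == "edge_color") {
          expect_identical(row$stroke, value_to_color(v, st))
        } else if (d$spec$target_channel == "node_color") {
          expect_identical(row$fill, value_to_color(v, st))
        } else {
          expect_equal(row$stroke_width, value_to_thickness(v, st))
        }
      }
    }
  }
})

test_that("a dataset whose channel lacks a state is a config error", {
  p <- paint_toy()
  expect_error(
    build_frames(p$diagram, p$exp, p$states["node_color"], p$net),
    "config error")
})

test_that("rendered frames are well-formed SVG with exact painted styles", {
  p <- paint_toy()
  svg <- render_frame(p$diagram, p$frames$frames[[2]], tier = 2)
  doc <- xml2::read_xml(svg)   # parses as XML
  expect_equal(xml2::xml_name(doc), "svg")

  # every reaction id appears exactly once as an element id (toy fixture has
  # no multi-pathway reactions)
  lines <- xml2::xml_find_all(doc, "//*[local-name()='line'][@class='reaction']")
  ids <- xml2::xml_attr(lines, "id")
  expect_setequal(ids, sanitize_id(p$net$reactions$id))
  expect_false(any(duplicated(ids)))

  # painted stroke equals the frame's color string exactly
  frame <- p$frames$frames[[2]]
  styled <- frame[frame$kind == "edge" & !is.na(frame$stroke), ]
  for (i in seq_len(nrow(styled))) {
    el <- lines[xml2::xml_attr(lines, "data-ref") == styled$target_id[[i]]]
    expect_identical(xml2::xml_attr(el, "stroke"), styled$stroke[[i]])
  }
  # tooltips: every reaction element carries a <title> child
  expect_equal(
    length(xml2::xml_find_all(doc, "//*[@class='reaction']/*[local-name()='title']")),
    length(lines))
})

test_that("zoom tiers control which glyphs are emitted", {
  p <- paint_toy()
  svg0 <- render_frame(p$diagram, NULL, tier = 0)
  d0 <- xml2::read_xml(svg0)
  expect_equal(length(xml2::xml_find_all(d0, "//*[@class='reaction']")), 0L)
  expect_equal(length(xml2::xml_find_all(d0, "//*[@id='membrane']")), 1L)

  svg1 <- render_frame(p$diagram, NULL, tier = 1)
  d1 <- xml2::read_xml(svg1)
  expect_gt(length(xml2::xml_find_all(d1, "//*[@class='pathway_label']")), 0L)
  expect_equal(length(xml2::xml_find_all(d1, "//*[@class='compound']")), 0L)

  svg2 <- render_frame(p$diagram, NULL, tier = 2)
  d2 <- xml2::read_xml(svg2)
  expect_gt(length(xml2::xml_find_all(d2, "//*[@class='compound']")), 0L)
  expect_equal(length(xml2::xml_find_all(d2, "//*[@class='compound_label']")), 0L)

  # tier 3 replaces node shapes with metabolite names
  svg3 <- render_frame(p$diagram, p$frames$frames[[1]], tier = 3)
  d3 <- xml2::read_xml(svg3)
  expect_equal(length(xml2::xml_find_all(d3, "//*[@class='compound']")), 0L)
  labels <- xml2::xml_find_all(d3, "//*[@class='compound_label']")
  expect_gt(length(labels), 0L)
  # metabolite names inherit the node's omics color
  frame <- p$frames$frames[[1]]
  painted <- frame[frame$kind == "node" & !is.na(frame$fill), ]
  for (i in seq_len(nrow(painted))) {
    lab <- labels[xml2::xml_attr(labels, "data-ref") == painted$target_id[[i]]]
    expect_true(all(xml2::xml_attr(lab, "fill") == painted$fill[[i]]))
  }
})

test_that("missing values render with the missing color and minimum width", {
  net <- toy_net()
  exp <- multi_omics_experiment(list(
    single_omics_dataset(
      dataset_spec("tx", "t", "gene", "edge_color", signed = TRUE),
      tibble::tibble(entity = c("quiA", "quiB"), v = c(NA, 2))),
    single_omics_dataset(
      dataset_spec("pr", "p", "protein", "edge_thickness"),
      tibble::tibble(entity = c("quiA", "quiB"), v = c(NA, 2)))))
  d <- layout_network(net)
  states <- suppressWarnings(default_channel_states(exp, net))
  fs <- suppressWarnings(build_frames(d, exp, states, net))
  svg <- render_frame(d, fs$frames[[1]], 2)
  doc <- xml2::read_xml(svg)
  el <- xml2::xml_find_first(doc, "//*[@data-ref='rxn-quiA']")
  expect_equal(xml2::xml_attr(el, "stroke"),
               states$edge_color$missing_color)
  expect_equal(as.numeric(xml2::xml_attr(el, "stroke-width")),
               states$edge_thickness$thickness_range[[1]])
})

test_that("empty diagram renders just membrane and parses as XML", {
  d <- layout_network(metabolic_network())
  svg <- render_frame(d, NULL, 2)
  doc <- xml2::read_xml(svg)
  expect_equal(length(xml2::xml_find_all(doc, "//*[@id='membrane']")), 1L)
  expect_equal(length(xml2::xml_find_all(doc, "//*[@class='reaction']")), 0L)
})

test_that("style fidelity holds for many random value/state pairs", {
  set.seed(77)
  net <- generate_toy_network(fixture_spec(4, 6, 4, seed = 77))
  d <- layout_network(net)
  genes <- network_tokens_for_test(net, "gene")
  compounds <- setdiff(network_tokens_for_test(net, "compound"),
                       c("atp", "adp"))
  n <- 250
  exp <- multi_omics_experiment(list(
    single_omics_dataset(
      dataset_spec("tx", "t", "gene", "edge_color", signed = TRUE),
      tibble::tibble(entity = sample(genes, n, replace = TRUE),
                     v = stats::rnorm(n, 0, 3))),
    single_omics_dataset(
      dataset_spec("pr", "p", "protein", "edge_thickness"),
      tibble::tibble(entity = sample(genes, n, replace = TRUE),
                     v = stats::rlnorm(n))),
    single_omics_dataset(
      dataset_spec("met", "m", "compound", "node_color", signed = TRUE),
      tibble::tibble(entity = sample(compounds, n, replace = TRUE),
                     v = stats::rnorm(n, 0, 2))),
    single_omics_dataset(
      dataset_spec("flux", "f", "compound", "node_thickness"),
      tibble::tibble(entity = sample(compounds, n, replace = TRUE),
                     v = stats::runif(n)))))
  states <- suppressWarnings(default_channel_states(exp, net))
  fs <- suppressWarnings(build_frames(d, exp, states, net))
  svg <- render_frame(d, fs$frames[[1]], 2)
  doc <- xml2::read_xml(svg)
  frame <- fs$frames[[1]]
  # extracted attributes equal the mapping module's outputs exactly
  for (i in seq_len(nrow(frame))) {
    ref <- frame$target_id[[i]]
    cls <- if (frame$kind[[i]] == "edge") "reaction" else "compound"
    els <- xml2::xml_find_all(doc, sprintf(
      "//*[@data-ref='%s'][@class='%s']", ref, cls))
    expect_gt(length(els), 0)
    if (!is.na(frame$stroke[[i]])) {
      expect_true(all(xml2::xml_attr(els, "stroke") == frame$stroke[[i]]))
    }
    if (!is.na(frame$fill[[i]])) {
      expect_true(all(xml2::xml_attr(els, "fill") == frame$fill[[i]]))
    }
    if (!is.na(frame$stroke_width[[i]])) {
      expect_true(all(abs(as.numeric(xml2::xml_attr(els, "stroke-width")) -
                            frame$stroke_width[[i]]) < 1e-9))
    }
  }
})

test_that("animation frames share geometry byte-for-byte and index them", {
  net <- toy_net()
  exp <- suppressWarnings(generate_experiment("synechocystis-like", net, 4))
  for (i in seq_along(exp$datasets)) {  # convert raw counts to fold changes
    if (ncol(exp$datasets[[i]]$table) - 1L >= 2) {
      exp$datasets[[i]]$table <-
        suppressWarnings(fold_change_transform(exp$datasets[[i]]$table, 1))
      exp$datasets[[i]]$spec$signed <- TRUE
    }
  }
  expect_equal(experiment_n_frames(exp), 4L)
  d <- layout_network(net)
  states <- suppressWarnings(default_channel_states(exp, net))
  fs <- suppressWarnings(build_frames(d, exp, states, net))
  dir <- withr::local_tempdir()
  render_animation(d, fs, 2, dir)
  files <- list.files(dir, pattern = "^frame_.*svg$")
  expect_length(files, 4L)
  # geometry (non-style attributes) identical across frames
  strip_styles <- function(f) {
    x <- readLines(file.path(dir, f))
    x <- gsub('stroke="[^"]*"', "", x)
    x <- gsub('fill="[^"]*"', "", x)
    gsub('stroke-width="[^"]*"', "", x)
  }
  base <- strip_styles(files[[1]])
  for (f in files[-1]) expect_identical(strip_styles(f), base)
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  expect_equal(idx$n_frames, 4L)
  expect_equal(idx$frames$label, experiment_frame_labels(exp))
  expect_equal(idx$frames$file, files)
})

test_that("popups plot one series per contributing row with exact values", {
  net <- toy_net()
  exp <- tiny_experiment()
  # rxn-pcaGH has two contributing genes in the 2-dataset experiment; only
  # the transcriptomics dataset touches reactions -> 2 series
  d <- popup_data("rxn-pcaGH", exp, net)
  expect_setequal(unique(d$token), c("pcaG", "pcaH"))
  svg <- render_popup("rxn-pcaGH", exp, net)
  doc <- xml2::read_xml(svg)
  pts <- xml2::xml_find_all(doc, "//*[@class='popup-point']")
  vals <- as.numeric(xml2::xml_attr(pts, "data-value"))
  toks <- xml2::xml_attr(pts, "data-token")
  tb <- exp$datasets[[1]]$table
  for (tok in c("pcaG", "pcaH")) {
    expect_equal(sort(vals[toks == tok]),
                 sort(as.numeric(tb[tb$entity == tok, -1])))
  }
  # a compound with a single 1-column dataset renders a single marker
  svg2 <- render_popup("quinate", exp, net)
  doc2 <- xml2::read_xml(svg2)
  pts2 <- xml2::xml_find_all(doc2, "//*[@class='popup-point']")
  expect_equal(length(pts2), 1L)
  expect_equal(as.numeric(xml2::xml_attr(pts2, "data-value")), 5.1)
  # untouched target -> "no data" error
  expect_error(render_popup("rxn-fumC", exp, net), "no data")
})

test_that("reaction popups show transcript and protein series per gene", {
  net <- toy_net()
  tx <- single_omics_dataset(
    dataset_spec("tx", "transcript", "gene", "edge_color", signed = TRUE),
    tibble::tibble(entity = c("pcaG", "pcaH"), a = c(1, 2), b = c(3, 4)))
  pr <- single_omics_dataset(
    dataset_spec("pr", "protein", "protein", "edge_thickness"),
    tibble::tibble(entity = c("pcaG", "pcaH"), a = c(5, 6), b = c(7, 8)))
  exp <- multi_omics_experiment(list(tx, pr))
  d <- popup_data("rxn-pcaGH", exp, net)
  # 2 genes x 2 datasets = 4 plotted series, pre-aggregation
  expect_equal(nrow(dplyr::distinct(d, dataset_id, token)), 4L)
})

test_that("legend shows one region per bin with labels and counts", {
  bp <- breakpoints(c(-2, -1, 0, 1, 2))
  st <- channel_state("edge_color", bp)
  series <- tibble::tibble(target_id = sprintf("t%d", 1:10), kind = "edge",
                           values = as.list(seq(-2, 2, length.out = 10)),
                           source_tokens = as.list(1:10))
  h <- compute_histogram(series, 1, bp)
  svg <- render_legend(h, st)
  doc <- xml2::read_xml(svg)
  bins <- xml2::xml_find_all(doc, "//*[@class='legend-bin']")
  expect_length(bins, 4L)
  expect_equal(xml2::xml_attr(bins, "fill"), st$colors)
  counts <- as.integer(xml2::xml_text(
    xml2::xml_find_all(doc, "//*[@class='legend-count']")))
  expect_equal(counts, h$bin_counts)
  labels <- xml2::xml_text(
    xml2::xml_find_all(doc, "//*[@class='legend-label']"))
  expect_equal(labels[[1]], "[-2.00, -1.00)")   # 2-decimal boundary labels
  # bin-count mismatch is an error
  st5 <- channel_state("edge_color", breakpoints(c(0, 1, 2, 3, 4, 5)))
  expect_error(render_legend(h, st5), "legend error")
})

test_that("the self-playing SVG wrapper embeds per-frame style animations", {
  p <- paint_toy()
  f <- withr::local_tempfile(fileext = ".svg")
  render_animated_svg(p$diagram, p$frames, 2, f)
  doc <- xml2::read_xml(f)
  anims <- xml2::xml_find_all(doc, "//*[local-name()='animate']")
  expect_gt(length(anims), 0)
  vals <- xml2::xml_attr(anims[[1]], "values")
  expect_length(strsplit(vals, ";")[[1]], p$frames$n_frames)
})
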