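test_that("default breakpoints are symmetric for signed, zero-anchored otherwise", {
  bp <- default_breakpoints(c(-7.72, 6.91, 0.3), n_bins = 5, signed = TRUE)
  expect_equal(unclass(bp), seq(-7.72, 7.72, length.out = 6))
  expect_equal(diff(unclass(bp)), rep(7.72 * 2 / 5, 5))

  bp2 <- default_breakpoints(c(0.1, 1, 0.4), n_bins = 5, signed = FALSE)
  expect_equal(unclass(bp2), c(0, 0.2, 0.4, 0.6, 0.8, 1.0))

  bp3 <- default_breakpoints(3.0, n_bins = 2, signed = TRUE)
  expect_equal(unclass(bp3), c(-3, 0, 3))

  expect_error(default_breakpoints(c(NA_real_, NA_real_)), "no non-missing")
})

test_that("histogram counts match a sort-and-count oracle and conserve data", {
  set.seed(101)
  bp <- breakpoints(c(-4, -2, 0, 2, 4))
  v <- c(stats::rnorm(1000, 0, 3), NA, NA)  # includes out-of-range values
  series <- tibble::tibble(
    target_id = sprintf("t%04d", seq_along(v)), kind = "edge",
    values = as.list(v), source_tokens = as.list(seq_along(v)))
  h <- compute_histogram(series, 1L, bp)

  # oracle: explicit per-value loop with the half-open convention
  oracle <- integer(4)
  n_missing <- 0L
  for (x in v) {
    if (is.na(x)) { n_missing <- n_missing + 1L; next }
    b <- unclass(bp)
    bin <- if (x >= b[[5]]) 4L else if (x < b[[1]]) 1L else {
      max(which(x >= b[-5]))
    }
    oracle[[bin]] <- oracle[[bin]] + 1L
  }
  expect_equal(h$bin_counts, oracle)
  expect_equal(sum(h$bin_counts), h$n_total - h$n_missing)
  expect_equal(h$n_missing, n_missing)
})

test_that("boundary values fall in the upper bin, the max in the last", {
  bp <- breakpoints(c(0, 1, 2, 3))
  expect_equal(bin_index(c(0, 1, 2, 3), bp), c(1L, 2L, 3L, 3L))
  expect_equal(bin_index(c(-5, 99), bp), c(1L, 3L))   # clamped
  expect_equal(bin_index(NA_real_, bp), NA_integer_)
})

test_that("value_to_color follows the bin convention with clamping", {
  bp <- breakpoints(c(-2, -1, 0, 1, 2))
  st <- channel_state("edge_color", bp, palette = "green_red")
  expect_length(st$colors, 4)
  expect_equal(value_to_color(-99, st), st$colors[[1]])
  expect_equal(value_to_color(99, st), st$colors[[4]])
  expect_equal(value_to_color(NA, st), st$missing_color)
  set.seed(5)
  v <- stats::runif(200, -3, 3)
  expect_equal(value_to_color(v, st), st$colors[bin_index(v, bp)])
  # color bin index is nondecreasing in v
  idx <- bin_index(sort(v), bp)
  expect_true(all(diff(idx) >= 0))
})

test_that("value_to_thickness is linear, clamped and monotone", {
  bp <- breakpoints(c(0, 0.5, 1))
  st <- channel_state("edge_thickness", bp, thickness_range = c(1, 10))
  expect_equal(value_to_thickness(0, st), 1)
  expect_equal(value_to_thickness(1, st), 10)
  expect_equal(value_to_thickness(0.5, st), 5.5)   # midpoint
  expect_equal(value_to_thickness(NA, st), 1)
  expect_equal(value_to_thickness(c(-5, 5), st), c(1, 10))
  # essentiality 1.0 on [0,1]: most essential gene gets the thickest edge
  expect_equal(value_to_thickness(1.0, st), 10)
  set.seed(6)
  v <- sort(stats::runif(500, -1, 2))
  expect_true(all(diff(value_to_thickness(v, st)) >= 0))
})

test_that("drag_breakpoint rescales affinely and preserves structure", {
  bp <- breakpoints(c(-4, -2, 0, 2, 4))
  out <- drag_breakpoint(bp, 3, 1)
  expect_equal(unclass(out), c(-4, -1.5, 1, 2.5, 4))
  # identity drag
  expect_equal(unclass(drag_breakpoint(bp, 3, 0)), unclass(bp))
  # bounds are rejected
  expect_error(drag_breakpoint(bp, 3, 4), "outside")
  expect_error(drag_breakpoint(bp, 1, 0), "interior")

  # property: 10,000 random drags preserve k, lo, hi and strict order
  set.seed(202)
  for (i in seq_len(10000)) {
    k <- sample(2:7, 1)
    b <- breakpoints(sort(stats::runif(k + 1, -10, 10)) +
                       seq(0, k) * 1e-6)
    j <- if (k == 2) 2L else sample(2:k, 1)
    lo <- b[[1]]; hi <- b[[k + 1]]
    nv <- stats::runif(1, lo + 1e-9 * abs(lo - hi), hi - 1e-9 * abs(lo - hi))
    d <- drag_breakpoint(b, j, nv)
    expect_identical(length(d), length(b))
    expect_identical(d[[1]], lo)
    expect_identical(d[[k + 1]], hi)
    if (!all(diff(unclass(d)) > 0)) fail("ordering violated")
    if (abs(d[[j]] - nv) > 1e-12) fail("dragged boundary not at target")
  }
  succeed()
})

test_that("resolve_targets aggregates duplicate contributors per policy", {
  net <- toy_net()
  # pcaG and pcaH both catalyze rxn-pcaGH
  tb <- tibble::tibble(entity = c("pcaG", "pcaH"), v1 = c(3, -5), v2 = c(2, 1))
  ds <- single_omics_dataset(
    dataset_spec("tx", "t", "gene", "edge_color"), tb)
  s_mag <- resolve_targets(ds, net, aggregation = "max_magnitude")
  expect_equal(s_mag$values[[which(s_mag$target_id == "rxn-pcaGH")]],
               c(-5, 2))
  s_mean <- resolve_targets(ds, net, aggregation = "mean")
  expect_equal(s_mean$values[[which(s_mean$target_id == "rxn-pcaGH")]],
               c(-1, 1.5))
  s_first <- resolve_targets(ds, net, aggregation = "first")
  expect_equal(s_first$values[[which(s_first$target_id == "rxn-pcaGH")]],
               c(3, 2))
  # ties in magnitude go to the first occurrence
  tb2 <- tibble::tibble(entity = c("pcaG", "pcaH"), v1 = c(4, -4))
  ds2 <- single_omics_dataset(dataset_spec("tx", "t", "gene", "edge_color"), tb2)
  s2 <- resolve_targets(ds2, net)
  expect_equal(s2$values[[1]][[1]], 4)
})

test_that("resolve_targets matches compounds and counts unmatched tokens", {
  net <- toy_net()
  tb <- tibble::tibble(entity = c("quinate", "zzz"), v1 = c(1.5, 2))
  ds <- single_omics_dataset(
    dataset_spec("m", "m", "compound", "node_color"), tb)
  expect_warning(s <- resolve_targets(ds, net), "unmatched")
  expect_equal(s$target_id, "quinate")
  expect_equal(s$values[[1]], 1.5)
  expect_equal(attr(s, "n_unmapped_tokens"), 1L)
})

test_that("with aggregation=first and unique tokens, rows map 1:1 to series", {
  net <- generate_toy_network(fixture_spec(4, 5, 6, seed = 9))
  tokens <- network_tokens_for_test(net, "compound")
  tb <- tibble::tibble(entity = tokens, v1 = seq_along(tokens))
  ds <- single_omics_dataset(
    dataset_spec("m", "m", "compound", "node_color"), tb)
  s <- resolve_targets(ds, net, aggregation = "first")
  expect_equal(nrow(s), nrow(tb))
  expect_setequal(unlist(s$source_tokens), tokens)
})

test_that("vectorized token resolution agrees with lookup_entity", {
  net <- toy_net()
  set.seed(12)
  pool <- c(net$compounds$id, unlist(net$compounds$synonyms), "junk", "JUNK2")
  tokens <- sample(pool, 50, replace = TRUE)
  tb <- tibble::tibble(entity = tokens, v1 = stats::rnorm(50))
  ds <- single_omics_dataset(
    dataset_spec("m", "m", "compound", "node_color"), tb)
  s <- suppressWarnings(resolve_targets(ds, net, aggregation = "first"))
  expect_setequal(
    s$target_id,
    unique(unlist(lapply(tokens, function(t) {
      suppressWarnings(lookup_entity(net, t, "compound"))
    }))))
})

test_that("channel config round-trips through YAML", {
  states <- list(
    channel_state("edge_color", breakpoints(c(-2, -1, 0, 1, 2)),
                  palette = "blue_red"),
    channel_state("node_thickness", breakpoints(c(0, 0.5, 1)),
                  thickness_range = c(2, 8)))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_channel_config(states, f)
  back <- read_channel_config(f)
  expect_equal(unclass(back$edge_color$breakpoints), c(-2, -1, 0, 1, 2))
  expect_equal(back$edge_color$colors, states[[1]]$colors)
  expect_equal(back$node_thickness$thickness_range, c(2, 8))
})
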