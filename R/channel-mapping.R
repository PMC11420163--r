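#' Shipped color palettes
#'
#' Anchor colors for the shipped scales; a scale of any bin count is obtained
#' by interpolation. The default is the diverging green-to-red scale; the
#' other palettes are conventional alternatives for signed (diverging) and
#' unsigned (sequential) data.
#'
#' @format Named list of character vectors of hex colors.
#' @export
oc_palettes <- list(
  green_red  = c("#1a9850", "#91cf60", "#d9d9a3", "#fc8d59", "#d73027"),
  blue_red   = c("#2166ac", "#67a9cf", "#d1c9c9", "#ef8a62", "#b2182b"),
  white_red  = c("#fff5f0", "#fcae91", "#fb6a4a", "#de2d26", "#a50f15"),
  white_blue = c("#f7fbff", "#bdd7e7", "#6baed6", "#3182bd", "#08519c")
)

DEFAULT_MISSING_COLOR <- "#c0c0c0"
DEFAULT_N_BINS <- 5L
DEFAULT_THICKNESS_RANGE <- c(1, 10)

palette_colors <- function(palette, k) {
  anchors <- if (is.character(palette) && length(palette) == 1) {
    if (!palette %in% names(oc_palettes)) {
      abort(sprintf("unknown palette '%s'", palette))
    }
    oc_palettes[[palette]]
  } else palette
  if (length(anchors) == k) return(anchors)
  tolower(grDevices::colorRampPalette(anchors)(k))
}

is_color_channel <- function(channel) endsWith(channel, "_color")

#' Breakpoints partitioning a data range into bins
#'
#' @param boundaries strictly increasing numeric vector of length k+1
#'   defining k bins over `[lo, hi]`.
#' @return A `breakpoints` object (numeric vector).
#' @export
breakpoints <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 3) abort("breakpoints need >= 2 bins (3 boundaries)")
  if (any(!is.finite(boundaries))) abort("breakpoints must be finite")
  if (any(diff(boundaries) <= 0)) abort("breakpoints must be strictly increasing")
  structure(boundaries, class = "breakpoints")
}

#' @export
print.breakpoints <- function(x, ...) {
  cat("<breakpoints>", paste(format(unclass(x), trim = TRUE), collapse = " | "), "\n")
  invisible(x)
}

n_bins <- function(bp) length(bp) - 1L

#' Default breakpoints for a value collection
#'
#' Signed data (values centered on zero, e.g. log2 fold changes) get equal
#' bins over the symmetric range `[-M, M]` with `M` the largest absolute
#' value, mirroring the default linear mapping the histogram control shows
#' (e.g. five colors over -7.72 to 7.72 when the extreme value is 7.72).
#' Unsigned data get equal bins over `[min(0, data min), data max]`.
#'
#' @param values numeric values (missing allowed, not all missing).
#' @param n_bins number of bins (default 5).
#' @param signed is the data centered on zero?
#' @return A [breakpoints()] object with `n_bins` equal-width bins.
#' @export
default_breakpoints <- function(values, n_bins = DEFAULT_N_BINS, signed = FALSE) {
  v <- values[is.finite(values)]
  if (length(v) == 0) abort("default_breakpoints: no non-missing values")
  if (n_bins < 2) abort("default_breakpoints: n_bins must be >= 2")
  if (signed) {
    m <- max(abs(v))
    if (m == 0) m <- 1
    lo <- -m; hi <- m
  } else {
    lo <- min(0, min(v)); hi <- max(v)
    if (hi <= lo) hi <- lo + 1
  }
  breakpoints(seq(lo, hi, length.out = n_bins + 1))
}

#' Bin index of values under the histogram convention
#'
#' Bins are half-open `[b_i, b_{i+1})`: a value equal to an interior boundary
#' falls in the upper bin, except the global maximum `hi`, which falls in the
#' last bin. Values outside `[lo, hi]` clamp into the first or last bin.
#' Missing values return `NA`.
#'
#' @param v numeric vector.
#' @param bp a [breakpoints()] object.
#' @return Integer vector of bin indices in `1..k` (NA for missing).
#' @export
bin_index <- function(v, bp) {
  b <- unclass(bp)
  k <- n_bins(bp)
  idx <- findInterval(v, b, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > k] <- k
  idx[!is.finite(v)] <- NA_integer_
  as.integer(idx)
}

#' Visual state of one channel
#'
#' Pairs breakpoints with either a discrete color scale (for the two color
#' channels) or a linear thickness range in pixels (for the two thickness
#' channels). Out-of-range values always clamp to the extreme bin or
#' thickness; after a breakpoint drag narrows the effective range, values
#' outside it accumulate at the extremes rather than erroring.
#'
#' @param channel one of edge_color, edge_thickness, node_color,
#'   node_thickness.
#' @param breakpoints a [breakpoints()] object.
#' @param palette palette name from [oc_palettes] or a vector of hex colors
#'   (color channels only).
#' @param missing_color hex color painted for missing values.
#' @param thickness_range `c(min_px, max_px)` (thickness channels only).
#' @return A `channel_state`.
#' @export
channel_state <- function(channel, breakpoints,
                          palette = "green_red",
                          missing_color = DEFAULT_MISSING_COLOR,
                          thickness_range = DEFAULT_THICKNESS_RANGE) {
  if (!channel %in% ALL_CHANNELS) {
    abort(sprintf("unknown channel '%s'", channel))
  }
  st <- list(channel = channel, breakpoints = breakpoints, clamp = TRUE)
  if (is_color_channel(channel)) {
    cols <- palette_colors(palette, n_bins(breakpoints))
    if (!all(grepl("^#[0-9a-fA-F]{6}$", c(cols, missing_color)))) {
      abort("colors must be #RRGGBB hex strings")
    }
    st$colors <- cols
    st$missing_color <- missing_color
    st$palette <- if (is.character(palette) && length(palette) == 1) palette else "custom"
  } else {
    thickness_range <- as.numeric(thickness_range)
    if (length(thickness_range) != 2 || diff(thickness_range) <= 0 ||
        any(thickness_range <= 0)) {
      abort("thickness_range must be c(min_px, max_px) with 0 < min < max")
    }
    st$thickness_range <- thickness_range
  }
  structure(st, class = "channel_state")
}

#' Map values to bin colors
#'
#' @param v numeric vector (missing allowed).
#' @param state a color-channel [channel_state()].
#' @return Character vector of hex colors; missing values get the state's
#'   missing color, out-of-range values the extreme bin's color.
#' @export
value_to_color <- function(v, state) {
  if (!is_color_channel(state$channel)) {
    abort(sprintf("value_to_color: '%s' is not a color channel", state$channel))
  }
  idx <- bin_index(v, state$breakpoints)
  out <- state$colors[idx]
  out[is.na(idx)] <- state$missing_color
  out
}

#' Map values to stroke widths
#'
#' Linear map from the breakpoint range `[lo, hi]` onto
#' `[min_px, max_px]`, clamped at both ends; missing values get `min_px`.
#' The map is monotone nondecreasing in the value.
#'
#' @param v numeric vector (missing allowed).
#' @param state a thickness-channel [channel_state()].
#' @return Numeric vector of stroke widths in pixels.
#' @export
value_to_thickness <- function(v, state) {
  if (is_color_channel(state$channel)) {
    abort(sprintf("value_to_thickness: '%s' is not a thickness channel",
                  state$channel))
  }
  b <- unclass(state$breakpoints)
  lo <- b[[1]]; hi <- b[[length(b)]]
  r <- state$thickness_range
  t <- (v - lo) / (hi - lo)
  t <- pmin(1, pmax(0, t))
  out <- r[[1]] + t * (r[[2]] - r[[1]])
  out[!is.finite(v)] <- r[[1]]
  out
}

#' Drag one interior breakpoint
#'
#' Moves the chosen interior boundary to a new position and affinely rescales
#' the boundaries on each side within `[lo, moved]` and `[moved, hi]`, so all
#' other bins shrink or grow proportionally while the outer limits, the bin
#' count and the strict ordering are preserved. This is the batch analogue of
#' dragging an axis label on the histogram control to widen one color region
#' at the expense of the others.
#'
#' @param bp a [breakpoints()] object.
#' @param boundary_index index of an interior boundary (2..k).
#' @param new_value new position, strictly inside `(lo, hi)`.
#' @return A new [breakpoints()] object.
#' @export
drag_breakpoint <- function(bp, boundary_index, new_value) {
  b <- unclass(bp)
  kp1 <- length(b)
  if (boundary_index <= 1 || boundary_index >= kp1) {
    abort("drag_breakpoint: only interior boundaries can be dragged")
  }
  lo <- b[[1]]; hi <- b[[kp1]]; old <- b[[boundary_index]]
  if (!is.finite(new_value) || new_value <= lo || new_value >= hi) {
    abort(sprintf("drag_breakpoint: new value %g outside (%g, %g)",
                  new_value, lo, hi))
  }
  left <- b[seq_len(boundary_index - 1)]
  right <- b[seq(boundary_index + 1, kp1)]
  new_left <- lo + (left - lo) / (old - lo) * (new_value - lo)
  new_right <- new_value + (right - old) / (hi - old) * (hi - new_value)
  out <- c(new_left, new_value, new_right)
  out[[1]] <- lo; out[[kp1]] <- hi   # guard against rounding at the ends
  breakpoints(out)
}

# ---- target resolution ------------------------------------------------------

# vectorized counterpart of lookup_entity; returns a list of target id
# vectors, one per token (property-tested against the scalar path)
lookup_tokens <- function(network, tokens, data_type) {
  keys <- tolower(tokens)
  if (data_type %in% c("gene", "protein")) {
    out <- network$gene_index[keys]
    out[vapply(out, is.null, logical(1))] <- list(character())
    unname(out)
  } else if (data_type == "reaction") {
    p <- unname(network$reaction_index$primary[keys])
    out <- as.list(p)
    miss <- is.na(p)
    out[miss] <- lapply(keys[miss], function(k) {
      network$reaction_index$enzymes[[k]] %||% character()
    })
    out
  } else if (data_type == "compound") {
    p <- unname(network$compound_index$primary[keys])
    s <- unname(network$compound_index$secondary[keys])
    p[is.na(p)] <- s[is.na(p)]
    lapply(p, function(x) if (is.na(x)) character() else x)
  } else {
    abort(sprintf("usage error: unknown data_type '%s'", data_type))
  }
}

#' Resolve a dataset's rows onto network entities
#'
#' Each table row's entity token is resolved against the network (gene and
#' protein tokens to the reactions their products catalyze, compound tokens
#' to metabolite nodes). When several rows land on one target — several genes
#' catalyzing one reaction, or replicate rows — their per-frame values are
#' combined by the aggregation policy. The default, `max_magnitude`, keeps
#' the value of largest absolute magnitude (ties go to the first contributing
#' row); `mean` averages non-missing values; `first` keeps the first
#' contributing row's values. Unmatched tokens are counted and warned about,
#' never fatal.
#'
#' @param dataset a [single_omics_dataset()].
#' @param network an indexed `metabolic_network`.
#' @param aggregation `"max_magnitude"` (default), `"mean"` or `"first"`.
#' @param n_frames pad/truncate the per-target series to this frame count,
#'   holding the last column (default: the dataset's own column count).
#' @return Tibble with one row per resolved target: `target_id`, `kind`
#'   (`"edge"` or `"node"`), `values` (list column, one number or `NA` per
#'   frame) and `source_tokens` (list column). Attributes
#'   `n_unmapped_tokens` and `unmatched_tokens` report resolution failures.
#' @export
resolve_targets <- function(dataset, network,
                            aggregation = c("max_magnitude", "mean", "first"),
                            n_frames = NULL) {
  aggregation <- match.arg(aggregation)
  tb <- selected_table(dataset)
  nf_own <- ncol(tb) - 1L
  nf <- as.integer(n_frames %||% nf_own)
  vals <- as.matrix(tb[, -1, drop = FALSE])
  if (nf > nf_own) {
    vals <- cbind(vals, vals[, rep(nf_own, nf - nf_own), drop = FALSE])
  } else if (nf < nf_own) {
    vals <- vals[, seq_len(nf), drop = FALSE]
  }

  hits <- lookup_tokens(network, tb$entity, dataset$spec$data_type)
  n_hit <- lengths(hits)
  unmatched <- unique(tb$entity[n_hit == 0])
  if (length(unmatched)) {
    warn(sprintf("dataset '%s': %d unmatched token(s), e.g. '%s'",
                 dataset$spec$dataset_id, length(unmatched), unmatched[[1]]))
  }

  kind <- if (dataset$spec$data_type == "compound") "node" else "edge"
  pairs_row <- rep(seq_along(hits), n_hit)
  pairs_target <- unlist(hits, use.names = FALSE)
  if (length(pairs_target) == 0) {
    out <- tibble(target_id = character(), kind = character(),
                  values = list(), source_tokens = list())
  } else {
    grp <- split(pairs_row, pairs_target)   # sorted by target id
    agg_fun <- switch(
      aggregation,
      first = function(m) m[1, ],
      mean = function(m) {
        s <- colMeans(m, na.rm = TRUE)
        s[is.nan(s)] <- NA_real_
        s
      },
      max_magnitude = function(m) {
        vapply(seq_len(ncol(m)), function(j) {
          col <- m[, j]
          ok <- which(!is.na(col))
          if (!length(ok)) return(NA_real_)
          col[ok[which.max(abs(col[ok]))]]
        }, numeric(1))
      }
    )
    out <- tibble(
      target_id = names(grp),
      kind = kind,
      values = lapply(grp, function(rows) {
        unname(agg_fun(vals[rows, , drop = FALSE]))
      }),
      source_tokens = lapply(grp, function(rows) unique(tb$entity[rows]))
    )
  }
  attr(out, "n_unmapped_tokens") <- length(unmatched)
  attr(out, "unmatched_tokens") <- unmatched
  attr(out, "dataset_id") <- dataset$spec$dataset_id
  attr(out, "channel") <- dataset$spec$target_channel
  out
}

# ---- histogram --------------------------------------------------------------

#' Histogram of resolved values over the channel's bins
#'
#' Mirrors the histogram legend control: one count per color bin at one
#' animation frame, using the same clamping half-open bin convention as
#' [value_to_color()]. Counts conserve data: they sum to the number of
#' resolved values minus the missing ones.
#'
#' @param series the tibble returned by [resolve_targets()].
#' @param frame 1-based frame index.
#' @param bp a [breakpoints()] object.
#' @return A `histogram_summary`: list with `bin_counts`, `n_total`,
#'   `n_missing`, `n_unmapped_tokens` and the breakpoints used.
#' @export
compute_histogram <- function(series, frame, bp) {
  nf <- if (nrow(series)) length(series$values[[1]]) else 0L
  if (nrow(series) && (frame < 1 || frame > nf)) {
    abort(sprintf("frame %d out of range 1..%d", frame, nf))
  }
  v <- vapply(series$values, function(x) x[[frame]] %||% NA_real_, numeric(1))
  idx <- bin_index(v, bp)
  counts <- tabulate(idx, nbins = n_bins(bp))
  structure(
    list(bin_counts = counts,
         n_total = length(v),
         n_missing = sum(is.na(idx)),
         n_unmapped_tokens = attr(series, "n_unmapped_tokens") %||% 0L,
         breakpoints = bp),
    class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf("<histogram_summary> %d values (%d missing), bins: %s\n",
              x$n_total, x$n_missing, paste(x$bin_counts, collapse = " ")))
  invisible(x)
}

#' @export
tidy.histogram_summary <- function(x, ...) {
  b <- unclass(x$breakpoints)
  k <- length(b) - 1L
  tibble(bin = seq_len(k), lower = b[-length(b)], upper = b[-1],
         count = x$bin_counts)
}

#' @export
glance.histogram_summary <- function(x, ...) {
  tibble(n_total = x$n_total, n_missing = x$n_missing,
         n_unmapped_tokens = x$n_unmapped_tokens,
         n_bins = length(x$bin_counts))
}

#' Plot a histogram summary as the legend control shows it
#'
#' @param object a `histogram_summary`.
#' @param state optional color [channel_state()] supplying the bin colors.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.histogram_summary <- function(object, state = NULL, ...) {
  d <- tidy(object)
  d$mid <- (d$lower + d$upper) / 2
  fill <- if (!is.null(state)) state$colors else rep("grey50", nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = fill, width = (d$upper - d$lower) * 0.95) +
    ggplot2::labs(x = "value", y = "data points") +
    ggplot2::theme_minimal()
}

# ---- channel config ---------------------------------------------------------

#' Write channel states to a YAML config
#'
#' Persists a tuned mapping (breakpoints, palette, missing color, thickness
#' range) so it can be reapplied to later paints.
#'
#' @param states list of [channel_state()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_channel_config <- function(states, path) {
  ser <- lapply(states, function(st) {
    out <- list(channel = st$channel,
                boundaries = as.numeric(unclass(st$breakpoints)))
    if (is_color_channel(st$channel)) {
      out$colors <- st$colors
      out$missing_color <- st$missing_color
      out$palette <- st$palette
    } else {
      out$thickness_range <- st$thickness_range
    }
    out
  })
  yaml::write_yaml(list(channels = ser), path)
  invisible(path)
}

#' Read channel states from a YAML config
#' @param path config written by [write_channel_config()].
#' @return Named list of [channel_state()] objects (names = channels).
#' @export
read_channel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  states <- lapply(cfg$channels, function(ch) {
    bp <- breakpoints(ch$boundaries)
    if (is_color_channel(ch$channel)) {
      channel_state(ch$channel, bp, palette = unlist(ch$colors),
                    missing_color = ch$missing_color %||% DEFAULT_MISSING_COLOR)
    } else {
      channel_state(ch$channel, bp,
                    thickness_range = unlist(ch$thickness_range))
    }
  })
  stats::setNames(states, vapply(states, `[[`, character(1), "channel"))
}

#' Default channel states for an experiment
#'
#' For every dataset, resolves its values against the network and builds a
#' default 5-bin state on that channel: signed datasets get a symmetric
#' green-to-red color scale (or symmetric thickness range), unsigned ones a
#' zero-anchored scale.
#'
#' @param experiment a `multi_omics_experiment`.
#' @param network a `metabolic_network`.
#' @param n_bins bins per scale (default 5).
#' @param thickness_range pixels, `c(min, max)`.
#' @return Named list of [channel_state()] objects keyed by channel.
#' @export
default_channel_states <- function(experiment, network,
                                   n_bins = DEFAULT_N_BINS,
                                   thickness_range = DEFAULT_THICKNESS_RANGE) {
  nf <- experiment_n_frames(experiment)
  states <- lapply(experiment$datasets, function(d) {
    series <- suppressWarnings(resolve_targets(d, network, n_frames = nf))
    v <- unlist(series$values, use.names = FALSE)
    bp <- if (length(v[is.finite(v)])) {
      default_breakpoints(v, n_bins = n_bins, signed = d$spec$signed)
    } else breakpoints(seq(0, 1, length.out = n_bins + 1))
    channel_state(d$spec$target_channel, bp, thickness_range = thickness_range)
  })
  stats::setNames(states,
                  vapply(experiment$datasets,
                         function(d) d$spec$target_channel, character(1)))
}
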