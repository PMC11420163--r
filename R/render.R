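NEUTRAL_EDGE_COLOR <- "#999999"
NEUTRAL_EDGE_WIDTH <- 1
NEUTRAL_NODE_FILL <- "#e8e8e8"
NEUTRAL_NODE_STROKE <- "#555555"
NEUTRAL_NODE_WIDTH <- 1
LABEL_COLOR <- "#333333"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Sanitize a network id for use as an SVG element id
#'
#' Non-alphanumeric characters become `_` so entity ids can address SVG
#' elements; the original id is kept on the element's `data-ref` attribute.
#'
#' @param id character vector of network ids.
#' @return Sanitized ids.
#' @export
sanitize_id <- function(id) gsub("[^A-Za-z0-9_]", "_", id)

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 10)
  out[!is.finite(x)] <- "0"
  out
}

# ---- frame building ---------------------------------------------------------

#' Build per-frame style assignments for an experiment
#'
#' Resolves every dataset onto the diagram's entities and converts each
#' frame's values into style components through the channel states: color
#' channels set `fill` (nodes) or `stroke` (edges), thickness channels set
#' `stroke_width`. Datasets shorter than the experiment's frame count hold
#' their last column, so one-time-point data stay constant through an
#' animation. Entities untouched by any dataset keep the neutral style.
#'
#' @param diagram a `diagram` from [layout_network()].
#' @param experiment a `multi_omics_experiment`.
#' @param channel_states named list of [channel_state()] objects covering
#'   every channel the experiment's datasets target (see
#'   [default_channel_states()]).
#' @param network the `metabolic_network` the diagram was laid out from.
#' @param aggregation multi-row aggregation policy, see [resolve_targets()].
#' @return A `frame_set`: list with `frames` (one style tibble per frame:
#'   `target_id`, `kind`, `fill`, `stroke`, `stroke_width`), `frame_labels`
#'   and `n_frames`.
#' @export
build_frames <- function(diagram, experiment, channel_states, network,
                         aggregation = "max_magnitude") {
  used <- vapply(experiment$datasets, function(d) d$spec$target_channel,
                 character(1))
  missing_state <- setdiff(used, names(channel_states))
  if (length(missing_state)) {
    abort(sprintf("config error: no channel state for '%s'",
                  missing_state[[1]]))
  }
  nf <- experiment_n_frames(experiment)
  labels <- experiment_frame_labels(experiment)
  diagram_ids <- unique(diagram$glyphs$ref_id[!is.na(diagram$glyphs$ref_id)])

  per_dataset <- lapply(experiment$datasets, function(d) {
    series <- resolve_targets(d, network, aggregation = aggregation,
                              n_frames = nf)
    series <- series[series$target_id %in% diagram_ids, ]
    list(series = series, state = channel_states[[d$spec$target_channel]],
         channel = d$spec$target_channel)
  })

  frames <- lapply(seq_len(nf), function(f) {
    pieces <- lapply(per_dataset, function(pd) {
      if (nrow(pd$series) == 0) return(NULL)
      v <- vapply(pd$series$values, `[[`, numeric(1), f)
      out <- tibble(target_id = pd$series$target_id,
                    kind = pd$series$kind,
                    fill = NA_character_, stroke = NA_character_,
                    stroke_width = NA_real_)
      if (pd$channel == "edge_color") {
        out$stroke <- value_to_color(v, pd$state)
      } else if (pd$channel == "node_color") {
        out$fill <- value_to_color(v, pd$state)
      } else {
        out$stroke_width <- value_to_thickness(v, pd$state)
      }
      out
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (!length(pieces)) {
      return(tibble(target_id = character(), kind = character(),
                    fill = character(), stroke = character(),
                    stroke_width = numeric()))
    }
    bind_rows(pieces) |>
      group_by(.data$target_id, .data$kind) |>
      summarise(fill = first_non_na(.data$fill),
                stroke = first_non_na(.data$stroke),
                stroke_width = first_non_na(.data$stroke_width),
                .groups = "drop")
  })

  structure(list(frames = frames, frame_labels = labels, n_frames = nf),
            class = "frame_set")
}

first_non_na <- function(x) {
  i <- which(!is.na(x))
  if (length(i)) x[[i[[1]]]] else x[[1]]
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frame(s): %s\n", x$n_frames,
              paste(x$frame_labels, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.frame_set <- function(x, ...) {
  purrr::imap_dfr(x$frames, function(fr, i) {
    mutate(fr, frame = i, frame_label = x$frame_labels[[i]], .before = 1)
  })
}

# ---- frame rendering --------------------------------------------------------

style_maps <- function(frame) {
  if (is.null(frame) || nrow(frame) == 0) {
    frame <- tibble(target_id = character(), kind = character(),
                    fill = character(), stroke = character(),
                    stroke_width = numeric())
  }
  e <- frame[frame$kind == "edge", ]
  n <- frame[frame$kind == "node", ]
  list(
    edge_stroke = stats::setNames(e$stroke, e$target_id),
    edge_width = stats::setNames(e$stroke_width, e$target_id),
    node_fill = stats::setNames(n$fill, n$target_id),
    node_width = stats::setNames(n$stroke_width, n$target_id)
  )
}

lookup_style <- function(map, ids, default) {
  out <- unname(map[ids])
  out[is.na(out)] <- default
  out
}

shape_element <- function(shape, x, y, size) {
  # returns the geometry part of the element, without id/style attributes
  ifelse(
    shape == "circle",
    sprintf('circle cx="%s" cy="%s" r="%s"', fmt_num(x), fmt_num(y), fmt_num(size)),
    ifelse(
      shape == "square",
      sprintf('rect x="%s" y="%s" width="%s" height="%s"',
              fmt_num(x - size), fmt_num(y - size),
              fmt_num(2 * size), fmt_num(2 * size)),
      ifelse(
        shape == "triangle",
        sprintf('polygon points="%s,%s %s,%s %s,%s"',
                fmt_num(x), fmt_num(y - size),
                fmt_num(x - size), fmt_num(y + size),
                fmt_num(x + size), fmt_num(y + size)),
        sprintf('polygon points="%s,%s %s,%s %s,%s %s,%s"',  # diamond
                fmt_num(x), fmt_num(y - size),
                fmt_num(x + size), fmt_num(y),
                fmt_num(x), fmt_num(y + size),
                fmt_num(x - size), fmt_num(y)))))
}

unique_svg_ids <- function(ids) {
  s <- sanitize_id(ids)
  dup <- stats::ave(seq_along(s), s, FUN = seq_along)
  ifelse(dup > 1, sprintf("%s__%d", s, dup), s)
}

#' Render one diagram frame as an SVG document
#'
#' Emits a well-formed SVG 1.1 document. Glyphs outside the requested zoom
#' tier are omitted (node shapes are replaced by colored metabolite names at
#' tier 3). Painted style strings are applied exactly as given in the frame's
#' style map; entities without a style keep the neutral grey style. Every
#' painted element carries the sanitized network id as its element id (later
#' duplicates get an `__<n>` suffix), the original id on `data-ref`, and a
#' `<title>` child for tooltips.
#'
#' @param diagram a `diagram`.
#' @param frame one style tibble from a [build_frames()] frame set, or `NULL`
#'   for an unpainted diagram.
#' @param tier zoom tier 0..3 (see [zoom_tier_for_scale()]).
#' @return A single SVG string.
#' @export
render_frame <- function(diagram, frame = NULL, tier = 2L) {
  tier <- as.integer(tier)
  if (tier < 0 || tier > 3) abort("tier must be in 0..3")
  sm <- style_maps(frame)
  g <- diagram$glyphs
  # tier 3 replaces node shapes with name labels
  vis <- g$min_tier <= tier & g$max_tier >= tier
  g <- g[vis, ]
  ext <- diagram$extent
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" viewBox="0 0 %s %s">'),
            fmt_num(ext[["width"]]), fmt_num(ext[["height"]]),
            fmt_num(ext[["width"]]), fmt_num(ext[["height"]])),
    sprintf('<rect width="%s" height="%s" fill="#ffffff"/>',
            fmt_num(ext[["width"]]), fmt_num(ext[["height"]]))
  )

  rg <- diagram$regions
  if (nrow(rg)) {
    out <- c(out, sprintf(
      '<rect class="region" data-side="%s" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#bbbbbb" stroke-dasharray="4,3"/>',
      rg$side, fmt_num(rg$x0), fmt_num(rg$y0),
      fmt_num(rg$x1 - rg$x0), fmt_num(rg$y1 - rg$y0)))
  }

  mb <- g[g$kind == "membrane", ]
  if (nrow(mb)) {
    out <- c(out, sprintf(
      '<rect id="membrane" class="membrane" x="%s" y="%s" width="%s" height="%s" rx="18" fill="none" stroke="#444444" stroke-width="3"/>',
      fmt_num(mb$x), fmt_num(mb$y), fmt_num(mb$x2 - mb$x), fmt_num(mb$y2 - mb$y)))
  }

  ed <- g[g$kind == "reaction_edge", ]
  if (nrow(ed)) {
    ids <- unique_svg_ids(ed$ref_id)
    stroke <- lookup_style(sm$edge_stroke, ed$ref_id, NEUTRAL_EDGE_COLOR)
    width <- lookup_style(sm$edge_width, ed$ref_id, NEUTRAL_EDGE_WIDTH)
    out <- c(out, sprintf(
      '<line id="%s" class="reaction" data-ref="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"><title>%s</title></line>',
      ids, xml_escape(ed$ref_id), fmt_num(ed$x), fmt_num(ed$y),
      fmt_num(ed$x2), fmt_num(ed$y2), stroke, fmt_num(width),
      xml_escape(ed$ref_id)))
  }

  nd <- g[g$kind == "compound_node", ]
  if (nrow(nd)) {
    ids <- unique_svg_ids(nd$ref_id)
    fill <- lookup_style(sm$node_fill, nd$ref_id, NEUTRAL_NODE_FILL)
    width <- lookup_style(sm$node_width, nd$ref_id, NEUTRAL_NODE_WIDTH)
    titles <- ifelse(is.na(nd$text), nd$ref_id, nd$text)
    out <- c(out, sprintf(
      '<%s id="%s" class="compound" data-ref="%s" data-shaded="%d" fill="%s" stroke="%s" stroke-width="%s"%s><title>%s</title></%s>',
      shape_element(nd$shape, nd$x, nd$y, nd$size),
      ids, xml_escape(nd$ref_id), as.integer(nd$shaded), fill,
      NEUTRAL_NODE_STROKE, fmt_num(width),
      ifelse(nd$shaded, ' fill-opacity="0.85"', ""),
      xml_escape(titles),
      sub(" .*$", "", shape_element(nd$shape, nd$x, nd$y, nd$size))))
  }

  lab <- g[g$kind %in% c("pathway_label", "region_label", "gene_label",
                         "compound_label"), ]
  if (nrow(lab)) {
    fill <- rep(LABEL_COLOR, nrow(lab))
    is_cl <- lab$kind == "compound_label"
    # metabolite names inherit the node's omics color at tier 3
    fill[is_cl] <- lookup_style(sm$node_fill, lab$ref_id[is_cl], LABEL_COLOR)
    sizes <- c(pathway_label = 9, region_label = 11, gene_label = 7,
               compound_label = 8)[lab$kind]
    idattr <- ifelse(is.na(lab$ref_id), "",
                     sprintf(' data-ref="%s"', xml_escape(lab$ref_id)))
    out <- c(out, sprintf(
      '<text class="%s"%s x="%s" y="%s" font-size="%s" fill="%s">%s</text>',
      lab$kind, idattr, fmt_num(lab$x), fmt_num(lab$y), fmt_num(sizes),
      fill, xml_escape(ifelse(is.na(lab$text), "", lab$text))))
  }

  paste(c(out, "</svg>"), collapse = "\n")
}

#' Render an animation as one SVG file per frame plus a JSON index
#'
#' Geometry is identical across frames (only `fill`, `stroke` and
#' `stroke-width` differ); the index lists the frames in order with their
#' time-point labels.
#'
#' @param diagram a `diagram`.
#' @param frameset a `frame_set` from [build_frames()].
#' @param tier zoom tier 0..3.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the index file path.
#' @export
render_animation <- function(diagram, frameset, tier, out_dir) {
  if (frameset$n_frames < 1) abort("frame set is empty")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) abort(sprintf("I/O error: cannot create directory '%s'", out_dir))
  files <- sprintf("frame_%03d.svg", seq_len(frameset$n_frames))
  for (i in seq_len(frameset$n_frames)) {
    svg <- render_frame(diagram, frameset$frames[[i]], tier)
    writeLines(svg, file.path(out_dir, files[[i]]), useBytes = TRUE)
  }
  idx <- file.path(out_dir, "index.json")
  jsonlite::write_json(
    list(n_frames = frameset$n_frames,
         frames = lapply(seq_len(frameset$n_frames), function(i) {
           list(index = i, label = frameset$frame_labels[[i]],
                file = files[[i]])
         })),
    idx, auto_unbox = TRUE, digits = NA)
  invisible(idx)
}

#' Render a self-playing animated SVG
#'
#' Convenience wrapper over the same frame set: one document whose painted
#' elements carry declarative `<animate>` children stepping through the
#' per-frame styles.
#'
#' @param diagram a `diagram`.
#' @param frameset a `frame_set`.
#' @param tier zoom tier.
#' @param path output file.
#' @param frame_seconds seconds per frame.
#' @return `path`, invisibly.
#' @export
render_animated_svg <- function(diagram, frameset, tier, path,
                                frame_seconds = 1) {
  base <- render_frame(diagram, frameset$frames[[1]], tier)
  all_styles <- tidy(frameset)
  dur <- sprintf('dur="%ss" repeatCount="indefinite"',
                 fmt_num(frame_seconds * frameset$n_frames))
  anim_for <- function(tid, kind) {
    rows <- all_styles[all_styles$target_id == tid & all_styles$kind == kind, ]
    rows <- rows[order(rows$frame), ]
    parts <- character(0)
    add <- function(attr, vals, default) {
      vals[is.na(vals)] <- default
      if (length(unique(vals)) > 1) {
        parts <<- c(parts, sprintf(
          '<animate attributeName="%s" values="%s" calcMode="discrete" %s/>',
          attr, paste(vals, collapse = ";"), dur))
      }
    }
    if (kind == "edge") {
      add("stroke", rows$stroke, NEUTRAL_EDGE_COLOR)
      add("stroke-width", fmt_num2(rows$stroke_width), fmt_num(NEUTRAL_EDGE_WIDTH))
    } else {
      add("fill", rows$fill, NEUTRAL_NODE_FILL)
      add("stroke-width", fmt_num2(rows$stroke_width), fmt_num(NEUTRAL_NODE_WIDTH))
    }
    paste(parts, collapse = "")
  }
  doc <- xml2::read_xml(base)
  styled <- unique(all_styles[, c("target_id", "kind")])
  for (i in seq_len(nrow(styled))) {
    anim <- anim_for(styled$target_id[[i]], styled$kind[[i]])
    if (!nzchar(anim)) next
    nodes <- xml2::xml_find_all(doc, sprintf(
      "//*[@data-ref='%s']", styled$target_id[[i]]))
    cls <- if (styled$kind[[i]] == "edge") "reaction" else "compound"
    for (nd in nodes) {
      if (!identical(xml2::xml_attr(nd, "class"), cls)) next
      for (an in xml2::xml_children(xml2::read_xml(
        paste0("<g>", anim, "</g>")))) {
        xml2::xml_add_child(nd, an)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

fmt_num2 <- function(x) {
  out <- fmt_num(x)
  out[is.na(x)] <- NA_character_
  out
}

# ---- legend -----------------------------------------------------------------

#' Render the histogram legend as SVG
#'
#' One colored region per bin, in boundary order, each labeled with its
#' boundary interval (2 decimals) and the number of data points it holds —
#' the static counterpart of the interactive histogram control.
#'
#' @param histogram a `histogram_summary` from [compute_histogram()].
#' @param state the matching [channel_state()] (bin counts must agree).
#' @return SVG string.
#' @export
render_legend <- function(histogram, state) {
  b <- unclass(histogram$breakpoints)
  k <- length(b) - 1L
  if (k != n_bins(state$breakpoints)) {
    abort(sprintf("legend error: histogram has %d bins, state has %d",
                  k, n_bins(state$breakpoints)))
  }
  colors <- if (is_color_channel(state$channel)) state$colors else
    rep("#888888", k)
  row_h <- 24; w <- 260
  y <- (seq_len(k) - 1) * row_h + 10
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%d" height="%d">'), w, k * row_h + 20),
    sprintf('<text x="10" y="%s" font-size="10" fill="#333333">%s</text>',
            fmt_num(6), xml_escape(sprintf("Histogram Target: %s",
                                           gsub("_", " ", state$channel)))),
    sprintf(
      '<rect class="legend-bin" x="10" y="%s" width="40" height="%d" fill="%s" stroke="#333333"/>',
      fmt_num(y), row_h - 4, colors),
    sprintf(
      '<text class="legend-label" x="58" y="%s" font-size="9" fill="#333333">[%.2f, %.2f)</text>',
      fmt_num(y + 13), b[-length(b)], b[-1]),
    sprintf(
      '<text class="legend-count" x="200" y="%s" font-size="9" fill="#333333">%d</text>',
      fmt_num(y + 13), histogram$bin_counts),
    "</svg>"
  )
  paste(out, collapse = "\n")
}

# ---- omics popup ------------------------------------------------------------

popup_series <- function(target_id, experiment, network) {
  pieces <- list()
  for (d in experiment$datasets) {
    tb <- selected_table(d)
    hits <- lookup_tokens(network, tb$entity, d$spec$data_type)
    touch <- vapply(hits, function(h) target_id %in% h, logical(1))
    if (!any(touch)) next
    sel <- tb[touch, ]
    for (i in seq_len(nrow(sel))) {
      pieces[[length(pieces) + 1]] <- tibble(
        dataset_id = d$spec$dataset_id,
        dataset_label = d$spec$label,
        token = sel$entity[[i]],
        column = names(sel)[-1],
        t = seq_len(ncol(sel) - 1L),
        value = as.numeric(sel[i, -1])
      )
    }
  }
  if (!length(pieces)) return(NULL)
  bind_rows(pieces)
}

#' Per-entity omics popup data
#'
#' Every dataset row that resolves to the target contributes one series,
#' pre-aggregation, so a reaction catalyzed by two genes shows both genes'
#' transcript and protein series separately.
#'
#' @param target_id reaction or compound id.
#' @param experiment a `multi_omics_experiment`.
#' @param network a `metabolic_network`.
#' @return Long tibble with `dataset_id`, `token`, `column`, `t`, `value`.
#' @export
popup_data <- function(target_id, experiment, network) {
  out <- popup_series(target_id, experiment, network)
  if (is.null(out)) {
    abort(sprintf("no data: '%s' is untouched by every dataset", target_id))
  }
  out
}

#' Render the omics popup plot for one entity as SVG
#'
#' A line-with-markers chart, one series per contributing dataset row, axes
#' labeled with the column labels. Each marker carries its raw value on a
#' `data-value` attribute, so plotted values can be recovered exactly from
#' the document.
#'
#' @inheritParams popup_data
#' @return SVG string.
#' @export
render_popup <- function(target_id, experiment, network) {
  d <- popup_data(target_id, experiment, network)
  w <- 480; h <- 320
  ml <- 60; mr <- 20; mt <- 40; mb <- 50
  pw <- w - ml - mr; ph <- h - mt - mb

  tmax <- max(d$t)
  vr <- range(d$value, na.rm = TRUE)
  if (!all(is.finite(vr))) vr <- c(0, 1)
  if (vr[1] == vr[2]) vr <- vr + c(-1, 1)
  sx <- function(t) ml + (t - 1) / max(1, tmax - 1) * pw
  sy <- function(v) mt + (vr[2] - v) / (vr[2] - vr[1]) * ph

  series <- split(d, list(d$dataset_id, d$token), drop = TRUE)
  pal <- rep(c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
               "#66a61e", "#e6ab02", "#a6761d", "#666666"),
             length.out = length(series))

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%d" height="%d">'), w, h),
    sprintf('<text class="popup-title" x="%d" y="20" font-size="12" fill="#333333">%s</text>',
            ml, xml_escape(sprintf("Omics data: %s", target_id))),
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333333"/>',
            fmt_num(ml), fmt_num(mt + ph), fmt_num(ml + pw), fmt_num(mt + ph)),
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333333"/>',
            fmt_num(ml), fmt_num(mt), fmt_num(ml), fmt_num(mt + ph))
  )
  # x axis: column labels of the longest contributing series
  longest <- series[[which.max(vapply(series, nrow, integer(1)))]]
  out <- c(out, sprintf(
    '<text class="axis-label" x="%s" y="%s" font-size="8" fill="#333333" text-anchor="middle">%s</text>',
    fmt_num(sx(longest$t)), fmt_num(mt + ph + 14), xml_escape(longest$column)))
  yt <- pretty(vr, 4)
  yt <- yt[yt >= vr[1] & yt <= vr[2]]
  out <- c(out, sprintf(
    '<text class="axis-tick" x="%s" y="%s" font-size="8" fill="#333333" text-anchor="end">%s</text>',
    fmt_num(ml - 4), fmt_num(sy(yt) + 3), fmt_num(yt)))

  for (si in seq_along(series)) {
    s <- series[[si]]
    s <- s[order(s$t), ]
    ok <- !is.na(s$value)
    col <- pal[[si]]
    sid <- sprintf("%s:%s", s$dataset_id[[1]], s$token[[1]])
    if (sum(ok) > 1) {
      out <- c(out, sprintf(
        '<polyline class="popup-line" data-series="%s" points="%s" fill="none" stroke="%s" stroke-width="1.5"/>',
        xml_escape(sid),
        paste(sprintf("%s,%s", fmt_num(sx(s$t[ok])), fmt_num(sy(s$value[ok]))),
              collapse = " "), col))
    }
    if (any(ok)) {
      out <- c(out, sprintf(
        '<circle class="popup-point" data-series="%s" data-dataset="%s" data-token="%s" data-value="%s" cx="%s" cy="%s" r="3" fill="%s"/>',
        xml_escape(sid), xml_escape(s$dataset_id[ok]),
        xml_escape(s$token[ok]),
        formatC(s$value[ok], format = "g", digits = 15),
        fmt_num(sx(s$t[ok])), fmt_num(sy(s$value[ok])), col))
    }
    out <- c(out, sprintf(
      '<text class="popup-series-label" x="%s" y="%s" font-size="8" fill="%s">%s</text>',
      fmt_num(ml + pw - 110), fmt_num(mt + 12 * si - 4), col,
      xml_escape(sprintf("%s (%s)", s$token[[1]], s$dataset_label[[1]]))))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}
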