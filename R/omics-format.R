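EDGE_CHANNELS <- c("edge_color", "edge_thickness")
NODE_CHANNELS <- c("node_color", "node_thickness")
ALL_CHANNELS <- c(EDGE_CHANNELS, NODE_CHANNELS)
DATA_TYPES <- c("gene", "protein", "reaction", "compound")
MISSING_TOKENS <- c("", "na", "nan")

#' Describe one single-omics dataset
#'
#' The spec carries everything the painter needs to know about a dataset
#' besides its numbers: what kind of entities its rows name, which visual
#' channel it drives, which value columns to use, and whether the values are
#' signed (centered on zero, e.g. log2 fold changes) — signed data get a
#' symmetric default color scale.
#'
#' Gene, protein and reaction data paint reaction edges, so they must target
#' an edge channel; compound data paint metabolite nodes.
#'
#' @param dataset_id unique identifier within the experiment.
#' @param label display label.
#' @param data_type one of gene, protein, reaction, compound.
#' @param target_channel one of edge_color, edge_thickness, node_color,
#'   node_thickness.
#' @param columns 1-based indices of the value columns to use; `integer(0)`
#'   means all columns.
#' @param signed are values centered on 0?
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(dataset_id, label, data_type, target_channel,
                         columns = integer(), signed = FALSE) {
  if (!data_type %in% DATA_TYPES) {
    abort(sprintf("validation error: unknown data_type '%s'", data_type))
  }
  if (!target_channel %in% ALL_CHANNELS) {
    abort(sprintf("validation error: unknown target_channel '%s'", target_channel))
  }
  if (data_type %in% c("gene", "protein", "reaction") &&
      !target_channel %in% EDGE_CHANNELS) {
    abort(sprintf(
      "validation error: %s data must target an edge channel, not '%s'",
      data_type, target_channel))
  }
  if (data_type == "compound" && !target_channel %in% NODE_CHANNELS) {
    abort(sprintf(
      "validation error: compound data must target a node channel, not '%s'",
      target_channel))
  }
  columns <- as.integer(columns)
  if (any(columns < 1)) abort("validation error: column indices must be >= 1")
  structure(list(dataset_id = dataset_id, label = label,
                 data_type = data_type, target_channel = target_channel,
                 columns = columns, signed = isTRUE(signed)),
            class = "dataset_spec")
}

#' Bundle a dataset spec with its value table
#'
#' @param spec a [dataset_spec()].
#' @param table tibble whose first column `entity` holds row tokens and whose
#'   remaining columns are numeric values (one column per time point or
#'   condition; `NA` marks a missing measurement).
#' @return A `single_omics_dataset`.
#' @export
single_omics_dataset <- function(spec, table) {
  table <- as_tibble(table)
  if (names(table)[[1]] != "entity") names(table)[[1]] <- "entity"
  if (ncol(table) < 2) abort("validation error: omics table needs >= 1 value column")
  if (any(!nzchar(table$entity))) abort("validation error: empty entity token")
  n_val <- ncol(table) - 1L
  if (length(spec$columns) && max(spec$columns) > n_val) {
    abort(sprintf(
      "validation error: dataset '%s' selects column %d but table has %d",
      spec$dataset_id, max(spec$columns), n_val))
  }
  structure(list(spec = spec, table = table), class = "single_omics_dataset")
}

#' Value table restricted to the spec's selected columns
#' @param dataset a `single_omics_dataset`.
#' @return Tibble with `entity` plus the selected value columns.
#' @export
selected_table <- function(dataset) {
  tb <- dataset$table
  cols <- dataset$spec$columns
  if (length(cols) == 0) tb else tb[, c(1L, cols + 1L)]
}

#' Number of frames (selected value columns) a dataset contributes
#' @param dataset a `single_omics_dataset`.
#' @return Integer count.
#' @export
dataset_n_frames <- function(dataset) {
  ncol(selected_table(dataset)) - 1L
}

#' Assemble a multi-omics experiment
#'
#' An experiment holds one to four single-omics datasets, no two of which may
#' share a visual channel. The experiment's frame count is the maximum number
#' of selected columns across datasets; datasets with fewer columns hold
#' their last value through the remaining animation frames, so a one-column
#' metabolomics dataset stays static while a time course plays.
#'
#' @param datasets list of [single_omics_dataset()] objects.
#' @return A `multi_omics_experiment`.
#' @export
multi_omics_experiment <- function(datasets) {
  exp <- structure(list(datasets = datasets), class = "multi_omics_experiment")
  validate_experiment(exp)
  exp
}

#' Validate a multi-omics experiment
#' @param experiment a `multi_omics_experiment`.
#' @return The experiment, invisibly; aborts on violation.
#' @export
validate_experiment <- function(experiment) {
  ds <- experiment$datasets
  if (length(ds) < 1) abort("validation error: an experiment needs >= 1 dataset")
  if (length(ds) > 4) {
    abort(sprintf(
      "validation error: at most 4 single-omics datasets allowed, got %d",
      length(ds)))
  }
  ids <- vapply(ds, function(d) d$spec$dataset_id, character(1))
  if (anyDuplicated(ids)) {
    abort(sprintf("validation error: duplicate dataset id '%s'",
                  ids[duplicated(ids)][[1]]))
  }
  ch <- vapply(ds, function(d) d$spec$target_channel, character(1))
  if (anyDuplicated(ch)) {
    abort(sprintf("validation error: channel '%s' targeted by two datasets",
                  ch[duplicated(ch)][[1]]))
  }
  invisible(experiment)
}

#' Frames in an experiment's animation
#' @param experiment a `multi_omics_experiment`.
#' @return Integer: max selected column count across datasets.
#' @export
experiment_n_frames <- function(experiment) {
  max(vapply(experiment$datasets, dataset_n_frames, integer(1)))
}

#' Frame labels: the column labels of the longest dataset
#' @param experiment a `multi_omics_experiment`.
#' @return Character vector of length [experiment_n_frames()].
#' @export
experiment_frame_labels <- function(experiment) {
  nf <- vapply(experiment$datasets, dataset_n_frames, integer(1))
  tb <- selected_table(experiment$datasets[[which.max(nf)]])
  names(tb)[-1]
}

#' @export
print.multi_omics_experiment <- function(x, ...) {
  cat(sprintf("<multi_omics_experiment> %d dataset(s), %d frame(s)\n",
              length(x$datasets), experiment_n_frames(x)))
  for (d in x$datasets) {
    cat(sprintf("  %s '%s': %s -> %s, %d rows x %d column(s)%s\n",
                d$spec$dataset_id, d$spec$label, d$spec$data_type,
                d$spec$target_channel, nrow(d$table), ncol(d$table) - 1L,
                if (d$spec$signed) ", signed" else ""))
  }
  invisible(x)
}

#' @export
tidy.multi_omics_experiment <- function(x, ...) {
  purrr::map_dfr(x$datasets, function(d) {
    selected_table(d) |>
      tidyr::pivot_longer(-"entity", names_to = "column", values_to = "value") |>
      mutate(dataset_id = d$spec$dataset_id,
             data_type = d$spec$data_type,
             target_channel = d$spec$target_channel,
             .before = 1)
  })
}

#' @export
glance.multi_omics_experiment <- function(x, ...) {
  tibble(
    n_datasets = length(x$datasets),
    n_frames = experiment_n_frames(x),
    n_rows = sum(vapply(x$datasets, function(d) nrow(d$table), integer(1))),
    channels = paste(vapply(x$datasets, function(d) d$spec$target_channel,
                            character(1)), collapse = ",")
  )
}

# ---- single-file format -----------------------------------------------------

rows_to_matrix <- function(rows, ncol_vals) {
  matrix(unlist(rows, use.names = FALSE), ncol = ncol_vals, byrow = TRUE)
}

parse_numeric_cells <- function(cells, lineno) {
  low <- tolower(trimws(cells))
  out <- suppressWarnings(as.numeric(cells))
  out[low %in% MISSING_TOKENS] <- NA_real_   # "nan" reads as missing, not NaN
  bad <- is.na(out) & !(low %in% MISSING_TOKENS)
  if (any(bad)) {
    abort(sprintf("validation error at line %d: non-numeric cell '%s'",
                  lineno, cells[bad][[1]]))
  }
  out
}

parse_spec_line <- function(f, lineno) {
  if (length(f) < 6) {
    abort(sprintf("validation error at line %d: !DATASET needs 6 fields", lineno))
  }
  cols <- if (toupper(trimws(f[[5]])) %in% c("ALL", "")) integer() else {
    v <- suppressWarnings(as.integer(strsplit(f[[5]], ",", fixed = TRUE)[[1]]))
    if (any(is.na(v))) {
      abort(sprintf("validation error at line %d: bad column list '%s'",
                    lineno, f[[5]]))
    }
    v
  }
  dataset_spec(dataset_id = f[[1]], label = f[[2]], data_type = f[[3]],
               target_channel = f[[4]], columns = cols, signed = f[[6]] == "1")
}

#' Parse the single-file multi-omics format
#'
#' The file is a UTF-8, tab-delimited text file with `#` comments allowed
#' anywhere. A header section declares the dataset count and per-dataset
#' parameters, then one table section per dataset follows:
#'
#' ```
#' !NUM-DATASETS 2
#' !DATASET tx <TAB> transcriptomics <TAB> gene <TAB> edge_color <TAB> ALL <TAB> 1
#' !LABELS  tx <TAB> 1 h <TAB> 3 h
#' !DATASET met <TAB> metabolomics <TAB> compound <TAB> node_color <TAB> 1 <TAB> 1
#' >DATASET tx
#' g001 <TAB> 0.4 <TAB> -1.2
#' >DATASET met
#' quinate <TAB> 5.1
#' ```
#'
#' Empty cells, `NA` and `NaN` (case-insensitive) are read as missing values,
#' never as zero. The optional `!LABELS` directive names the value columns.
#'
#' @param path file to parse.
#' @return A validated `multi_omics_experiment`.
#' @export
parse_single_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  n_declared <- NA_integer_
  specs <- list(); labels <- list()
  sections <- list(); current <- NULL

  flush_section <- function() {
    if (is.null(current)) return(invisible())
    if (current$id %in% names(sections)) {
      abort(sprintf("validation error at line %d: duplicate section '%s'",
                    current$start, current$id))
    }
    sections[[current$id]] <<- current
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    t <- trimws(line)
    if (!nzchar(t) || startsWith(t, "#")) next
    if (startsWith(line, "!NUM-DATASETS")) {
      n_declared <- suppressWarnings(
        as.integer(trimws(sub("^!NUM-DATASETS", "", line))))
      if (is.na(n_declared)) {
        abort(sprintf("validation error at line %d: bad !NUM-DATASETS", i))
      }
    } else if (startsWith(line, "!DATASET")) {
      f <- strsplit(sub("^!DATASET\t?", "", line), "\t", fixed = TRUE)[[1]]
      sp <- parse_spec_line(f, i)
      if (sp$dataset_id %in% names(specs)) {
        abort(sprintf("validation error at line %d: duplicate dataset id '%s'",
                      i, sp$dataset_id))
      }
      specs[[sp$dataset_id]] <- sp
    } else if (startsWith(line, "!LABELS")) {
      f <- strsplit(sub("^!LABELS\t?", "", line), "\t", fixed = TRUE)[[1]]
      labels[[f[[1]]]] <- f[-1]
    } else if (startsWith(line, ">DATASET")) {
      flush_section()
      id <- trimws(sub("^>DATASET", "", line))
      if (!nzchar(id)) abort(sprintf("validation error at line %d: >DATASET needs an id", i))
      current <- list(id = id, rows = list(), start = i)
    } else if (!is.null(current)) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      current$rows[[length(current$rows) + 1L]] <-
        list(entity = f[[1]], values = parse_numeric_cells(f[-1], i))
    } else {
      abort(sprintf("validation error at line %d: data row before any >DATASET", i))
    }
  }
  flush_section()

  if (is.na(n_declared)) abort("validation error: missing !NUM-DATASETS header")
  if (length(sections) != n_declared) {
    abort(sprintf(
      "validation error: header declares %d dataset(s) but file contains %d section(s)",
      n_declared, length(sections)))
  }
  if (n_declared > 4) {
    abort(sprintf(
      "validation error: at most 4 single-omics datasets allowed, got %d",
      n_declared))
  }
  missing_spec <- setdiff(names(sections), names(specs))
  if (length(missing_spec)) {
    abort(sprintf("validation error: section '%s' has no !DATASET header line",
                  missing_spec[[1]]))
  }

  datasets <- lapply(names(sections), function(id) {
    sec <- sections[[id]]
    if (!length(sec$rows)) {
      abort(sprintf("validation error: dataset '%s' has no data rows", id))
    }
    # trailing empty fields (missing last columns) are invisible to strsplit;
    # the label directive, when present, fixes the true column count
    ncol_vals <- max(lengths(lapply(sec$rows, `[[`, "values")),
                     length(labels[[id]] %||% integer()))
    if (ncol_vals < 1) {
      abort(sprintf("validation error: dataset '%s' has no value columns", id))
    }
    vals <- rows_to_matrix(lapply(sec$rows, function(r) {
      v <- r$values
      length(v) <- ncol_vals   # right-pad short rows with missing
      v
    }), ncol_vals)
    labs <- labels[[id]] %||% paste0("C", seq_len(ncol_vals))
    if (length(labs) != ncol_vals) labs <- paste0("C", seq_len(ncol_vals))
    tb <- as_tibble(as.data.frame(vals), .name_repair = "minimal")
    names(tb) <- labs
    tb <- bind_cols(
      tibble(entity = vapply(sec$rows, `[[`, character(1), "entity")), tb)
    single_omics_dataset(specs[[id]], tb)
  })
  multi_omics_experiment(datasets)
}

#' Write an experiment in the single-file multi-omics format
#'
#' Inverse of [parse_single_file()]: parsing the written file yields a
#' structurally equal experiment. Missing cells are written as empty fields.
#'
#' @param experiment a `multi_omics_experiment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_single_file <- function(experiment, path) {
  validate_experiment(experiment)
  fmt_vals <- function(m) {
    s <- format(m, trim = TRUE, scientific = FALSE, digits = 15)
    s[is.na(m)] <- ""
    s
  }
  out <- c("# multi-omics experiment",
           sprintf("!NUM-DATASETS\t%d", length(experiment$datasets)))
  for (d in experiment$datasets) {
    sp <- d$spec
    cols <- if (length(sp$columns)) paste(sp$columns, collapse = ",") else "ALL"
    out <- c(out,
             sprintf("!DATASET\t%s\t%s\t%s\t%s\t%s\t%d",
                     sp$dataset_id, sp$label, sp$data_type, sp$target_channel,
                     cols, as.integer(sp$signed)),
             sprintf("!LABELS\t%s\t%s", sp$dataset_id,
                     paste(names(d$table)[-1], collapse = "\t")))
  }
  for (d in experiment$datasets) {
    out <- c(out, sprintf(">DATASET %s", d$spec$dataset_id))
    vals <- as.matrix(d$table[, -1, drop = FALSE])
    rows <- apply(matrix(fmt_vals(vals), nrow = nrow(vals)), 1,
                  paste, collapse = "\t")
    out <- c(out, paste(d$table$entity, rows, sep = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}

# ---- master-file (multi-file) format ----------------------------------------

#' Parse the master-file (multi-file) multi-omics format
#'
#' The master file carries the header parameters of the single-file format
#' plus, per dataset, the name of a tab-delimited table file (path relative
#' to the master file). The result is identical to parsing the equivalent
#' single-file form.
#'
#' Master grammar: `!NUM-DATASETS n`, then per dataset
#' `!DATASET id<TAB>label<TAB>data_type<TAB>channel<TAB>columns<TAB>signed<TAB>file`
#' and an optional `!LABELS id<TAB>...` line. Table files hold one
#' `token<TAB>v1<TAB>v2...` row per entity.
#'
#' @param path master file.
#' @return A validated `multi_omics_experiment`.
#' @export
parse_master_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  base <- dirname(path)
  n_declared <- NA_integer_
  entries <- list(); labels <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]; t <- trimws(line)
    if (!nzchar(t) || startsWith(t, "#")) next
    if (startsWith(line, "!NUM-DATASETS")) {
      n_declared <- suppressWarnings(
        as.integer(trimws(sub("^!NUM-DATASETS", "", line))))
    } else if (startsWith(line, "!DATASET")) {
      f <- strsplit(sub("^!DATASET\t?", "", line), "\t", fixed = TRUE)[[1]]
      if (length(f) < 7) {
        abort(sprintf(
          "validation error at line %d: master !DATASET needs 7 fields", i))
      }
      sp <- parse_spec_line(f[1:6], i)
      entries[[sp$dataset_id]] <- list(spec = sp, file = f[[7]])
    } else if (startsWith(line, "!LABELS")) {
      f <- strsplit(sub("^!LABELS\t?", "", line), "\t", fixed = TRUE)[[1]]
      labels[[f[[1]]]] <- f[-1]
    } else {
      abort(sprintf("validation error at line %d: unknown master record", i))
    }
  }
  if (is.na(n_declared)) abort("validation error: missing !NUM-DATASETS header")
  if (length(entries) == 0) abort("validation error: an experiment needs >= 1 dataset")
  if (length(entries) != n_declared) {
    abort(sprintf(
      "validation error: header declares %d dataset(s) but master lists %d",
      n_declared, length(entries)))
  }

  datasets <- lapply(entries, function(en) {
    fp <- file.path(base, en$file)
    if (!file.exists(fp)) {
      abort(sprintf("missing dataset file: '%s'", en$file))
    }
    tlines <- readLines(fp, encoding = "UTF-8", warn = FALSE)
    tlines <- tlines[nzchar(trimws(tlines)) & !startsWith(trimws(tlines), "#")]
    if (!length(tlines)) {
      abort(sprintf("validation error: dataset file '%s' is empty", en$file))
    }
    parts <- strsplit(tlines, "\t", fixed = TRUE)
    ncol_vals <- max(max(lengths(parts)) - 1L,
                     length(labels[[en$spec$dataset_id]] %||% integer()))
    vals <- rows_to_matrix(lapply(seq_along(parts), function(j) {
      v <- parse_numeric_cells(parts[[j]][-1], j)
      length(v) <- ncol_vals
      v
    }), ncol_vals)
    labs <- labels[[en$spec$dataset_id]] %||% paste0("C", seq_len(ncol_vals))
    if (length(labs) != ncol_vals) labs <- paste0("C", seq_len(ncol_vals))
    tb <- as_tibble(as.data.frame(vals), .name_repair = "minimal")
    names(tb) <- labs
    tb <- bind_cols(tibble(entity = vapply(parts, `[[`, character(1), 1)), tb)
    single_omics_dataset(en$spec, tb)
  })
  multi_omics_experiment(unname(datasets))
}

#' Write an experiment in master-file (multi-file) form
#'
#' Writes `<stem>.master` plus one `<stem>_<dataset id>.tsv` table file per
#' dataset, all in the same directory.
#'
#' @param experiment a `multi_omics_experiment`.
#' @param master_path path of the master file to write.
#' @return `master_path`, invisibly.
#' @export
write_master_file <- function(experiment, master_path) {
  validate_experiment(experiment)
  base <- dirname(master_path)
  stem <- sub("\\.[^.]*$", "", basename(master_path))
  out <- c("# multi-omics master file",
           sprintf("!NUM-DATASETS\t%d", length(experiment$datasets)))
  for (d in experiment$datasets) {
    sp <- d$spec
    fn <- sprintf("%s_%s.tsv", stem, sp$dataset_id)
    cols <- if (length(sp$columns)) paste(sp$columns, collapse = ",") else "ALL"
    out <- c(out,
             sprintf("!DATASET\t%s\t%s\t%s\t%s\t%s\t%d\t%s",
                     sp$dataset_id, sp$label, sp$data_type, sp$target_channel,
                     cols, as.integer(sp$signed), fn),
             sprintf("!LABELS\t%s\t%s", sp$dataset_id,
                     paste(names(d$table)[-1], collapse = "\t")))
    vals <- as.matrix(d$table[, -1, drop = FALSE])
    s <- format(vals, trim = TRUE, scientific = FALSE, digits = 15)
    s[is.na(vals)] <- ""
    rows <- apply(matrix(s, nrow = nrow(vals)), 1, paste, collapse = "\t")
    writeLines(paste(d$table$entity, rows, sep = "\t"),
               file.path(base, fn), useBytes = TRUE)
  }
  writeLines(out, master_path, useBytes = TRUE)
  invisible(master_path)
}

# ---- preprocessing transforms -----------------------------------------------

#' Fold changes relative to a reference column
#'
#' Divides every value column by the reference column and drops the
#' reference, so an n-column time course becomes n-1 fold-change columns
#' (e.g. a five-time-point series referenced to its first time point yields
#' four columns). With `log2 = TRUE` (default) the ratios are
#' log2-transformed. A missing or zero reference value makes the whole row's
#' outputs missing, with a warning.
#'
#' @param table omics tibble (`entity` + value columns).
#' @param reference_column 1-based index of the reference value column.
#' @param log2 log2-transform the ratios?
#' @return Tibble with `entity` and n-1 value columns.
#' @export
fold_change_transform <- function(table, reference_column = 1L, log2 = TRUE) {
  nv <- ncol(table) - 1L
  if (nv < 2) abort("fold-change error: need >= 2 value columns")
  if (reference_column < 1 || reference_column > nv) {
    abort(sprintf("fold-change error: reference column %d out of range 1..%d",
                  reference_column, nv))
  }
  vals <- as.matrix(table[, -1, drop = FALSE])
  ref <- vals[, reference_column]
  bad_ref <- is.na(ref) | ref == 0
  if (any(bad_ref)) {
    warn(sprintf("fold change: %d row(s) with missing or zero reference set to missing",
                 sum(bad_ref)))
  }
  out <- vals[, -reference_column, drop = FALSE] / ref
  if (log2) out <- base::log2(out)
  out[bad_ref, ] <- NA_real_
  out[!is.finite(out)] <- NA_real_
  res <- as_tibble(as.data.frame(out), .name_repair = "minimal")
  names(res) <- names(table)[-1][-reference_column]
  bind_cols(table[, 1], res)
}

#' Gene essentiality from normalized growth yields
#'
#' Knockout growth yields normalized to wild type are converted to an
#' essentiality score by `1 - yield`, so higher values mean more essential.
#' Values are expected in \[0, 1\]; out-of-range values are transformed
#' anyway with a warning. Missing stays missing.
#'
#' @param table omics tibble (`entity` + value columns of growth yields).
#' @return Tibble of the same shape with essentiality values.
#' @export
essentiality_transform <- function(table) {
  vals <- as.matrix(table[, -1, drop = FALSE])
  oob <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(oob)) {
    warn(sprintf("essentiality: %d value(s) outside [0, 1]", sum(oob)))
  }
  out <- 1 - vals
  res <- as_tibble(as.data.frame(out), .name_repair = "minimal")
  names(res) <- names(table)[-1]
  bind_cols(table[, 1], res)
}
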