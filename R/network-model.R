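#' @import tibble
#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr filter mutate select arrange bind_rows bind_cols left_join group_by summarise ungroup n row_number
#' @importFrom generics tidy glance
NULL

COMPOUND_CLASSES <- c("amino_acid", "carbohydrate", "nucleotide", "lipid",
                      "cofactor", "other")
PATHWAY_TOP_CATEGORIES <- c("biosynthesis", "degradation", "energy", "other")

#' Construct a metabolic network
#'
#' Bundles compounds, reactions and pathways into a `metabolic_network`
#' object and builds the lookup indexes used when omics rows are resolved to
#' diagram entities: a gene index (gene id, case-folded, to the set of
#' reaction ids its products catalyze) and a compound index (case-folded id,
#' name or synonym to the primary compound id).
#'
#' @param compounds tibble with columns `id`, `name`, `compound_class`
#'   (one of amino_acid, carbohydrate, nucleotide, lipid, cofactor, other),
#'   `phosphorylated` (logical) and `synonyms` (list of character vectors).
#' @param reactions tibble with columns `id`, `substrates`, `products`,
#'   `genes`, `enzymes` (list columns of character vectors) and `reversible`.
#' @param pathways tibble with columns `id`, `name`, `category` (list column;
#'   first element one of biosynthesis, degradation, energy, other) and
#'   `reactions` (list column of reaction ids, in pathway order).
#' @param validate run the structural validators (default `TRUE`).
#'
#' @return A `metabolic_network`: a list with the three tibbles plus the
#'   rebuilt indexes.
#' @export
metabolic_network <- function(compounds = empty_compounds(),
                              reactions = empty_reactions(),
                              pathways = empty_pathways(),
                              validate = TRUE) {
  net <- structure(
    list(
      compounds = as_tibble(compounds),
      reactions = as_tibble(reactions),
      pathways  = as_tibble(pathways)
    ),
    class = "metabolic_network"
  )
  net <- rebuild_indexes(net)
  if (validate) validate_network(net)
  net
}

empty_compounds <- function() {
  tibble(id = character(), name = character(),
         compound_class = character(), phosphorylated = logical(),
         synonyms = list())
}

empty_reactions <- function() {
  tibble(id = character(), substrates = list(), products = list(),
         genes = list(), enzymes = list(), reversible = logical())
}

empty_pathways <- function() {
  tibble(id = character(), name = character(), category = list(),
         reactions = list())
}

#' Rebuild the lookup indexes of a network
#'
#' The indexes are a pure function of the stored records; rebuilding an
#' already-indexed network yields identical indexes.
#'
#' @param network a `metabolic_network`.
#' @return The network with fresh `gene_index`, `compound_index`,
#'   `reaction_index` and `pathways_of_reaction` components.
#' @export
rebuild_indexes <- function(network) {
  rx <- network$reactions
  cp <- network$compounds
  pw <- network$pathways

  gene_index <- list()
  if (nrow(rx) > 0) {
    pairs <- tibble(
      gene = tolower(unlist(rx$genes) %||% character()),
      rid  = rep(rx$id, lengths(rx$genes))
    )
    if (nrow(pairs) > 0) {
      gene_index <- split(pairs$rid, pairs$gene)
      gene_index <- lapply(gene_index, function(v) sort(unique(v)))
    }
  }

  # primary ids always win over names/synonyms; the secondary map is only
  # consulted after a primary miss
  compound_primary <- stats::setNames(cp$id, tolower(cp$id))
  sec_keys <- c(tolower(cp$name), tolower(unlist(cp$synonyms) %||% character()))
  sec_vals <- c(cp$id, rep(cp$id, lengths(cp$synonyms)))
  keep <- !duplicated(sec_keys) & nzchar(sec_keys)
  compound_secondary <- stats::setNames(sec_vals[keep], sec_keys[keep])

  reaction_primary <- stats::setNames(rx$id, tolower(rx$id))
  enz_keys <- tolower(unlist(rx$enzymes) %||% character())
  enz_vals <- rep(rx$id, lengths(rx$enzymes))
  enzyme_index <- if (length(enz_keys)) {
    lapply(split(enz_vals, enz_keys), function(v) sort(unique(v)))
  } else list()

  pw_pairs <- tibble(
    rid = unlist(pw$reactions) %||% character(),
    pid = rep(pw$id, lengths(pw$reactions))
  )
  pathways_of_reaction <- if (nrow(pw_pairs)) split(pw_pairs$pid, pw_pairs$rid) else list()

  network$gene_index <- gene_index
  network$compound_index <- list(primary = compound_primary,
                                 secondary = compound_secondary)
  network$reaction_index <- list(primary = reaction_primary,
                                 enzymes = enzyme_index)
  network$pathways_of_reaction <- pathways_of_reaction
  network
}

#' Validate a metabolic network
#'
#' Checks id uniqueness, reference closure (every substrate/product id
#' resolves to a compound, every pathway member to a reaction), enum
#' membership of compound classes and pathway top-level categories, and that
#' no reaction has an empty participant set.
#'
#' @param network a `metabolic_network`.
#' @return The network, invisibly; aborts with a validation error otherwise.
#' @export
validate_network <- function(network) {
  cp <- network$compounds; rx <- network$reactions; pw <- network$pathways
  check_ids <- function(ids, what) {
    if (any(!nzchar(ids))) abort(sprintf("validation error: empty %s id", what))
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) {
      abort(sprintf("validation error: duplicate %s id(s): %s",
                    what, paste(dup, collapse = ", ")))
    }
  }
  check_ids(cp$id, "compound")
  check_ids(rx$id, "reaction")
  check_ids(pw$id, "pathway")

  bad_class <- setdiff(cp$compound_class, COMPOUND_CLASSES)
  if (length(bad_class)) {
    abort(sprintf("validation error: unknown compound class(es): %s",
                  paste(bad_class, collapse = ", ")))
  }

  refs <- unique(unlist(c(rx$substrates, rx$products)))
  missing_cp <- setdiff(refs, cp$id)
  if (length(missing_cp)) {
    abort(sprintf("validation error: reaction references unknown compound(s): %s",
                  paste(missing_cp, collapse = ", ")))
  }
  empty_part <- rx$id[lengths(rx$substrates) + lengths(rx$products) == 0]
  if (length(empty_part)) {
    abort(sprintf("validation error: reaction(s) with no participants: %s",
                  paste(empty_part, collapse = ", ")))
  }

  if (nrow(pw)) {
    if (any(lengths(pw$category) == 0)) {
      abort("validation error: pathway with empty category path")
    }
    tops <- vapply(pw$category, `[[`, character(1), 1)
    bad_top <- setdiff(tops, PATHWAY_TOP_CATEGORIES)
    if (length(bad_top)) {
      abort(sprintf("validation error: unknown pathway top category: %s",
                    paste(bad_top, collapse = ", ")))
    }
    missing_rx <- setdiff(unique(unlist(pw$reactions)), rx$id)
    if (length(missing_rx)) {
      abort(sprintf("validation error: pathway references unknown reaction(s): %s",
                    paste(missing_rx, collapse = ", ")))
    }
  }
  invisible(network)
}

#' Reactions assigned to no pathway
#'
#' @param network a `metabolic_network`.
#' @return Character vector of orphan reaction ids, sorted.
#' @export
orphan_reactions <- function(network) {
  in_pw <- names(network$pathways_of_reaction)
  sort(setdiff(network$reactions$id, in_pw))
}

#' Resolve one entity token against the network
#'
#' Matching is case-insensitive and exact (no fuzzy matching): primary ids
#' are consulted first, then names and synonyms. Gene and protein tokens
#' resolve to the set of reactions catalyzed by products of that gene;
#' reaction tokens to a reaction id; compound tokens to a compound id.
#' An unmatched token yields an empty set plus a warning, never an error.
#'
#' @param network an indexed `metabolic_network`.
#' @param token entity name or identifier from an omics table row.
#' @param data_type one of `"gene"`, `"protein"`, `"reaction"`, `"compound"`.
#' @param quiet suppress the unmatched-token warning.
#' @return Character vector of target ids (possibly empty): reaction ids for
#'   gene/protein/reaction tokens, compound ids for compound tokens.
#' @export
lookup_entity <- function(network, token, data_type, quiet = FALSE) {
  if (!data_type %in% c("gene", "protein", "reaction", "compound")) {
    abort(sprintf("usage error: unknown data_type '%s'", data_type))
  }
  key <- tolower(token)
  hit <- switch(
    data_type,
    gene = ,
    protein = network$gene_index[[key]] %||% character(),
    reaction = {
      p <- unname(network$reaction_index$primary[key])
      if (!is.na(p)) p else network$reaction_index$enzymes[[key]] %||% character()
    },
    compound = {
      p <- unname(network$compound_index$primary[key])
      if (is.na(p)) p <- unname(network$compound_index$secondary[key])
      if (is.na(p)) character() else p
    }
  )
  if (length(hit) == 0 && !quiet) {
    warn(sprintf("unmatched %s token: '%s'", data_type, token))
  }
  sort(unique(hit))
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf(
    "<metabolic_network> %d compounds, %d reactions (%d orphan), %d pathways\n",
    nrow(x$compounds), nrow(x$reactions),
    length(orphan_reactions(x)), nrow(x$pathways)))
  invisible(x)
}

#' @export
glance.metabolic_network <- function(x, ...) {
  tibble(
    n_compounds = nrow(x$compounds),
    n_reactions = nrow(x$reactions),
    n_pathways = nrow(x$pathways),
    n_orphan_reactions = length(orphan_reactions(x)),
    n_genes = length(x$gene_index)
  )
}

#' @export
tidy.metabolic_network <- function(x, ...) {
  pw <- x$pathways_of_reaction
  x$reactions |>
    mutate(
      n_substrates = lengths(.data$substrates),
      n_products = lengths(.data$products),
      n_genes = lengths(.data$genes),
      pathway_ids = lapply(.data$id, function(i) pw[[i]] %||% character())
    ) |>
    select("id", "n_substrates", "n_products", "n_genes",
           "reversible", "pathway_ids")
}

# ---- flat network format ----------------------------------------------------

split_list_field <- function(x, sep = ",") {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, sep, fixed = TRUE)[[1]])
}

#' Read a metabolic network from the flat tab-delimited format
#'
#' The flat format is a line-oriented UTF-8 fixture format: `#` starts a
#' comment, fields are tab-separated, and each line is one of
#' `COMPOUND id name class phospho(0/1) syn1|syn2`,
#' `REACTION id sub1,sub2 prod1 gene1,gene2 reversible(0/1)` or
#' `PATHWAY id name category/subcategory r1,r2,...`.
#'
#' @param path file to read.
#' @return A validated `metabolic_network`.
#' @export
read_flat_network <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  cps <- list(); rxs <- list(); pws <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    rec <- f[[1]]
    if (rec == "COMPOUND") {
      if (length(f) < 5) abort(sprintf("line %d: COMPOUND needs >= 5 fields", i))
      cps[[length(cps) + 1]] <- tibble(
        id = f[[2]], name = f[[3]], compound_class = f[[4]],
        phosphorylated = f[[5]] == "1",
        synonyms = list(if (length(f) >= 6) split_list_field(f[[6]], "|") else character())
      )
    } else if (rec == "REACTION") {
      if (length(f) < 6) abort(sprintf("line %d: REACTION needs 6 fields", i))
      rxs[[length(rxs) + 1]] <- tibble(
        id = f[[2]],
        substrates = list(split_list_field(f[[3]])),
        products = list(split_list_field(f[[4]])),
        genes = list(split_list_field(f[[5]])),
        enzymes = list(character()),
        reversible = f[[6]] == "1"
      )
    } else if (rec == "PATHWAY") {
      if (length(f) < 5) abort(sprintf("line %d: PATHWAY needs 5 fields", i))
      pws[[length(pws) + 1]] <- tibble(
        id = f[[2]], name = f[[3]],
        category = list(split_list_field(f[[4]], "/")),
        reactions = list(split_list_field(f[[5]]))
      )
    } else {
      abort(sprintf("line %d: unknown record type '%s'", i, rec))
    }
  }
  metabolic_network(
    compounds = if (length(cps)) bind_rows(cps) else empty_compounds(),
    reactions = if (length(rxs)) bind_rows(rxs) else empty_reactions(),
    pathways = if (length(pws)) bind_rows(pws) else empty_pathways()
  )
}

#' Write a metabolic network in the flat tab-delimited format
#'
#' Inverse of [read_flat_network()]: reading the written file reproduces the
#' flat data model exactly (enzyme names are not part of the flat format).
#'
#' @param network a `metabolic_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flat_network <- function(network, path) {
  cp <- network$compounds; rx <- network$reactions; pw <- network$pathways
  join <- function(xs, sep = ",") vapply(xs, paste, character(1), collapse = sep)
  lines <- c(
    "# flat metabolic network",
    sprintf("# MANIFEST compounds=%d reactions=%d pathways=%d",
            nrow(cp), nrow(rx), nrow(pw)),
    if (nrow(cp)) sprintf("COMPOUND\t%s\t%s\t%s\t%s\t%s",
                          cp$id, cp$name, cp$compound_class,
                          as.integer(cp$phosphorylated), join(cp$synonyms, "|")),
    if (nrow(rx)) sprintf("REACTION\t%s\t%s\t%s\t%s\t%s",
                          rx$id, join(rx$substrates), join(rx$products),
                          join(rx$genes), as.integer(rx$reversible)),
    if (nrow(pw)) sprintf("PATHWAY\t%s\t%s\t%s\t%s",
                          pw$id, pw$name, join(pw$category, "/"),
                          join(pw$reactions))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read the manifest comment of a flat network file
#'
#' Fixture files written by this package carry a `# MANIFEST` comment with
#' the record counts; tests compare parsed counts against it.
#'
#' @param path flat network file.
#' @return Named integer vector (compounds, reactions, pathways) or `NULL`.
#' @export
read_flat_manifest <- function(path) {
  lines <- readLines(path, n = 10L, warn = FALSE)
  m <- grep("^# MANIFEST ", lines, value = TRUE)
  if (!length(m)) return(NULL)
  kv <- regmatches(m[[1]], gregexpr("[a-z]+=[0-9]+", m[[1]]))[[1]]
  parts <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(as.integer(vapply(parts, `[[`, character(1), 2)),
                  vapply(parts, `[[`, character(1), 1))
}

# ---- SBML -------------------------------------------------------------------

sbml_child <- function(node, local) {
  xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", local))
}

sbml_attr_any <- function(node, local) {
  # match both plain and namespace-prefixed attribute names (fbc:id etc.)
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == local | grepl(paste0(":", local, "$"), names(at)))
  if (length(hit)) unname(at[[hit[[1]]]]) else NA_character_
}

#' Read a metabolic network from SBML
#'
#' Accepts SBML Level 3 (Level 2 tolerated): one compound per species
#' (boundary species included, so currency metabolites stay paintable), one
#' reaction per `<reaction>`. Pathway membership is taken from the SBML
#' `groups` package when present (each group becomes one pathway; reactions
#' in no group are orphans). Gene links come from `fbc` gene-product
#' associations when present. Compound classes are not encoded in core SBML
#' and default to `other`.
#'
#' @param path SBML file.
#' @return A validated `metabolic_network`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(sprintf("parse error: %s", conditionMessage(e)))
  )
  model <- xml2::xml_find_first(doc, "/*[local-name()='sbml']/*[local-name()='model']")
  if (inherits(model, "xml_missing")) abort("parse error: no <model> element")

  # fbc geneProduct id -> label (gene name); fall back to the id itself
  gp_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    vapply(gp_nodes, function(n) {
      lb <- sbml_attr_any(n, "label")
      if (is.na(lb)) sbml_attr_any(n, "id") else lb
    }, character(1)),
    vapply(gp_nodes, sbml_attr_any, character(1), "id"))

  sp_nodes <- xml2::xml_find_all(
    model, "./*[local-name()='listOfSpecies']/*[local-name()='species']")
  compounds <- if (length(sp_nodes)) {
    tibble(
      id = vapply(sp_nodes, sbml_attr_any, character(1), "id"),
      name = vapply(sp_nodes, function(n) {
        nm <- sbml_attr_any(n, "name")
        if (is.na(nm)) sbml_attr_any(n, "id") else nm
      }, character(1)),
      compound_class = "other",
      phosphorylated = FALSE,
      synonyms = rep(list(character()), length(sp_nodes))
    )
  } else empty_compounds()

  rx_nodes <- xml2::xml_find_all(
    model, "./*[local-name()='listOfReactions']/*[local-name()='reaction']")
  species_refs <- function(n, side) {
    refs <- xml2::xml_find_all(
      n, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", side))
    vapply(refs, sbml_attr_any, character(1), "species")
  }
  reactions <- if (length(rx_nodes)) {
    tibble(
      id = vapply(rx_nodes, sbml_attr_any, character(1), "id"),
      substrates = lapply(rx_nodes, species_refs, "listOfReactants"),
      products = lapply(rx_nodes, species_refs, "listOfProducts"),
      genes = lapply(rx_nodes, function(n) {
        refs <- xml2::xml_find_all(n, ".//*[local-name()='geneProductRef']")
        ids <- vapply(refs, sbml_attr_any, character(1), "geneProduct")
        labs <- unname(gp_label[ids])
        out <- ifelse(is.na(labs), ids, labs)
        unique(out[!is.na(out)])
      }),
      enzymes = rep(list(character()), length(rx_nodes)),
      reversible = vapply(rx_nodes, function(n) {
        rv <- sbml_attr_any(n, "reversible")
        is.na(rv) || rv == "true"   # SBML L2 default is reversible
      }, logical(1))
    )
  } else empty_reactions()

  grp_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfGroups']/*[local-name()='group']")
  pathways <- if (length(grp_nodes)) {
    tibble(
      id = vapply(grp_nodes, sbml_attr_any, character(1), "id"),
      name = vapply(grp_nodes, function(n) {
        nm <- sbml_attr_any(n, "name")
        if (is.na(nm)) sbml_attr_any(n, "id") else nm
      }, character(1)),
      category = rep(list("other"), length(grp_nodes)),
      reactions = lapply(grp_nodes, function(n) {
        mem <- xml2::xml_find_all(n, ".//*[local-name()='member']")
        refs <- vapply(mem, sbml_attr_any, character(1), "idRef")
        refs[!is.na(refs)]
      })
    )
  } else empty_pathways()

  metabolic_network(compounds, reactions, pathways)
}
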