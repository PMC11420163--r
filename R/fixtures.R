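# deterministic RNG scope: all generators draw from a local seed and restore
# the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a toy-network fixture
#'
#' @param n_pathways number of pathways (split between biosynthesis and
#'   degradation categories, alternating).
#' @param reactions_per_pathway chain length of each pathway.
#' @param n_orphan_reactions reactions assigned to no pathway.
#' @param n_compounds total compounds; must cover the chains and orphans
#'   (default: exactly enough). Extra compounds are isolated.
#' @param seed RNG seed; the same seed yields byte-identical outputs.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_pathways = 2, reactions_per_pathway = 3,
                         n_orphan_reactions = 3, n_compounds = NULL,
                         seed = 1L) {
  if (n_pathways < 0 || reactions_per_pathway < 0 || n_orphan_reactions < 0) {
    abort("fixture counts must be nonnegative")
  }
  needed <- n_pathways * (reactions_per_pathway + 1) + 2 * n_orphan_reactions
  n_compounds <- n_compounds %||% needed
  if (n_compounds < needed) {
    abort(sprintf(
      "impossible spec: %d compounds cannot support %d reactions (need >= %d)",
      n_compounds, n_pathways * reactions_per_pathway + n_orphan_reactions,
      needed))
  }
  structure(list(n_pathways = n_pathways,
                 reactions_per_pathway = reactions_per_pathway,
                 n_orphan_reactions = n_orphan_reactions,
                 n_compounds = n_compounds, seed = as.integer(seed)),
            class = "fixture_spec")
}

PW_SUBCATEGORIES <- list(
  biosynthesis = c("amino_acid", "cofactor", "nucleotide", "lipid"),
  degradation = c("carbohydrate", "aromatic_compound", "amine", "fatty_acid")
)

#' Generate a deterministic toy metabolic network
#'
#' Pathways alternate between biosynthesis and degradation categories; each
#' is a linear substrate-product chain with 1-3 genes per reaction, random
#' compound classes, occasional phosphorylated compounds, and ATP/ADP
#' sprinkled in as currency participants. Orphan reactions connect dedicated
#' compound pairs. The same spec (same seed) yields byte-identical flat
#' files.
#'
#' @param spec a [fixture_spec()].
#' @param path optional flat-file path to also write the network to.
#' @return A validated `metabolic_network`.
#' @export
generate_toy_network <- function(spec, path = NULL) {
  net <- with_seed(spec$seed, {
    n_chain_cp <- spec$n_pathways * (spec$reactions_per_pathway + 1)
    n_cp <- spec$n_compounds
    cp_ids <- sprintf("c%04d", seq_len(n_cp))
    classes <- sample(COMPOUND_CLASSES, n_cp, replace = TRUE,
                      prob = c(0.2, 0.2, 0.1, 0.1, 0.1, 0.3))
    compounds <- tibble(
      id = cp_ids,
      name = sprintf("metabolite %d", seq_len(n_cp)),
      compound_class = classes,
      phosphorylated = stats::runif(n_cp) < 0.15,
      synonyms = lapply(seq_len(n_cp), function(i) {
        if (i %% 7 == 0) sprintf("syn-%d", i) else character()
      })
    )
    currency <- tibble(
      id = c("atp", "adp"), name = c("ATP", "ADP"),
      compound_class = "cofactor", phosphorylated = TRUE,
      synonyms = list(character(), character()))
    compounds <- bind_rows(compounds, currency)

    n_rx <- spec$n_pathways * spec$reactions_per_pathway +
      spec$n_orphan_reactions
    gene_pool <- sprintf("g%04d", seq_len(max(1, ceiling(n_rx * 1.2))))

    rxs <- list(); pws <- list()
    rx_i <- 0L; cp_i <- 0L
    for (p in seq_len(spec$n_pathways)) {
      top <- if (p %% 2 == 1) "biosynthesis" else "degradation"
      sub <- sample(PW_SUBCATEGORIES[[top]], 1)
      chain <- cp_ids[cp_i + seq_len(spec$reactions_per_pathway + 1)]
      cp_i <- cp_i + spec$reactions_per_pathway + 1
      prids <- character(0)
      for (k in seq_len(spec$reactions_per_pathway)) {
        rx_i <- rx_i + 1L
        rid <- sprintf("r%04d", rx_i)
        prids <- c(prids, rid)
        subs <- chain[[k]]; prods <- chain[[k + 1]]
        if (stats::runif(1) < 0.2) {
          subs <- c(subs, "atp"); prods <- c(prods, "adp")
        }
        rxs[[rx_i]] <- tibble(
          id = rid, substrates = list(subs), products = list(prods),
          genes = list(sample(gene_pool, sample(1:3, 1))),
          enzymes = list(character()),
          reversible = stats::runif(1) < 0.3)
      }
      pws[[p]] <- tibble(
        id = sprintf("pwy%03d", p),
        name = sprintf("%s of %s %d", top, sub, p),
        category = list(c(top, sub)),
        reactions = list(prids))
    }
    for (k in seq_len(spec$n_orphan_reactions)) {
      rx_i <- rx_i + 1L
      pair <- cp_ids[cp_i + 1:2]; cp_i <- cp_i + 2L
      rxs[[rx_i]] <- tibble(
        id = sprintf("r%04d", rx_i),
        substrates = list(pair[[1]]), products = list(pair[[2]]),
        genes = list(sample(gene_pool, sample(1:3, 1))),
        enzymes = list(character()),
        reversible = stats::runif(1) < 0.3)
    }
    metabolic_network(
      compounds = compounds,
      reactions = if (length(rxs)) bind_rows(rxs) else empty_reactions(),
      pathways = if (length(pws)) bind_rows(pws) else empty_pathways())
  })
  if (!is.null(path)) write_flat_network(net, path)
  net
}

#' The shipped toy quinate network
#'
#' A small hand-built network emulating quinate catabolism feeding aromatic
#' amino acid biosynthesis: one degradation pathway (quinate to
#' beta-ketoadipate), one biosynthesis pathway (chorismate to tyrosine) and
#' three orphan reactions. 11 compounds, 9 reactions, 2 pathways. The same
#' network ships as a flat file under `inst/extdata/toy_quinate_network.tsv`.
#'
#' @return A validated `metabolic_network`.
#' @export
toy_quinate_network <- function() {
  compounds <- tibble(
    id = c("quinate", "dhq", "dhs", "pca", "bka",
           "chorismate", "prephenate", "tyr",
           "succ", "fum", "mal"),
    name = c("quinate", "3-dehydroquinate", "3-dehydroshikimate",
             "protocatechuate", "beta-ketoadipate",
             "chorismate", "prephenate", "L-tyrosine",
             "succinate", "fumarate", "malate"),
    compound_class = c("carbohydrate", "carbohydrate", "carbohydrate",
                       "other", "other", "other", "other", "amino_acid",
                       "other", "other", "other"),
    phosphorylated = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                       FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    synonyms = list("quinic acid", character(), character(),
                    "PCA", character(), character(), character(),
                    c("tyrosine", "Tyr"), character(), character(),
                    character())
  )
  rx <- function(id, s, p, g, rev = FALSE) {
    tibble(id = id, substrates = list(s), products = list(p),
           genes = list(g), enzymes = list(character()), reversible = rev)
  }
  reactions <- bind_rows(
    rx("rxn-quiA", "quinate", "dhq", "quiA"),
    rx("rxn-quiB", "dhq", "dhs", "quiB"),
    rx("rxn-quiC", "dhs", "pca", "quiC"),
    rx("rxn-pcaGH", "pca", "bka", c("pcaG", "pcaH")),
    rx("rxn-aroQ", "chorismate", "prephenate", "aroQ", rev = TRUE),
    rx("rxn-tyrA", "prephenate", "tyr", "tyrA"),
    rx("rxn-sdh", "succ", "fum", c("sdhA", "sdhB")),
    rx("rxn-fumC", "fum", "mal", "fumC", rev = TRUE),
    rx("rxn-shunt", "quinate", "pca", "quiX")
  )
  pathways <- tibble(
    id = c("pwy-quinate-deg", "pwy-tyr-syn"),
    name = c("quinate degradation", "tyrosine biosynthesis"),
    category = list(c("degradation", "aromatic_compound"),
                    c("biosynthesis", "amino_acid")),
    reactions = list(c("rxn-quiA", "rxn-quiB", "rxn-quiC", "rxn-pcaGH"),
                     c("rxn-aroQ", "rxn-tyrA"))
  )
  metabolic_network(compounds, reactions, pathways)
}

# ---- experiment generation --------------------------------------------------

#' Specify one generated single-omics dataset
#'
#' @param data_type gene, protein, reaction or compound.
#' @param target_channel visual channel to paint.
#' @param n_columns value columns (time points / conditions).
#' @param distribution `"normal"`, `"lognormal"` or `"uniform"`.
#' @param p1,p2 distribution parameters (mean/sd, meanlog/sdlog, min/max).
#' @param fraction_missing fraction of cells set to missing.
#' @param fraction_unmatched fraction of rows given tokens matching nothing.
#' @param n_rows rows to draw (default: every matching entity).
#' @param labels optional column labels.
#' @param signed values centered on zero?
#' @return A list describing the dataset.
#' @export
fixture_dataset <- function(data_type, target_channel, n_columns = 1,
                            distribution = "normal", p1 = 0, p2 = 1,
                            fraction_missing = 0, fraction_unmatched = 0,
                            n_rows = NULL, labels = NULL, signed = FALSE) {
  if (!distribution %in% c("normal", "lognormal", "uniform")) {
    abort(sprintf("unknown distribution '%s'", distribution))
  }
  if (fraction_missing < 0 || fraction_missing > 1 ||
      fraction_unmatched < 0 || fraction_unmatched > 1) {
    abort("fractions must be in [0, 1]")
  }
  list(data_type = data_type, target_channel = target_channel,
       n_columns = as.integer(n_columns), distribution = distribution,
       p1 = p1, p2 = p2, fraction_missing = fraction_missing,
       fraction_unmatched = fraction_unmatched, n_rows = n_rows,
       labels = labels, signed = signed)
}

network_tokens <- function(network, data_type) {
  switch(data_type,
         gene = ,
         protein = sort(unique(unlist(network$reactions$genes))),
         reaction = sort(network$reactions$id),
         compound = sort(network$compounds$id))
}

draw_values <- function(ds, n) {
  switch(ds$distribution,
         normal = stats::rnorm(n, ds$p1, ds$p2),
         lognormal = stats::rlnorm(n, ds$p1, ds$p2),
         uniform = stats::runif(n, ds$p1, ds$p2))
}

#' Generate a multi-omics experiment over a network
#'
#' Tokens are drawn from the network's genes, reactions or compounds, plus
#' the requested fraction of unmatched tokens; values come from the stated
#' distributions. Two presets emulate the shapes of published case studies:
#' `"synechocystis-like"` (transcriptomics and proteomics with 5 raw
#' time-point columns at 1 h, 3 h, 11.75 h, 13 h and 15 h, plus a one-column
#' metabolomics score set) and `"abaylyi-like"` (three one-column datasets:
#' expression to edge color, knockout growth yields to edge thickness,
#' metabolite changes to node color).
#'
#' @param datasets list of [fixture_dataset()] specs, or a preset name.
#' @param network the network to sample tokens from.
#' @param seed RNG seed (same seed, same experiment).
#' @param path optional single-file path to also write the experiment to.
#' @return A validated `multi_omics_experiment`.
#' @export
generate_experiment <- function(datasets, network, seed = 1L, path = NULL) {
  if (is.character(datasets) && length(datasets) == 1) {
    datasets <- experiment_preset(datasets)
  }
  if (length(datasets) > 4) abort("at most 4 datasets allowed")
  exp <- with_seed(seed, {
    built <- lapply(seq_along(datasets), function(i) {
      ds <- datasets[[i]]
      tokens <- network_tokens(network, ds$data_type)
      n <- min(ds$n_rows %||% length(tokens), length(tokens))
      tokens <- if (n < length(tokens)) sort(sample(tokens, n)) else tokens
      n_un <- round(ds$fraction_unmatched * length(tokens))
      if (n_un > 0) {
        tokens[sample(length(tokens), n_un)] <-
          sprintf("unmatched-%03d", seq_len(n_un))
      }
      vals <- matrix(draw_values(ds, length(tokens) * ds$n_columns),
                     ncol = ds$n_columns)
      if (ds$fraction_missing > 0) {
        vals[stats::runif(length(vals)) < ds$fraction_missing] <- NA_real_
      }
      labs <- ds$labels %||% paste0("C", seq_len(ds$n_columns))
      tb <- as_tibble(as.data.frame(vals), .name_repair = "minimal")
      names(tb) <- labs
      single_omics_dataset(
        dataset_spec(sprintf("ds%d", i),
                     sprintf("%s (%s)", ds$data_type, ds$target_channel),
                     ds$data_type, ds$target_channel, signed = ds$signed),
        bind_cols(tibble(entity = tokens), tb))
    })
    multi_omics_experiment(built)
  })
  if (!is.null(path)) write_single_file(exp, path)
  exp
}

#' Built-in experiment presets
#' @param name `"synechocystis-like"` or `"abaylyi-like"`.
#' @return List of [fixture_dataset()] specs.
#' @export
experiment_preset <- function(name) {
  tp <- c("1 h", "3 h", "11.75 h", "13 h", "15 h")
  switch(
    name,
    "synechocystis-like" = list(
      fixture_dataset("gene", "edge_color", n_columns = 5,
                      distribution = "lognormal", p1 = 5, p2 = 1.2,
                      fraction_missing = 0.02, fraction_unmatched = 0.05,
                      labels = tp),
      fixture_dataset("protein", "edge_thickness", n_columns = 5,
                      distribution = "lognormal", p1 = 3, p2 = 0.8,
                      fraction_missing = 0.1, fraction_unmatched = 0.05,
                      labels = tp),
      fixture_dataset("compound", "node_color", n_columns = 1,
                      distribution = "normal", p1 = 0, p2 = 2,
                      fraction_missing = 0, fraction_unmatched = 0.05,
                      labels = "score", signed = TRUE)
    ),
    "abaylyi-like" = list(
      fixture_dataset("gene", "edge_color", n_columns = 1,
                      distribution = "normal", p1 = 0, p2 = 2.5,
                      fraction_missing = 0.02, fraction_unmatched = 0.05,
                      labels = "log2 FC quinate vs succinate", signed = TRUE),
      fixture_dataset("gene", "edge_thickness", n_columns = 1,
                      distribution = "uniform", p1 = 0, p2 = 1,
                      fraction_missing = 0.02, fraction_unmatched = 0.05,
                      labels = "growth yield"),
      fixture_dataset("compound", "node_color", n_columns = 1,
                      distribution = "normal", p1 = 0, p2 = 2,
                      fraction_missing = 0, fraction_unmatched = 0.05,
                      labels = "log2 abundance change", signed = TRUE)
    ),
    abort(sprintf("unknown preset '%s'", name))
  )
}
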