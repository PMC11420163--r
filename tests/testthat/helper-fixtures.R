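# shared fixture builders: everything is generated in code at test time

network_tokens_for_test <- function(net, data_type) {
  omicanvas:::network_tokens(net, data_type)
}

toy_net <- function() toy_quinate_network()

# a tiny two-dataset experiment with known values over the toy network
tiny_experiment <- function() {
  tx <- single_omics_dataset(
    dataset_spec("tx", "transcriptomics", "gene", "edge_color", signed = TRUE),
    tibble::tibble(entity = c("quiA", "quiB", "pcaG", "pcaH", "zzz-absent"),
                   `1 h` = c(0, 0, 0, 0, 0),
                   `3 h` = c(1.5, -2, 3, -5, 1)))
  met <- single_omics_dataset(
    dataset_spec("met", "metabolomics", "compound", "node_color", signed = TRUE),
    tibble::tibble(entity = c("quinic acid", "PCA", "tyr"),
                   score = c(5.1, 2.0, NA)))
  multi_omics_experiment(list(tx, met))
}

random_experiment <- function(seed, max_datasets = 4) {
  set.seed(seed)
  nd <- sample(seq_len(max_datasets), 1)
  channels <- sample(c("edge_color", "edge_thickness", "node_color",
                       "node_thickness"), nd)
  datasets <- lapply(seq_len(nd), function(i) {
    ch <- channels[[i]]
    dt <- if (startsWith(ch, "node")) "compound" else
      sample(c("gene", "protein", "reaction"), 1)
    nr <- sample(1:8, 1); nc <- sample(1:5, 1)
    vals <- matrix(round(stats::rnorm(nr * nc), 6), nr, nc)
    vals[stats::runif(nr * nc) < 0.15] <- NA_real_
    tb <- tibble::as_tibble(as.data.frame(vals), .name_repair = "minimal")
    names(tb) <- sprintf("t%d", seq_len(nc))
    tb <- dplyr::bind_cols(
      tibble::tibble(entity = sprintf("tok_%d_%d", i, seq_len(nr))), tb)
    single_omics_dataset(
      dataset_spec(sprintf("ds%d", i), sprintf("dataset %d", i), dt, ch,
                   signed = i %% 2 == 0),
      tb)
  })
  multi_omics_experiment(datasets)
}

expect_experiment_equal <- function(a, b) {
  expect_equal(length(a$datasets), length(b$datasets))
  for (i in seq_along(a$datasets)) {
    expect_equal(a$datasets[[i]]$spec, b$datasets[[i]]$spec)
    expect_equal(a$datasets[[i]]$table, b$datasets[[i]]$table,
                 tolerance = 1e-12)
  }
}

# minimal SBML fixture written in code; counts: 5 species, 3 reactions,
# 1 group of 2 reactions
write_sbml_fixture <- function(path, break_reference = FALSE) {
  bad <- if (break_reference) "s9" else "s4"
  xml <- sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1">
 <model id="m1">
  <listOfSpecies>
   <species id="s1" name="alpha" boundaryCondition="true"/>
   <species id="s2" name="beta"/>
   <species id="s3"/>
   <species id="s4"/>
   <species id="s5"/>
  </listOfSpecies>
  <fbc:listOfGeneProducts>
    <fbc:geneProduct fbc:id="gp1" fbc:label="geneA"/>
  </fbc:listOfGeneProducts>
  <listOfReactions>
   <reaction id="r1" reversible="false">
    <listOfReactants><speciesReference species="s1"/></listOfReactants>
    <listOfProducts><speciesReference species="s2"/></listOfProducts>
    <fbc:geneProductAssociation><fbc:geneProductRef fbc:geneProduct="gp1"/></fbc:geneProductAssociation>
   </reaction>
   <reaction id="r2" reversible="true">
    <listOfReactants><speciesReference species="s2"/></listOfReactants>
    <listOfProducts><speciesReference species="s3"/></listOfProducts>
   </reaction>
   <reaction id="r3" reversible="false">
    <listOfReactants><speciesReference species="%s"/></listOfReactants>
    <listOfProducts><speciesReference species="s5"/></listOfProducts>
   </reaction>
  </listOfReactions>
  <groups:listOfGroups>
   <groups:group groups:id="path1" groups:kind="collection" groups:name="chain">
    <groups:listOfMembers>
     <groups:member groups:idRef="r1"/>
     <groups:member groups:idRef="r2"/>
    </groups:listOfMembers>
   </groups:group>
  </groups:listOfGroups>
 </model>
</sbml>', bad)
  writeLines(xml, path)
  path
}
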