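test_that("SBML writer/reader round-trips the generator's model exactly", {
  gem <- generate_toy_gem(n_chain = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(gem$model, path)
  m2 <- read_sbml_model(path)
  expect_equal(m2$objective_reaction, gem$model$objective_reaction)
  expect_setequal(m2$gene_ids, gem$model$gene_ids)
  expect_setequal(m2$metabolites, gem$model$metabolites)
  expect_equal(names(m2$reactions), names(gem$model$reactions))
  for (rid in names(gem$model$reactions)) {
    a <- gem$model$reactions[[rid]]; b <- m2$reactions[[rid]]
    expect_equal(b$lower_bound, a$lower_bound, tolerance = 1e-12)
    expect_equal(b$upper_bound, a$upper_bound, tolerance = 1e-12)
    expect_equal(sort(names(b$stoichiometry)), sort(names(a$stoichiometry)))
    expect_identical(deparse_gpr(b$gpr), deparse_gpr(a$gpr))
  }
})

test_that("SBML without an objective is a hard error naming the model", {
  gem <- generate_toy_gem(seed = 1)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(gem$model, path)
  txt <- readLines(path)
  txt <- txt[!grepl("Objective", txt)]
  writeLines(txt, path)
  expect_error(read_sbml_model(path), "no objective reaction")
})

test_that("COBRA Level-2 dialect (kineticLaw bounds, notes GPR) is read", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="l2toy"><listOfSpecies>',
    '<species id="A" compartment="c"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_A" reversible="false">',
    '<listOfProducts><speciesReference species="A"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="7"/>',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="0"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '<reaction id="R_bio" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: ga and gb</p></body></notes>',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="1000"/>',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="1"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '</listOfReactions></model></sbml>'), path)
  m <- read_sbml_model(path)
  expect_equal(m$objective_reaction, "R_bio")
  expect_equal(m$reactions$EX_A$upper_bound, 7)
  expect_equal(deparse_gpr(m$reactions$R_bio$gpr), "ga and gb")
  expect_equal(optimize_growth(m)$objective_value, 7)
})

test_that("expression TSV round-trips and collapses duplicate genes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  set.seed(3)
  mat <- matrix(round(rnorm(500 * 60, 8, 2), 6), 500, 60,
                dimnames = list(sprintf("g%03d", 1:500),
                                sprintf("s%02d", 1:60)))
  write_expression_matrix(mat, path)
  back <- read_expression_matrix(path)
  expect_equal(unclass(back), unclass(mat), tolerance = 1e-12,
               ignore_attr = TRUE)

  writeLines(c("gene\ts1\ts2", "gA\t2\t10", "gA\t4\t20", "gB\t1\t1"), path)
  expect_message(dup <- read_expression_matrix(path), "collapsed")
  expect_equal(dup["gA", ], c(s1 = 3, s2 = 15))
  expect_equal(attr(dup, "n_collapsed"), 1L)

  writeLines(c("gene\ts1\ts2", "gA\t2\t10", "gB\t4"), path)
  expect_error(read_expression_matrix(path), "ragged")
})

test_that("edge-list reading defaults, preserves signs, deduplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf\ttarget", "TF1\tG1", "TF2\tG2"), path)
  net <- read_network_edges(path)
  expect_equal(nrow(net), 2)
  expect_true(all(net$sign == "unknown"))
  expect_true(all(net$confidence == "standard"))

  writeLines(c("tf\ttarget\tsign", "TF1\tG1\tactivation",
               "TF2\tG2\tinhibition"), path)
  expect_equal(read_network_edges(path)$sign,
               c("activation", "inhibition"))

  writeLines(c("tf\ttarget\tsign", "TF1\tG1\tunknown",
               "TF1\tG1\tactivation", "TF2\tG2\tinhibition"), path)
  expect_message(dd <- read_network_edges(path), "collapsed")
  expect_equal(nrow(dd), 2)
  expect_equal(dd$sign[dd$tf == "TF1"], "activation")
  expect_equal(attr(dd, "n_deduplicated"), 1L)

  writeLines(c("regulator\ttarget", "TF1\tG1"), path)
  expect_error(read_network_edges(path), "tf")
})

test_that("clinical table validates events and drops non-positive times", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\ttime\tevent", "s1\t10\t1", "s2\t20\t0",
               "s3\t5\t1", "s4\t8\t0"), path)
  expect_equal(nrow(read_clinical_table(path)), 4)

  writeLines(c("sample\ttime\tevent", "s1\t10\t1", "s2\t0\t0",
               "s3\t5\t1", "s4\t8\t0"), path)
  expect_warning(cl <- read_clinical_table(path), "non-positive")
  expect_equal(nrow(cl), 3)
  expect_equal(attr(cl, "n_dropped"), 1L)

  writeLines(c("sample\ttime\tevent", "s1\t10\t2"), path)
  expect_error(read_clinical_table(path), "event")
})

test_that("network export: SIF wording and GraphML attribute round trip", {
  net <- tibble::tibble(tf = c("TF1", "TF2"), target = c("G1", "G2"),
                        sign = c("activation", "inhibition"),
                        confidence = c("high", "standard"),
                        source_tag = "x")
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "SIF")
  expect_equal(readLines(sif)[1], "TF1\tregulates\tG1")

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "GraphML")
  back <- read_network_graphml(gml)
  expect_setequal(paste(back$tf, back$target, back$sign, back$confidence),
                  paste(net$tf, net$target, net$sign, net$confidence))

  expect_error(export_network(net, sif, "dot"))
  expect_error(export_network(net[0, ], sif, "SIF"), "empty")
})
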