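test_that("cohort essentiality replicates identical models and masks", {
  gem <- generate_toy_gem(n_chain = 2, seed = 3)
  models <- list(P1 = gem$model, P2 = gem$model, P3 = gem$model)
  em <- cohort_essentiality(models)
  expect_equal(em$ratios[, "P1"], em$ratios[, "P2"])
  expect_equal(em$ratios[, "P1"], em$ratios[, "P3"])
  expect_false(any(em$absent))

  # a gene carried by only one patient is masked in the others
  extra <- gem$model
  extra$reactions[["R_opt"]] <- reaction("R_opt", c(M1 = -1, M2 = 1),
                                         0, 5, gpr = "gonly")
  extra <- metabolic_model(unname(extra$reactions),
                           extra$objective_reaction)
  em2 <- cohort_essentiality(list(P1 = extra, P2 = gem$model,
                                  P3 = gem$model))
  expect_false(em2$absent["gonly", "P1"])
  expect_true(all(em2$absent["gonly", c("P2", "P3")]))
  expect_equal(unname(em2$ratios["gonly", c("P2", "P3")]), c(1, 1))

  # a non-growing patient model is excluded with a warning
  dead <- set_bounds(gem$model, "EX_in", upper = 0)
  expect_warning(em3 <- cohort_essentiality(list(P1 = gem$model,
                                                 P2 = dead)),
                 "cannot grow")
  expect_equal(em3$excluded, "P2")
})

test_that("the at-least-half consensus rule is exact at the boundary", {
  genes <- c("gA", "gB", "gC")
  pats <- sprintf("P%02d", 1:10)
  ratios <- matrix(1, 3, 10, dimnames = list(genes, pats))
  ratios["gA", 1:6] <- 0      # essential in 6/10 -> in
  ratios["gB", 1:4] <- 0      # essential in 4/10 -> out
  ratios["gC", 1:5] <- 0.005  # essential in exactly half -> in
  em <- structure(list(ratios = ratios,
                       absent = matrix(FALSE, 3, 10,
                                       dimnames = dimnames(ratios)),
                       wildtype_growth = stats::setNames(rep(10, 10),
                                                         pats),
                       excluded = character()),
                  class = "essentiality_matrix")
  got <- consensus_essential_genes(em, pats, essential_cutoff = 0.01,
                                   min_fraction = 0.5)
  expect_setequal(got, c("gA", "gC"))

  # genes with no influence anywhere are excluded even if "non-lethal
  # essential" thresholds would admit them
  ratios2 <- ratios; ratios2["gB", ] <- 1
  em$ratios <- ratios2
  expect_false("gB" %in% consensus_essential_genes(em, pats, 0.5, 0.1))

  # monotone in the cutoff: raising it never removes a gene
  set.seed(10)
  emr <- em
  emr$ratios <- matrix(runif(30), 3, 10, dimnames = dimnames(ratios))
  cuts <- c(0.01, 0.1, 0.3, 0.6, 0.9)
  lists <- lapply(cuts, function(ct)
    consensus_essential_genes(emr, pats, ct, 0.5))
  for (i in seq_along(cuts)[-1])
    expect_true(all(lists[[i - 1]] %in% lists[[i]]))
})

test_that("shared/exclusive gene partitioning follows set semantics", {
  lists <- list(C1 = c("A", "B"), C2 = c("B", "C"), C3 = "B")
  res <- class_exclusive_genes(lists)
  expect_equal(res$shared, "B")
  expect_equal(res$exclusive$C1, "A")
  expect_equal(res$exclusive$C2, "C")
  expect_length(res$exclusive$C3, 0)
  expect_equal(res$pairwise_shared[["C1&C2"]], "B")

  same <- class_exclusive_genes(list(C1 = c("X", "Y"), C2 = c("X", "Y")))
  expect_setequal(same$shared, c("X", "Y"))
  expect_true(all(lengths(same$exclusive) == 0))

  # exclusives are pairwise disjoint by construction
  set.seed(6)
  rnd <- lapply(1:3, function(i) sample(LETTERS, 10))
  names(rnd) <- paste0("C", 1:3)
  ex <- class_exclusive_genes(rnd)$exclusive
  expect_length(intersect(ex[[1]], ex[[2]]), 0)
  expect_length(intersect(ex[[1]], ex[[3]]), 0)
  expect_length(intersect(ex[[2]], ex[[3]]), 0)
})

test_that("flux categorization thresholds at epsilon", {
  expect_equal(flux_category(1e-9, 1e-6), "zero")
  expect_equal(flux_category(0.5), "pos")
  expect_equal(flux_category(-0.5), "neg")
  expect_equal(flux_category(c(-2, 0, 2)), c("neg", "zero", "pos"))
})

pattern_fixture <- function(c1, c2, c3) {
  # 4 patients per class; c* are the class flux values
  ft <- matrix(c(rep(c1, 4), rep(c2, 4), rep(c3, 4)), nrow = 1)
  colnames(ft) <- sprintf("P%02d", 1:12)
  rownames(ft) <- "RX"
  labs <- stats::setNames(rep(c("Class1", "Class2", "Class3"), each = 4),
                          colnames(ft))
  classify_flux_patterns(ft, labs, poor_class = "Class2")
}

test_that("the four flux-reprogramming types match their definitions", {
  expect_equal(pattern_fixture(-1, +1, -1)$pattern_type, "1")
  expect_equal(pattern_fixture(+2, -1, +2)$pattern_type, "2")
  expect_equal(pattern_fixture(+2, 0, +2)$pattern_type, "3")
  expect_equal(pattern_fixture(0, -3, 0)$pattern_type, "4")
  expect_equal(pattern_fixture(+2, +1, +2)$pattern_type, "none")
  expect_equal(pattern_fixture(-1, +1, +1)$pattern_type, "none")
})

test_that("a 50/50 split in the poor class breaks the strict majority", {
  ft <- matrix(c(rep(-1, 4), c(1, 1, 0, 0), rep(-1, 4)), nrow = 1,
               dimnames = list("RX", sprintf("P%02d", 1:12)))
  labs <- stats::setNames(rep(c("Class1", "Class2", "Class3"), each = 4),
                          colnames(ft))
  res <- classify_flux_patterns(ft, labs, "Class2")
  expect_equal(res$pattern_type, "none")
})

test_that("patterns are mutually exclusive on fuzzed inputs", {
  set.seed(23)
  for (i in 1:200) {
    vals <- sample(c(-2, -1, 0, 1, 2), 12, replace = TRUE)
    ft <- matrix(vals, nrow = 1,
                 dimnames = list("RX", sprintf("P%02d", 1:12)))
    labs <- stats::setNames(rep(c("Class1", "Class2", "Class3"),
                                each = 4), colnames(ft))
    res <- classify_flux_patterns(ft, labs, "Class2")
    expect_length(res$pattern_type, 1)
    expect_true(res$pattern_type %in% c("1", "2", "3", "4", "none"))
    # a typed call requires a strict majority category in every class
    if (res$pattern_type != "none") {
      fr <- unlist(res[paste0("fraction_",
                              c("Class1", "Class2", "Class3"))])
      expect_true(all(fr > 0.5))
    }
  }
})

test_that("absent reactions are excluded from majority denominators", {
  ft <- matrix(c(rep(-1, 3), NA, rep(1, 4), rep(-1, 3), NA), nrow = 1,
               dimnames = list("RX", sprintf("P%02d", 1:12)))
  labs <- stats::setNames(rep(c("Class1", "Class2", "Class3"), each = 4),
                          colnames(ft))
  res <- classify_flux_patterns(ft, labs, "Class2")
  expect_equal(res$pattern_type, "1")
  expect_equal(res$fraction_Class1, 1)
})

test_that("planted class-specific flux shifts are recovered", {
  # 5-sigma planted shifts with Gaussian noise; >= 95% of planted
  # reactions must recover their planted type
  set.seed(71)
  n_per <- 10; sigma <- 0.05
  labs <- stats::setNames(rep(c("Class1", "Class2", "Class3"),
                              each = n_per), sprintf("P%02d", 1:30))
  planted <- list(`1` = c(-1, 1), `2` = c(1, -1),
                  `3` = c(1, 0), `4` = c(0, 1))
  n_rep <- 25
  ft <- matrix(NA_real_, 4 * n_rep, 30,
               dimnames = list(sprintf("R%03d", 1:(4 * n_rep)),
                               names(labs)))
  truth <- character(4 * n_rep)
  row <- 0
  for (tp in names(planted)) {
    for (r in seq_len(n_rep)) {
      row <- row + 1
      mu <- planted[[tp]]
      base <- ifelse(labs == "Class2", mu[2] * 5 * sigma,
                     mu[1] * 5 * sigma)
      ft[row, ] <- base + rnorm(30, sd = sigma)
      truth[row] <- tp
    }
  }
  res <- classify_flux_patterns(ft, labs, "Class2", epsilon = 2.5 * sigma)
  expect_gte(mean(res$pattern_type == truth), 0.95)
})
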