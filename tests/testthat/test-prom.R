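test_that("binarization uses a single pooled quantile threshold", {
  m <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  bin <- binarize_expression(m, 0.5)
  expect_equal(bin$threshold, 2.5)
  expect_identical(unname(bin$calls),
                   matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))

  # quantile 0: everything strictly above the minimum is ON
  b0 <- binarize_expression(m, 0)
  expect_equal(sum(!b0$calls), 1)

  expect_error(binarize_expression(matrix(2, 3, 3), 0.5), "degenerate")
})

test_that("planted OFF fraction is recovered by the matching quantile", {
  reg <- toy_regulon_net()
  sim <- simulate_expression_cohort(reg$net, reg$planted_p,
                                    n_samples = 150, seed = 21)
  off_frac <- sim$truth$off_rate_overall
  bin <- binarize_expression(sim$expr, off_frac)
  expect_lt(abs(mean(!bin$calls) - off_frac), 0.02)
  # calls agree with the generator's planted states almost everywhere
  agree <- mean(bin$calls == sim$truth$on_states)
  expect_gt(agree, 0.98)
})

test_that("conditional probabilities are plain count fractions", {
  calls <- rbind(
    TFX = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    G1  = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    G2  = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  colnames(calls) <- paste0("s", 1:6)
  bin <- structure(list(calls = calls, threshold = 0, quantile = 0.5),
                   class = "binarized_expression")
  net <- tibble::tibble(tf = c("TFX", "TFX", "TFX"),
                        target = c("G1", "G2", "G_unmeasured"),
                        sign = "activation")
  expect_warning(pr <- estimate_conditional_probabilities(bin, net,
                                                          min_off_samples = 2),
                 "skipped")
  expect_equal(pr$p_on_given_off[pr$target == "G1"], 0.25)
  expect_equal(pr$p_on_given_off[pr$target == "G2"], 1)
  expect_equal(nrow(pr), 2)

  # a TF that is never OFF is flagged with p = 1
  net2 <- tibble::tibble(tf = "G2", target = "G1", sign = "activation")
  pr2 <- estimate_conditional_probabilities(bin, net2, min_off_samples = 2)
  expect_true(pr2$flagged_insufficient)
  expect_equal(pr2$p_on_given_off, 1)
})

test_that("planted conditional probabilities are recovered at n = 200", {
  reg <- toy_regulon_net()
  sim <- simulate_expression_cohort(reg$net, reg$planted_p,
                                    n_samples = 200, seed = 33)
  bin <- binarize_expression(sim$expr, sim$truth$off_rate_overall)
  pr <- estimate_conditional_probabilities(bin, reg$net)
  truth <- sim$truth$planted_edges
  merged <- dplyr::inner_join(pr, truth, by = c("tf", "target"))
  expect_equal(nrow(merged), nrow(truth))
  expect_true(all(merged$n_off_samples >= 20))
  expect_true(all(abs(merged$p_on_given_off - merged$p) <= 0.05))
})

test_that("PROM constraints scale bounds by kappa * Vmax and only tighten", {
  gem <- generate_toy_gem(n_chain = 3, seed = 9)
  fva <- flux_variability(gem$model, 0)

  probs1 <- tibble::tibble(tf = "TF", target = "gchain1",
                           sign = "activation", p_on_given_off = 1,
                           n_off_samples = 50L,
                           flagged_insufficient = FALSE)
  m1 <- constrain_model_for_tf_knockout(gem$model, "TF", probs1, fva)
  expect_equal(reaction_bounds(m1), reaction_bounds(gem$model))
  expect_equal(attr(m1, "n_constrained_reactions"), 0L)

  probs0 <- dplyr::mutate(probs1, p_on_given_off = 0)
  m0 <- constrain_model_for_tf_knockout(gem$model, "TF", probs0, fva)
  expect_equal(m0$reactions$R_chain1$upper_bound, 0)
  expect_equal(m0$reactions$R_chain1$lower_bound, 0)

  # p = 0.5 on the rate-limiting chain (Vmax = 10) halves the cap
  probs5 <- dplyr::mutate(probs1, p_on_given_off = 0.5)
  m5 <- constrain_model_for_tf_knockout(gem$model, "TF", probs5, fva)
  expect_equal(m5$reactions$R_chain1$upper_bound, 5, tolerance = 1e-9)
  r5 <- simulate_tf_knockout(gem$model, "TF", probs5, fva)
  expect_equal(r5$growth_ratio, 0.5, tolerance = 1e-9)

  # inhibition edges do not constrain in sign-aware mode, but do in
  # prom_pure mode
  probsI <- dplyr::mutate(probs5, sign = "inhibition")
  expect_warning(mI <- constrain_model_for_tf_knockout(gem$model, "TF",
                                                       probsI, fva),
                 "no regulated targets")
  expect_equal(reaction_bounds(mI), reaction_bounds(gem$model))
  mP <- constrain_model_for_tf_knockout(gem$model, "TF", probsI, fva,
                                        sign_mode = "prom_pure")
  expect_equal(mP$reactions$R_chain1$upper_bound, 5, tolerance = 1e-9)
})

test_that("a TF that is also a metabolic gene is deleted as a gene", {
  gem <- generate_toy_gem(n_chain = 3, seed = 9)
  fva <- flux_variability(gem$model, 0)
  # gchain2 acts as a TF regulating the isozyme gene with p = 1: the
  # probabilistic constraint is inert, but the gene deletion is lethal
  probs <- tibble::tibble(tf = "gchain2", target = "giso1_a",
                          sign = "activation", p_on_given_off = 1,
                          n_off_samples = 50L,
                          flagged_insufficient = FALSE)
  res <- simulate_tf_knockout(gem$model, "gchain2", probs, fva)
  expect_equal(res$growth_ratio, 0)
})

test_that("TF screen recovers graded planted probabilities exactly", {
  gem <- generate_toy_gem(n_chain = 3, seed = 11)
  planted <- c(TF_lethal = 0, TF_quarter = 0.25, TF_half = 0.5,
               TF_inert = 1)
  reg <- toy_regulon_net(planted)
  probs <- tibble::tibble(tf = reg$net$tf, target = reg$net$target,
                          sign = "activation",
                          p_on_given_off = reg$planted_p,
                          n_off_samples = 100L,
                          flagged_insufficient = FALSE)
  sc <- suppressWarnings(screen_tf_knockouts(gem$model, probs))
  got <- stats::setNames(sc$growth_ratio, sc$tf)
  expect_equal(unname(got[names(planted)]), unname(planted),
               tolerance = 1e-6)
  # sorted ascending by growth ratio; the fully-gating TF ranks first
  expect_equal(sc$tf[1], "TF_lethal")
  expect_true(!is.unsorted(sc$growth_ratio))

  # order invariance
  sc2 <- suppressWarnings(
    screen_tf_knockouts(gem$model, probs, tf_list = rev(names(planted))))
  expect_equal(as.data.frame(sc2), as.data.frame(sc))
})

test_that("TF-knockout ratios never exceed 1 (constraints only tighten)", {
  set.seed(55)
  for (s in 1:8) {
    m <- random_toy_model(s)
    fva <- flux_variability(m, 0)
    genes <- m$gene_ids
    for (k in 1:6) {
      targets <- sample(genes, sample(1:3, 1))
      probs <- tibble::tibble(tf = "TFr", target = targets,
                              sign = sample(c("activation", "unknown"),
                                            length(targets), TRUE),
                              p_on_given_off = runif(length(targets)),
                              n_off_samples = 50L,
                              flagged_insufficient = FALSE)
      res <- suppressWarnings(simulate_tf_knockout(m, "TFr", probs, fva))
      expect_lte(res$growth_ratio, 1 + 1e-6)
      expect_gte(res$growth_ratio, 0)
    }
  }
})

test_that("condition-specific TFs obey the impact/neutral thresholds", {
  a <- tibble::tibble(tf = c("T1", "T2", "T3"),
                      growth_ratio = c(0.95, 0.99, 0.95))
  b <- tibble::tibble(tf = c("T1", "T2", "T3", "T4"),
                      growth_ratio = c(1.0, 1.0, 0.97, 0.5))
  sel <- specific_tfs(a, b, impact_threshold = 0.98,
                      neutral_threshold = 0.999)
  expect_equal(sel, "T1") # T2 not impaired, T3 impaired in both, T4 absent
})

test_that("identical inputs give bit-identical screen tables", {
  gem <- generate_toy_gem(n_chain = 3, seed = 11)
  reg <- toy_regulon_net()
  probs <- tibble::tibble(tf = reg$net$tf, target = reg$net$target,
                          sign = "activation",
                          p_on_given_off = reg$planted_p,
                          n_off_samples = 100L,
                          flagged_insufficient = FALSE)
  s1 <- suppressWarnings(screen_tf_knockouts(gem$model, probs))
  s2 <- suppressWarnings(screen_tf_knockouts(gem$model, probs))
  expect_identical(s1, s2)
})
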