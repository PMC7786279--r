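sim_expr <- function(n_genes = 500, n_per = 6, shift_genes = 0,
                     shift = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  m <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%d", 1:n_genes),
                              sprintf("s%d", 1:n)))
  if (shift_genes > 0)
    m[1:shift_genes, 1:n_per] <- m[1:shift_genes, 1:n_per] + shift
  m
}

test_that("moderated t matches limma's empirical-Bayes pipeline", {
  expect_true(requireNamespace("limma", quietly = TRUE))
  expr <- sim_expr(800, 6, shift_genes = 40, seed = 5)
  a <- sprintf("s%d", 1:6); b <- sprintf("s%d", 7:12)
  tab <- moderated_t_test(expr, a, b)
  design <- cbind(intercept = 1, groupA = rep(c(1, 0), each = 6))
  fit <- limma::eBayes(limma::lmFit(expr, design))
  expect_equal(attr(tab, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(tab, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(tab$t_moderated, unname(fit$t[, 2]), tolerance = 1e-9)
  expect_equal(tab$p, unname(fit$p.value[, 2]), tolerance = 1e-9)
  expect_equal(tab$log2_fc, unname(fit$coefficients[, 2]),
               tolerance = 1e-12)
})

test_that("prior df 0 reduces exactly to the ordinary two-sample t", {
  expr <- sim_expr(300, 5, seed = 9)
  a <- sprintf("s%d", 1:5); b <- sprintf("s%d", 6:10)
  tab <- moderated_t_test(expr, a, b, prior_df = 0)
  ref <- apply(expr, 1, function(x)
    stats::t.test(x[1:5], x[6:10], var.equal = TRUE)$statistic)
  expect_equal(tab$t_moderated, unname(ref), tolerance = 1e-9)
  expect_equal(unique(tab$df_total), 8)
})

test_that("infinite prior df shrinks to a single common variance", {
  expr <- sim_expr(200, 6, seed = 11)
  tab <- moderated_t_test(expr, sprintf("s%d", 1:6), sprintf("s%d", 7:12),
                          prior_df = Inf)
  # identical mean differences then give identical t
  se_implied <- tab$log2_fc / tab$t_moderated
  expect_lt(stats::sd(se_implied), 1e-12)
})

test_that("zero-variance genes are flagged and excluded from the prior", {
  expr <- sim_expr(100, 4, seed = 2)
  expr["g1", ] <- rep(c(3, 1), each = 4) # no within-group noise
  expr["g2", ] <- 2
  tab <- moderated_t_test(expr, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  expect_true(tab$zero_variance[tab$gene == "g1"])
  expect_equal(tab$t_moderated[tab$gene == "g1"], Inf)
  expect_equal(tab$p[tab$gene == "g1"], 0)
  expect_equal(tab$t_moderated[tab$gene == "g2"], 0)
  expect_equal(tab$p[tab$gene == "g2"], 1)
})

test_that("DEG selection applies |log2FC| and p thresholds by direction", {
  tab <- tibble::tibble(
    gene = c("up1", "weakfc", "down1", "highp"),
    log2_fc = c(1.2, 0.9, -1.5, 2.0),
    p = c(0.01, 0.001, 0.04, 0.2),
    p_adj = c(0.05, 0.01, 0.1, 0.4))
  sel <- select_degs(tab, lfc_min = 1, p_max = 0.05)
  expect_equal(sel$up, "up1")
  expect_equal(sel$down, "down1")
  # invariant to row order
  sel2 <- select_degs(tab[c(3, 1, 4, 2), ], lfc_min = 1, p_max = 0.05)
  expect_equal(sel2, sel)
  # adjusted-p filtering is stricter here
  sel3 <- select_degs(tab, use_adjusted = TRUE)
  expect_equal(sel3$down, character(0))
})

test_that("contrast intersection keeps concordant genes only", {
  ab <- list(up = c("g1", "g2"), down = c("d1", "d2"))
  ac <- list(up = c("g2", "g3"), down = c("d2", "g1"))
  res <- intersect_contrasts(ab, ac)
  expect_equal(res$up, "g2")
  expect_equal(res$down, "d2")
  expect_equal(res$conflicts, "g1")
  expect_true(all(res$up %in% ab$up) && all(res$up %in% ac$up))
})

test_that("BH adjustment preserves the p-value ordering", {
  expr <- sim_expr(400, 5, shift_genes = 30, seed = 21)
  tab <- moderated_t_test(expr, sprintf("s%d", 1:5), sprintf("s%d", 6:10))
  expect_true(all(tab$p_adj >= tab$p - 1e-15))
  # sorting by p sorts p_adj too (monotone step-up adjustment)
  expect_true(all(diff(tab$p_adj[order(tab$p)]) >= -1e-15))
})

test_that("hypergeometric enrichment equals exact tail enumeration", {
  universe <- sprintf("u%d", 1:100)
  set <- universe[1:10]
  query <- c(universe[1:5], universe[50:64]) # overlap 5, size 20
  res <- hypergeometric_enrichment(query, universe,
                                   list(mySet = set))
  # exact enumeration of P(X >= 5)
  enum <- sum(vapply(5:10, function(k)
    choose(10, k) * choose(90, 20 - k) / choose(100, 20), numeric(1)))
  expect_equal(res$p, enum, tolerance = 1e-12)

  # zero overlap is never significant
  res0 <- hypergeometric_enrichment(universe[50:59], universe,
                                    list(s = universe[1:10]))
  expect_gt(res0$p, 0.3)

  # query == set is the extreme case among same-size sets
  resx <- hypergeometric_enrichment(set, universe,
                                    list(exact = set,
                                         other = universe[11:20]))
  expect_lt(resx$p[resx$set == "exact"], resx$p[resx$set == "other"])
  expect_equal(resx$p[resx$set == "exact"],
               1 / choose(100, 10) * 1, tolerance = 1e-12)
  expect_error(hypergeometric_enrichment("a", character(), list(s = "a")),
               "universe")
})
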