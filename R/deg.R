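#' Empirical-Bayes moderated t-test between two groups
#'
#' Per gene, the two-group pooled residual variance s^2 (d = n_a + n_b - 2
#' df) is shrunk toward a prior (d0, s0^2) fitted by moment matching on
#' log s^2 (the scaled chi-square / log-F hierarchical model): the
#' posterior variance is (d0 s0^2 + d s^2) / (d0 + d) and the moderated t
#' uses d0 + d degrees of freedom. At d0 = 0 this is the ordinary
#' two-sample t; as d0 grows all genes share a common variance.
#'
#' Expression is assumed log2-scale, so `mean_a - mean_b` is the log2 fold
#' change. Genes with zero variance in both groups are excluded from the
#' prior fit and flagged with an infinite t (p = 0) when their means
#' differ, t = 0 otherwise.
#'
#' @param expr Numeric gene-by-sample matrix (log2 scale).
#' @param samples_a,samples_b Column names (or indices) of the two groups,
#'   each of size >= 2. `a` is the focal group: positive fold changes mean
#'   higher in `a`.
#' @param prior_df Optional override of the fitted prior df d0 (`0` gives
#'   the ordinary t; `Inf` full shrinkage to the common variance).
#' @return Tibble of class `deg_table`: `gene`, `mean_a`, `mean_b`,
#'   `log2_fc`, `s2`, `t_moderated`, `df_total`, `p`, `p_adj` (BH),
#'   `direction`; prior estimates in attributes `prior_df`, `prior_var`.
#' @export
moderated_t_test <- function(expr, samples_a, samples_b, prior_df = NULL) {
  A <- expr[, samples_a, drop = FALSE]
  B <- expr[, samples_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  stopifnot(na >= 2, nb >= 2)
  mean_a <- rowMeans(A)
  mean_b <- rowMeans(B)
  d <- na + nb - 2
  s2 <- (rowSums((A - mean_a)^2) + rowSums((B - mean_b)^2)) / d

  ok <- s2 > 0
  if (!any(ok)) stop("all genes have zero residual variance", call. = FALSE)
  fit <- fit_variance_prior(s2[ok], d)
  d0 <- if (is.null(prior_df)) fit$df_prior else prior_df
  s02 <- fit$var_prior

  # total df for the t reference, capped at the pooled residual df of
  # the whole experiment (the prior cannot add more information than
  # the data that estimated it)
  df_pool <- d * length(s2)
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- rep(df_pool, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- rep(d, length(s2))
  } else {
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
    df_total <- rep(min(d0 + d, df_pool), length(s2))
  }

  diff <- mean_a - mean_b
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- diff / se
  # zero-variance genes: no within-group noise at all
  t_mod[!ok] <- ifelse(diff[!ok] == 0, 0, sign(diff[!ok]) * Inf)
  p <- ifelse(is.finite(df_total),
              2 * stats::pt(-abs(t_mod), df_total),
              2 * stats::pnorm(-abs(t_mod)))
  p[!ok & diff != 0] <- 0
  p[!ok & diff == 0] <- 1

  out <- tibble::tibble(
    gene = rownames(expr), mean_a = unname(mean_a),
    mean_b = unname(mean_b), log2_fc = unname(diff), s2 = unname(s2),
    t_moderated = unname(t_mod), df_total = unname(df_total),
    p = unname(p), p_adj = stats::p.adjust(unname(p), method = "BH"),
    direction = unname(ifelse(diff >= 0, "up", "down")),
    zero_variance = unname(!ok))
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  class(out) <- c("deg_table", class(out))
  out
}

# Moment-matching fit of the inverse-chi-square variance prior on
# log(s^2): E[log s^2] and Var[log s^2] identify (d0, s0^2) through the
# digamma/trigamma moments of log chi-square variables.
fit_variance_prior <- function(s2, d) {
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  if (is.na(evar)) evar <- 0
  evar <- evar - trigamma(d / 2)
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no excess dispersion beyond sampling noise: variances are
    # exchangeable and the prior collapses to their plain mean
    df_prior <- Inf
    var_prior <- mean(s2)
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone,
# convex in 1/x), following the standard approach for this inversion.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Threshold-filter differential expression results
#'
#' Keeps genes with |log2 fold change| >= `lfc_min` and p-value (raw by
#' default) <= `p_max`, split by direction.
#'
#' @param table A `deg_table` from [moderated_t_test()].
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param p_max Maximum p-value (default 0.05).
#' @param use_adjusted Filter on the BH-adjusted p instead of the raw p
#'   (default `FALSE`).
#' @return List with character vectors `up` and `down` (sorted).
#' @export
select_degs <- function(table, lfc_min = 1, p_max = 0.05,
                        use_adjusted = FALSE) {
  p <- if (use_adjusted) table$p_adj else table$p
  keep <- abs(table$log2_fc) >= lfc_min & p <= p_max
  list(up = sort(table$gene[keep & table$log2_fc > 0]),
       down = sort(table$gene[keep & table$log2_fc < 0]))
}

#' Intersect the DEG sets of two contrasts sharing a focal class
#'
#' Genes called in the same direction in both contrasts (e.g. class 2 vs 1
#' and class 2 vs 3) are the focal class's signature; genes with opposite
#' directions in the two contrasts are excluded and reported.
#'
#' @param degs_ab,degs_ac Lists from [select_degs()], both with the focal
#'   class as group `a`.
#' @return List with `up`, `down`, and `conflicts` (genes discordant
#'   between contrasts).
#' @export
intersect_contrasts <- function(degs_ab, degs_ac) {
  up <- intersect(degs_ab$up, degs_ac$up)
  down <- intersect(degs_ab$down, degs_ac$down)
  conflicts <- sort(union(intersect(degs_ab$up, degs_ac$down),
                          intersect(degs_ab$down, degs_ac$up)))
  list(up = sort(up), down = sort(down), conflicts = conflicts)
}

#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric test P(X >= overlap) of a query gene list
#' against each named gene set within a fixed universe, BH-adjusted across
#' sets. Gene sets are intersected with the universe before testing.
#'
#' @param genes Query gene set (character), a subset of `universe`.
#' @param universe Background gene identifiers.
#' @param gene_sets Named list of character vectors.
#' @return Tibble: `set`, `set_size`, `overlap`, `p`, `p_adj`.
#' @export
hypergeometric_enrichment <- function(genes, universe, gene_sets) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  genes <- intersect(unique(genes), universe)
  res <- purrr::imap_dfr(gene_sets, function(set, name) {
    set <- intersect(unique(set), universe)
    ov <- length(intersect(genes, set))
    p <- stats::phyper(ov - 1, length(set),
                       length(universe) - length(set),
                       length(genes), lower.tail = FALSE)
    tibble::tibble(set = name, set_size = length(set),
                   overlap = ov, p = p)
  })
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  dplyr::arrange(res, .data$p)
}
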