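#' Binarize an expression matrix at a pooled quantile
#'
#' A single threshold — the given quantile of all finite values pooled
#' across genes and samples — splits every measurement into ON (strictly
#' above) or OFF. This is the standard preprocessing for estimating
#' P(target ON | TF OFF) in probabilistic regulation of metabolism.
#'
#' @param expr Numeric gene-by-sample matrix.
#' @param quantile Pooled quantile in `[0, 1]` (default 0.33).
#' @return A `binarized_expression`: list with `calls` (logical matrix,
#'   `TRUE` = ON), `threshold`, `quantile`.
#' @export
binarize_expression <- function(expr, quantile = 0.33) {
  stopifnot(is.matrix(expr), length(expr) > 0, quantile >= 0, quantile <= 1)
  vals <- expr[is.finite(expr)]
  if (max(vals) == min(vals))
    stop("degenerate expression: matrix is constant", call. = FALSE)
  thr <- stats::quantile(vals, quantile, names = FALSE)
  structure(list(calls = expr > thr, threshold = thr, quantile = quantile),
            class = "binarized_expression")
}

#' Estimate P(target ON | TF OFF) for every regulatory edge
#'
#' The conditional probability of each target gene being ON in the samples
#' where its TF is OFF — the quantity that scales flux bounds during a TF
#' knockout. Edges whose TF is OFF in fewer than `min_off_samples` samples
#' carry too little evidence and are assigned p = 1 (no constraint) with
#' `flagged_insufficient = TRUE`. Edges whose TF or target is not measured
#' are skipped with a warning.
#'
#' @param bin A [binarize_expression()] result.
#' @param net Edge tibble (`tf`, `target`, `sign`, ...).
#' @param min_off_samples Minimum number of TF-OFF samples (default 5).
#' @return Tibble with columns `tf`, `target`, `sign`, `p_on_given_off`,
#'   `n_off_samples`, `flagged_insufficient`.
#' @export
estimate_conditional_probabilities <- function(bin, net,
                                               min_off_samples = 5) {
  stopifnot(inherits(bin, "binarized_expression"))
  calls <- bin$calls
  measured <- net$tf %in% rownames(calls) & net$target %in% rownames(calls)
  if (any(!measured))
    warning(sum(!measured), " edges skipped: tf or target not measured",
            call. = FALSE)
  net <- net[measured, , drop = FALSE]
  res <- purrr::pmap(list(net$tf, net$target), function(tf, tg) {
    off <- !calls[tf, ]
    n_off <- sum(off)
    if (n_off < min_off_samples)
      return(c(p = 1, n = n_off, flag = 1))
    c(p = sum(calls[tg, off]) / n_off, n = n_off, flag = 0)
  })
  res <- do.call(rbind, res)
  tibble::tibble(tf = net$tf, target = net$target,
                 sign = if ("sign" %in% names(net)) net$sign else "unknown",
                 p_on_given_off = unname(res[, "p"]),
                 n_off_samples = as.integer(res[, "n"]),
                 flagged_insufficient = res[, "flag"] == 1)
}

#' Apply PROM-style constraints for one TF knockout
#'
#' For every reaction whose GPR involves a target of the TF, the reaction's
#' availability is re-evaluated with each regulated gene g at its
#' P(g ON | TF OFF); the resulting scale factor kappa tightens the bounds
#' to `kappa * Vmax` (upper, when Vmax > 0) and `kappa * Vmin` (lower,
#' when Vmin < 0), where Vmin/Vmax come from flux variability analysis of
#' the unconstrained model. Bounds only ever tighten.
#'
#' In `sign_aware` mode (default) inhibition edges do not constrain —
#' losing an inhibitor cannot starve its target — while activation and
#' unknown-sign edges do; `prom_pure` ignores signs, as classic PROM does.
#'
#' @param model A [metabolic_model()].
#' @param tf TF identifier.
#' @param probs Tibble from [estimate_conditional_probabilities()].
#' @param fva Tibble from [flux_variability()] on the unconstrained model.
#' @param sign_mode `"sign_aware"` or `"prom_pure"`.
#' @return Constrained copy of the model; attribute
#'   `n_constrained_reactions` counts reactions whose bounds changed.
#' @export
constrain_model_for_tf_knockout <- function(model, tf, probs, fva,
                                            sign_mode = c("sign_aware",
                                                          "prom_pure")) {
  sign_mode <- match.arg(sign_mode)
  pr <- probs[probs$tf == tf, , drop = FALSE]
  if (sign_mode == "sign_aware")
    pr <- pr[pr$sign != "inhibition", , drop = FALSE]
  pr <- pr[pr$target %in% model$gene_ids, , drop = FALSE]
  if (!nrow(pr)) {
    warning(sprintf("TF '%s' has no regulated targets in the model", tf),
            call. = FALSE)
    attr(model, "n_constrained_reactions") <- 0L
    return(model)
  }
  gene_vals <- stats::setNames(pr$p_on_given_off, pr$target)
  scale_bounds_by_activity(model, gene_vals, fva)
}

#' Tighten reaction bounds from continuous gene activities
#'
#' For every reaction whose GPR mentions a gene in `activity`, the rule is
#' evaluated with those genes at their activities (others at 1), giving a
#' scale factor kappa; the upper bound tightens to `kappa * Vmax` (when
#' Vmax > 0) and the lower to `kappa * Vmin` (when Vmin < 0). Bounds never
#' loosen. This is the shared constraint engine behind TF-knockout
#' simulation and activity-based per-class model construction.
#'
#' @param model A [metabolic_model()].
#' @param activity Named numeric vector of gene activities in `[0, 1]`.
#' @param fva Tibble from [flux_variability()] on the unconstrained model.
#' @return Constrained model copy with attribute
#'   `n_constrained_reactions`.
#' @export
scale_bounds_by_activity <- function(model, activity, fva) {
  vmin <- stats::setNames(fva$v_min, fva$reaction)
  vmax <- stats::setNames(fva$v_max, fva$reaction)
  n_changed <- 0L
  for (rid in names(model$reactions)) {
    g <- model$reactions[[rid]]$gpr
    if (is.null(g) || !any(gpr_genes(g) %in% names(activity))) next
    kappa <- evaluate_gpr(g, activity)
    if (kappa >= 1) next
    r <- model$reactions[[rid]]
    new_ub <- r$upper_bound
    new_lb <- r$lower_bound
    if (!is.na(vmax[rid]) && vmax[rid] > 0)
      new_ub <- min(r$upper_bound, kappa * vmax[rid])
    if (!is.na(vmin[rid]) && vmin[rid] < 0)
      new_lb <- max(r$lower_bound, kappa * vmin[rid])
    # a positive lower bound can cross a scaled-down upper bound; relax it
    # onto the new upper bound to keep the LP well-posed
    if (new_lb > new_ub) new_lb <- new_ub
    if (new_ub < r$upper_bound || new_lb > r$lower_bound) {
      model$reactions[[rid]]$upper_bound <- new_ub
      model$reactions[[rid]]$lower_bound <- new_lb
      n_changed <- n_changed + 1L
    }
  }
  attr(model, "n_constrained_reactions") <- n_changed
  model
}

#' Simulate a TF knockout and its growth impact
#'
#' Constrains the model per [constrain_model_for_tf_knockout()]; if the TF
#' itself appears in the model's GPRs it is additionally deleted as a
#' metabolic gene. Growth ratio is knockout optimum over wildtype optimum.
#'
#' @inheritParams constrain_model_for_tf_knockout
#' @return One-row tibble: `tf`, `growth_ratio`, `wildtype_growth`,
#'   `knockout_growth`, `n_constrained_reactions`.
#' @export
simulate_tf_knockout <- function(model, tf, probs, fva,
                                 sign_mode = "sign_aware") {
  wt <- optimize_growth(model)
  if (wt$status != "optimal" || wt$objective_value <= 1e-9)
    stop("model cannot grow: wildtype optimum is not positive", call. = FALSE)
  ko <- suppressWarnings(
    constrain_model_for_tf_knockout(model, tf, probs, fva, sign_mode))
  n_constrained <- attr(ko, "n_constrained_reactions")
  if (tf %in% model$gene_ids)
    ko <- apply_gene_knockout(ko, tf)
  res <- optimize_growth(ko)
  growth <- if (res$status == "optimal") max(0, res$objective_value) else 0
  tibble::tibble(tf = tf,
                 growth_ratio = growth / wt$objective_value,
                 wildtype_growth = wt$objective_value,
                 knockout_growth = growth,
                 n_constrained_reactions = n_constrained)
}

#' Screen a panel of TF knockouts
#'
#' Computes flux variability once on the unconstrained model and simulates
#' each TF knockout against it; results are sorted by increasing growth
#' ratio (most growth-limiting TF first).
#'
#' @param model A [metabolic_model()].
#' @param probs Tibble from [estimate_conditional_probabilities()].
#' @param tf_list TFs to screen (default: all TFs in `probs`).
#' @param sign_mode `"sign_aware"` or `"prom_pure"`.
#' @param objective_fraction FVA objective fraction for Vmax (default 0:
#'   the full feasible envelope).
#' @return Tibble of [simulate_tf_knockout()] rows, class `tf_screen`.
#' @export
screen_tf_knockouts <- function(model, probs, tf_list = NULL,
                                sign_mode = "sign_aware",
                                objective_fraction = 0) {
  if (is.null(tf_list)) tf_list <- sort(unique(probs$tf))
  fva <- flux_variability(model, objective_fraction)
  out <- purrr::map_dfr(tf_list, function(tf)
    simulate_tf_knockout(model, tf, probs, fva, sign_mode))
  out <- dplyr::arrange(out, .data$growth_ratio, .data$tf)
  class(out) <- c("tf_screen", class(out))
  out
}

#' TFs that selectively impair one condition
#'
#' Selects TFs whose knockout reduces growth below `impact_threshold` in
#' screen `results_a` while leaving growth at or above `neutral_threshold`
#' in screen `results_b` — e.g. TFs that only impair the poor-prognosis
#' class. TFs missing from either screen are excluded.
#'
#' @param results_a,results_b Screens from [screen_tf_knockouts()].
#' @param impact_threshold Growth ratio below which a knockout counts as
#'   impairing (default 0.98).
#' @param neutral_threshold Growth ratio at or above which a knockout
#'   counts as neutral (default 0.98).
#' @return Character vector of selected TFs.
#' @export
specific_tfs <- function(results_a, results_b, impact_threshold = 0.98,
                         neutral_threshold = 0.98) {
  shared <- intersect(results_a$tf, results_b$tf)
  ra <- stats::setNames(results_a$growth_ratio, results_a$tf)[shared]
  rb <- stats::setNames(results_b$growth_ratio, results_b$tf)[shared]
  sort(shared[ra < impact_threshold & rb >= neutral_threshold])
}
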