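#' Flux balance analysis: maximize growth
#'
#' Solves the linear program max c'v subject to S v = 0 and
#' `lower_bound <= v <= upper_bound`, with c the indicator of the model's
#' objective (biomass) reaction.
#'
#' @param model A [metabolic_model()].
#' @return A `flux_result`: list with `status` (`"optimal"` or
#'   `"infeasible"`), `objective_value`, and `fluxes` (named numeric over
#'   reactions; `NULL` unless optimal).
#' @export
optimize_growth <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  lp <- model_lp_parts(model)
  obj <- as.numeric(names(model$reactions) == model$objective_reaction)
  sol <- lp_solve(obj, lp$S, lp$b, lp$lb, lp$ub, maximize = TRUE)
  flux_result(sol, names(model$reactions))
}

model_lp_parts <- function(model) {
  S <- stoichiometric_matrix(model)
  if (nrow(S) == 0L) S <- NULL
  list(S = S,
       b = if (is.null(S)) numeric() else rep(0, nrow(S)),
       lb = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
       ub = vapply(model$reactions, `[[`, numeric(1), "upper_bound"))
}

flux_result <- function(sol, rxn_ids) {
  fluxes <- NULL
  if (identical(sol$status, "optimal")) {
    fluxes <- sol$x
    names(fluxes) <- rxn_ids
  }
  structure(list(status = sol$status,
                 objective_value = if (identical(sol$status, "optimal"))
                   sol$value else NA_real_,
                 fluxes = fluxes),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> status: %s, objective: %s\n", x$status,
              format(x$objective_value, digits = 6)))
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux compatible with steady
#' state, the bounds, and an objective flux at least
#' `objective_fraction` times the FBA optimum.
#'
#' @param model A [metabolic_model()].
#' @param objective_fraction Fraction of the optimal growth that must be
#'   maintained, in `[0, 1]`. 0 explores the full feasible envelope.
#' @param reactions Reaction identifiers to scan (default: all).
#' @return Tibble with columns `reaction`, `v_min`, `v_max`.
#' @export
flux_variability <- function(model, objective_fraction = 0,
                             reactions = NULL) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  wt <- optimize_growth(model)
  if (wt$status != "optimal")
    stop("flux variability requires a feasible base model", call. = FALSE)
  if (is.null(reactions)) reactions <- names(model$reactions)

  obj_id <- model$objective_reaction
  floor_v <- objective_fraction * wt$objective_value
  m2 <- set_bounds(model, obj_id,
                   lower = max(model$reactions[[obj_id]]$lower_bound, floor_v))
  lp <- model_lp_parts(m2)
  ids <- names(m2$reactions)

  rng <- vapply(reactions, function(rid) {
    obj <- as.numeric(ids == rid)
    lo <- lp_solve(obj, lp$S, lp$b, lp$lb, lp$ub, maximize = FALSE)
    hi <- lp_solve(obj, lp$S, lp$b, lp$lb, lp$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop(sprintf("FVA subproblem infeasible for reaction '%s'", rid),
           call. = FALSE)
    c(lo$value, hi$value)
  }, numeric(2))

  tibble::tibble(reaction = reactions,
                 v_min = unname(rng[1, ]), v_max = unname(rng[2, ]))
}

#' Delete genes from a model
#'
#' Evaluates every GPR with the knocked-out genes at 0 and all others at 1;
#' reactions whose rule evaluates to 0 have both bounds set to 0. Returns a
#' modified copy; the input is unchanged.
#'
#' @param model A [metabolic_model()].
#' @param genes Character vector of gene identifiers to delete.
#' @return The knockout model.
#' @export
apply_gene_knockout <- function(model, genes) {
  missing <- setdiff(genes, model$gene_ids)
  if (length(missing))
    warning("genes absent from the model ignored: ",
            paste(missing, collapse = ", "), call. = FALSE)
  vals <- stats::setNames(rep(0, length(genes)), genes)
  for (rid in names(model$reactions)) {
    g <- model$reactions[[rid]]$gpr
    if (is.null(g)) next
    if (!any(gpr_genes(g) %in% genes)) next
    if (evaluate_gpr(g, vals) == 0) {
      model$reactions[[rid]]$lower_bound <- 0
      model$reactions[[rid]]$upper_bound <- 0
    }
  }
  model
}

#' Single-gene-deletion essentiality screen
#'
#' Knocks out each gene in turn and reports the ratio of knockout to
#' wildtype optimal growth, clamped to be nonnegative; an infeasible
#' knockout model reads as lethal (ratio 0).
#'
#' @param model A [metabolic_model()] with wildtype growth > 1e-9.
#' @return Tibble with columns `gene`, `growth_ratio`, carrying the
#'   wildtype growth as attribute `wildtype_growth`.
#' @export
single_gene_deletion_screen <- function(model) {
  wt <- optimize_growth(model)
  if (wt$status != "optimal" || wt$objective_value <= 1e-9)
    stop("model cannot grow: wildtype optimum is not positive", call. = FALSE)

  ratios <- vapply(model$gene_ids, function(g) {
    ko <- suppressWarnings(apply_gene_knockout(model, g))
    # no reaction disabled => LP unchanged => ratio exactly 1
    if (identical(reaction_bounds(ko), reaction_bounds(model))) return(1)
    res <- optimize_growth(ko)
    if (res$status != "optimal") return(0)
    max(0, res$objective_value / wt$objective_value)
  }, numeric(1))

  out <- tibble::tibble(gene = model$gene_ids,
                        growth_ratio = unname(ratios))
  attr(out, "wildtype_growth") <- wt$objective_value
  out
}

#' Parsimonious flux distribution (pFBA)
#'
#' Among flux vectors attaining at least `optimality_fraction` of the
#' optimal growth, returns one minimizing total absolute flux. Plain FBA
#' flux vectors are degenerate; the parsimonious solution gives a
#' reproducible representative for cross-sample flux comparison.
#'
#' @param model A [metabolic_model()].
#' @param optimality_fraction Required fraction of optimal growth
#'   (default 0.999).
#' @return A `flux_result` whose `objective_value` is the growth attained;
#'   attribute `total_flux` holds the minimized sum of absolute fluxes.
#' @export
parsimonious_fluxes <- function(model, optimality_fraction = 0.999) {
  wt <- optimize_growth(model)
  if (wt$status != "optimal")
    return(flux_result(list(status = wt$status), names(model$reactions)))

  obj_id <- model$objective_reaction
  m2 <- set_bounds(model, obj_id,
                   lower = max(model$reactions[[obj_id]]$lower_bound,
                               optimality_fraction * wt$objective_value))
  lp <- model_lp_parts(m2)
  n <- length(m2$reactions)
  # split v = p - n with p, q >= 0; minimize sum(p + q)
  lb_p <- pmax(0, lp$lb); ub_p <- pmax(0, lp$ub)
  lb_q <- pmax(0, -lp$ub); ub_q <- pmax(0, -lp$lb)
  A <- if (is.null(lp$S)) NULL else cbind(lp$S, -lp$S)
  sol <- lp_solve(obj = rep(1, 2 * n), A = A, b = lp$b,
                  lb = c(lb_p, lb_q), ub = c(ub_p, ub_q), maximize = FALSE)
  if (sol$status != "optimal")
    return(flux_result(list(status = "infeasible"), names(model$reactions)))
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  out <- flux_result(list(status = "optimal", x = v,
                          value = v[which(names(m2$reactions) == obj_id)]),
                     names(m2$reactions))
  attr(out, "total_flux") <- sum(abs(v))
  out
}
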