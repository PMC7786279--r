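#' Construct a reaction
#'
#' A reaction couples metabolites through fixed stoichiometric coefficients
#' and carries flux bounds (mmol/gDW/h) plus an optional gene-protein-reaction
#' (GPR) rule gating its availability.
#'
#' @param id Reaction identifier (character scalar).
#' @param stoichiometry Named numeric vector, metabolite -> coefficient
#'   (negative = consumed, positive = produced). May be empty for exchange
#'   reactions, which exchange mass with the environment.
#' @param lower_bound,upper_bound Flux bounds; `lower_bound <= upper_bound`.
#' @param gpr A GPR tree from [parse_gpr()], a rule string, or `NULL` for a
#'   reaction that is not gene-gated.
#' @return An object of class `rxn`.
#' @export
reaction <- function(id, stoichiometry = numeric(), lower_bound = -1000,
                     upper_bound = 1000, gpr = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) && is.null(names(stoichiometry)))
    stop("stoichiometry must be a named numeric vector", call. = FALSE)
  if (lower_bound > upper_bound)
    stop(sprintf("reaction '%s': lower_bound > upper_bound", id), call. = FALSE)
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  structure(
    list(id = id, stoichiometry = stoichiometry,
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound), gpr = gpr),
    class = "rxn"
  )
}

#' Construct a constraint-based metabolic model
#'
#' The model holds the stoichiometric matrix S implicitly through its
#' reactions; flux balance analysis solves max c'v subject to S v = 0 and
#' per-reaction bounds, with the biomass pseudo-reaction as the objective.
#'
#' @param reactions List of [reaction()] objects.
#' @param objective Identifier of the objective (biomass) reaction; must be
#'   one of the reactions.
#' @param id Model identifier.
#' @return An object of class `metabolic_model` with fields `id`,
#'   `reactions` (named list), `metabolites`, `objective_reaction`,
#'   `gene_ids`.
#' @export
metabolic_model <- function(reactions, objective, id = "model") {
  stopifnot(is.list(reactions), length(reactions) > 0L)
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate reaction identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(reactions) <- ids
  if (!objective %in% ids)
    stop(sprintf("objective reaction '%s' not among the model's reactions",
                 objective), call. = FALSE)
  mets <- sort(unique(unlist(lapply(reactions,
                                    function(r) names(r$stoichiometry)))))
  genes <- sort(unique(unlist(lapply(reactions,
                                     function(r) gpr_genes(r$gpr)))))
  structure(
    list(id = id, reactions = reactions,
         metabolites = if (is.null(mets)) character() else mets,
         objective_reaction = objective,
         gene_ids = if (is.null(genes)) character() else genes),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "<metabolic_model '%s'>: %d reactions, %d metabolites, %d genes; objective: %s\n",
    x$id, length(x$reactions), length(x$metabolites), length(x$gene_ids),
    x$objective_reaction))
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model A [metabolic_model()].
#' @return Dense numeric matrix, one row per metabolite, one column per
#'   reaction, in the model's metabolite/reaction order.
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- matrix(0, nrow = length(model$metabolites),
              ncol = length(model$reactions),
              dimnames = list(model$metabolites, names(model$reactions)))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    if (length(st)) S[names(st), j] <- st
  }
  S
}

#' Flux bounds of a model as a tibble
#'
#' @param model A [metabolic_model()].
#' @return Tibble with columns `reaction`, `lower_bound`, `upper_bound`.
#' @export
reaction_bounds <- function(model) {
  tibble::tibble(
    reaction = names(model$reactions),
    lower_bound = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
    upper_bound = vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  )
}

#' Replace the bounds of one reaction (returns a modified copy)
#' @param model A [metabolic_model()].
#' @param rxn_id Reaction identifier.
#' @param lower,upper New bounds; `NULL` keeps the current value.
#' @return The modified model.
#' @export
set_bounds <- function(model, rxn_id, lower = NULL, upper = NULL) {
  stopifnot(rxn_id %in% names(model$reactions))
  if (!is.null(lower)) model$reactions[[rxn_id]]$lower_bound <- lower
  if (!is.null(upper)) model$reactions[[rxn_id]]$upper_bound <- upper
  model
}
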