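# Test helpers: random model corpus and independent LP oracle.
#
# The oracle solves every LP with scipy.optimize.linprog (HiGHS) through
# the system python, batched into a single subprocess call per test, with
# a formulation (free variables with native bounds, |v| handled by
# auxiliary t >= +/-v rows) independent of the package's shifted x >= 0
# formulation.

scipy_available <- function() {
  nzchar(Sys.which("python")) &&
    system2("python", c("-c", "import scipy.optimize"),
            stdout = FALSE, stderr = FALSE) == 0
}

# instances: list of list(obj, A_eq, b_eq, A_ub, b_ub, lb, ub, maximize)
# (A_eq/A_ub may be NULL); returns objective values (NA = infeasible)
scipy_lp_batch <- function(instances) {
  payload <- lapply(instances, function(it) list(
    obj = as.numeric(it$obj),
    A_eq = if (is.null(it$A_eq)) NULL else unname(as.matrix(it$A_eq)),
    b_eq = if (is.null(it$A_eq)) NULL else as.numeric(it$b_eq),
    A_ub = if (is.null(it$A_ub)) NULL else unname(as.matrix(it$A_ub)),
    b_ub = if (is.null(it$A_ub)) NULL else as.numeric(it$b_ub),
    lb = as.numeric(it$lb), ub = as.numeric(it$ub),
    maximize = isTRUE(it$maximize)))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("instances = json.load(open(%s))", deparse(fin)),
    "out = []",
    "for it in instances:",
    "    c = np.array(it['obj'], dtype=float)",
    "    sign = -1.0 if it['maximize'] else 1.0",
    "    def arr(key):",
    "        v = it.get(key)",
    "        return None if v is None else np.atleast_2d(np.array(v, dtype=float))",
    "    def vec(key):",
    "        v = it.get(key)",
    "        return None if v is None else np.atleast_1d(np.array(v, dtype=float))",
    "    r = linprog(sign * c, A_eq=arr('A_eq'), b_eq=vec('b_eq'),",
    "                A_ub=arr('A_ub'), b_ub=vec('b_ub'),",
    "                bounds=list(zip(it['lb'], it['ub'])), method='highs')",
    "    out.append(sign * r.fun if r.status == 0 else None)",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(fout))),
    script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  vals <- jsonlite::read_json(fout, simplifyVector = FALSE)
  vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
         numeric(1))
}

model_lp_data <- function(model) {
  list(S = stoichiometric_matrix(model),
       lb = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
       ub = vapply(model$reactions, `[[`, numeric(1), "upper_bound"))
}

# FBA LP as an oracle instance (optionally different objective/sense)
lp_instance <- function(model, obj_rxn = model$objective_reaction,
                        maximize = TRUE) {
  d <- model_lp_data(model)
  list(obj = as.numeric(names(model$reactions) == obj_rxn),
       A_eq = d$S, b_eq = rep(0, nrow(d$S)),
       lb = d$lb, ub = d$ub, maximize = maximize)
}

# pFBA oracle: variables [v; t], min sum t, S v = 0, v - t <= 0,
# -v - t <= 0, with the growth floor already fixed into the bounds
pfba_instance <- function(model) {
  d <- model_lp_data(model)
  n <- length(d$lb)
  tmax <- pmax(abs(d$lb), abs(d$ub))
  list(obj = c(rep(0, n), rep(1, n)),
       A_eq = cbind(d$S, matrix(0, nrow(d$S), n)),
       b_eq = rep(0, nrow(d$S)),
       A_ub = rbind(cbind(diag(n), -diag(n)),
                    cbind(-diag(n), -diag(n))),
       b_ub = rep(0, 2 * n),
       lb = c(d$lb, rep(0, n)), ub = c(d$ub, tmax),
       maximize = FALSE)
}

# random growing toy model: the generator's chain/isozyme/parallel GEM
# plus random extra reactions (lower bounds <= 0, so wildtype growth is
# preserved) carrying random GPRs
random_toy_model <- function(seed) {
  set.seed(seed)
  base <- generate_toy_gem(n_chain = sample(2:4, 1),
                           n_isozyme_pairs = sample(1:2, 1),
                           n_parallel = sample(0:2, 1),
                           exchange_bound = round(runif(1, 2, 15), 2),
                           seed = seed)
  m <- base$model
  genes_pool <- c(m$gene_ids, paste0("gx", 1:3))
  rxns <- unname(m$reactions)
  for (i in seq_len(sample(1:4, 1))) {
    pair <- sample(m$metabolites, 2)
    st <- stats::setNames(c(-1, 1), pair)
    lbs <- sample(c(-round(runif(1, 0, 20), 2), 0), 1)
    ubs <- round(runif(1, 0, 20), 2)
    gp <- if (runif(1) < 0.6)
      paste(sample(genes_pool, sample(1:2, 1)),
            collapse = sample(c(" and ", " or "), 1)) else NULL
    rxns <- c(rxns, list(reaction(sprintf("R_extra%d", i), st, lbs, ubs,
                                  gpr = gp)))
  }
  metabolic_model(rxns, m$objective_reaction, id = sprintf("rand%d", seed))
}

# growth-floored copy of a model (for FVA/pFBA oracle construction)
with_growth_floor <- function(model, fraction, optimum) {
  set_bounds(model, model$objective_reaction,
             lower = max(model$reactions[[model$objective_reaction]]$lower_bound,
                         fraction * optimum))
}
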