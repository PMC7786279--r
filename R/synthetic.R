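#' Generate a toy genome-scale metabolic model with known ground truth
#'
#' Builds an exchange-fed linear pathway into a biomass sink, with every
#' single-gene chain step essential, one two-subunit enzyme complex (AND:
#' both genes essential), `n_isozyme_pairs` OR-gated steps (isozymes,
#' individually dispensable) and `n_parallel` segments carried by two
#' redundant parallel reactions (each gene dispensable). The optimal
#' growth equals the limiting exchange bound.
#'
#' @param n_chain Number of single-gene chain steps (>= 2).
#' @param n_isozyme_pairs Number of OR-isozyme steps (default 1).
#' @param n_parallel Number of redundant parallel segments (default 1).
#' @param exchange_bound Upper bound of the feeding exchange (default 10).
#' @param seed Integer seed (construction is deterministic; the seed is
#'   recorded in the truth object).
#' @param sbml_path Optional path; when given the model is also written as
#'   SBML.
#' @return List with `model` ([metabolic_model()]) and `truth` (list:
#'   `essential_genes`, `nonessential_genes`, `optimal_growth`,
#'   `limiting_reaction`, `seed`).
#' @export
generate_toy_gem <- function(n_chain = 3, n_isozyme_pairs = 1,
                             n_parallel = 1, exchange_bound = 10,
                             seed = 1L, sbml_path = NULL) {
  stopifnot(n_chain >= 2)
  steps <- list()
  essential <- character()
  nonessential <- character()
  for (i in seq_len(n_chain)) {
    g <- sprintf("gchain%d", i)
    steps <- c(steps, list(list(id = sprintf("R_chain%d", i), gpr = g)))
    essential <- c(essential, g)
  }
  ga <- "gcplx_a"; gb <- "gcplx_b"
  steps <- c(steps, list(list(id = "R_complex",
                              gpr = sprintf("%s and %s", ga, gb))))
  essential <- c(essential, ga, gb)
  for (i in seq_len(n_isozyme_pairs)) {
    g1 <- sprintf("giso%d_a", i); g2 <- sprintf("giso%d_b", i)
    steps <- c(steps, list(list(id = sprintf("R_iso%d", i),
                                gpr = sprintf("%s or %s", g1, g2))))
    nonessential <- c(nonessential, g1, g2)
  }

  rxns <- list(reaction("EX_in", c(M1 = 1), 0, exchange_bound))
  met <- 1L
  for (s in steps) {
    rxns <- c(rxns, list(reaction(
      s$id,
      stats::setNames(c(-1, 1), c(sprintf("M%d", met),
                                  sprintf("M%d", met + 1L))),
      0, 1000, gpr = s$gpr)))
    met <- met + 1L
  }
  for (i in seq_len(n_parallel)) {
    g1 <- sprintf("gpar%d_a", i); g2 <- sprintf("gpar%d_b", i)
    st <- stats::setNames(c(-1, 1), c(sprintf("M%d", met),
                                      sprintf("M%d", met + 1L)))
    rxns <- c(rxns, list(reaction(sprintf("R_par%d_a", i), st, 0, 1000,
                                  gpr = g1),
                         reaction(sprintf("R_par%d_b", i), st, 0, 1000,
                                  gpr = g2)))
    nonessential <- c(nonessential, g1, g2)
    met <- met + 1L
  }
  rxns <- c(rxns, list(reaction("R_biomass",
                                stats::setNames(-1, sprintf("M%d", met)),
                                0, 1000)))
  model <- metabolic_model(rxns, objective = "R_biomass", id = "toy_gem")
  truth <- list(essential_genes = essential,
                nonessential_genes = nonessential,
                optimal_growth = exchange_bound,
                limiting_reaction = "EX_in", seed = as.integer(seed))
  if (!is.null(sbml_path)) write_sbml_model(model, sbml_path)
  list(model = model, truth = truth)
}

#' Simulate an expression cohort with planted regulons, classes and
#' survival
#'
#' Gene states are planted as exact empirical frequencies: each TF is OFF
#' in `round(tf_off_rate * n)` randomly chosen samples; among those, each
#' target is ON in exactly `round(p * n_off)` samples (its planted
#' conditional probability), and in `round(p_on_given_on * n_on)` of the
#' TF-ON samples. Continuous levels are a two-component Gaussian: OFF
#' level `baseline`, ON level `baseline + effect_size * noise_sd`, noise
#' sd `noise_sd` — so the planted probabilities are recoverable up to
#' rounding once expression is binarized. Latent classes add a mean shift
#' of the same size on class-specific signature genes; survival is
#' exponential with class-specific hazards under uniform censoring tuned
#' to the requested censoring fraction.
#'
#' @param net Edge tibble (`tf`, `target`, ...); one regulator per target
#'   is assumed (later duplicates of a target are dropped with a warning).
#' @param planted_p Numeric vector of planted P(target ON | TF OFF), one
#'   per edge of `net` (recycled if scalar).
#' @param n_samples Number of samples (>= 10 per class).
#' @param n_classes Number of latent classes (default 3).
#' @param effect_size ON/OFF and class-shift separation in units of
#'   `noise_sd` (default 5).
#' @param noise_sd Gaussian noise sd (default 1).
#' @param n_class_genes Signature genes per class (default 30).
#' @param n_background Unstructured background genes (default 50).
#' @param tf_off_rate Fraction of samples with each TF OFF (default 0.4).
#' @param p_on_given_on P(target ON | TF ON) (default 0.9).
#' @param baseline OFF-state mean expression, log2-like scale (default 5).
#' @param hazards Per-class event rates (1/day). Default: baseline
#'   0.002/day with multipliers 1, 3, 1.5, ... (class 2 is the
#'   poor-prognosis class).
#' @param censor_frac Expected fraction censored (default 0.3).
#' @param seed Integer seed.
#' @return List with `expr` (gene x sample matrix), `clinical` (tibble:
#'   `sample`, `time`, `event`, `class_label`) and `truth` (list:
#'   `class_assignments`, `planted_edges`, `signature_genes`, `hazards`,
#'   `on_states`, `off_rate_overall`, `seed`).
#' @export
simulate_expression_cohort <- function(net, planted_p, n_samples,
                                       n_classes = 3, effect_size = 5,
                                       noise_sd = 1, n_class_genes = 30,
                                       n_background = 50,
                                       tf_off_rate = 0.4,
                                       p_on_given_on = 0.9, baseline = 5,
                                       hazards = NULL, censor_frac = 0.3,
                                       seed = 1L) {
  stopifnot(n_samples >= 10 * n_classes)
  set.seed(seed)
  planted_p <- rep_len(planted_p, nrow(net))
  dup <- duplicated(net$target)
  if (any(dup)) {
    warning(sum(dup), " duplicate-target edges dropped by the generator",
            call. = FALSE)
    planted_p <- planted_p[!dup]
    net <- net[!dup, , drop = FALSE]
  }
  tfs <- unique(net$tf)
  targets <- net$target
  sig_genes <- lapply(seq_len(n_classes), function(k)
    sprintf("Gclass%d_%d", k, seq_len(n_class_genes)))
  bg_genes <- sprintf("Gbg_%d", seq_len(n_background))
  genes <- unique(c(tfs, targets, unlist(sig_genes), bg_genes))
  samples <- sprintf("S%03d", seq_len(n_samples))

  # exact-count ON/OFF planting
  on <- matrix(FALSE, length(genes), n_samples,
               dimnames = list(genes, samples))
  n_off <- round(tf_off_rate * n_samples)
  for (tf in tfs) {
    off_idx <- sample(n_samples, n_off)
    on[tf, -off_idx] <- TRUE
    kids <- which(net$tf == tf)
    for (e in kids) {
      tg <- net$target[e]
      k_off <- round(planted_p[e] * n_off)
      k_on <- round(p_on_given_on * (n_samples - n_off))
      on[tg, sample(off_idx, k_off)] <- TRUE
      on[tg, sample(setdiff(seq_len(n_samples), off_idx), k_on)] <- TRUE
    }
  }
  for (g in bg_genes)
    on[g, sample(n_samples, round((1 - tf_off_rate) * n_samples))] <- TRUE

  cls <- sample(rep(seq_len(n_classes), length.out = n_samples))
  for (k in seq_len(n_classes))
    on[sig_genes[[k]], cls == k] <- TRUE

  expr <- baseline + on * (effect_size * noise_sd) +
    matrix(stats::rnorm(length(on), sd = noise_sd), nrow(on), ncol(on))
  dimnames(expr) <- dimnames(on)

  if (is.null(hazards)) {
    mult <- c(1, 3, 1.5, rep(2, max(0, n_classes - 3)))[seq_len(n_classes)]
    hazards <- 0.002 * mult
  }
  rate <- hazards[cls]
  t_event <- stats::rexp(n_samples, rate)
  # uniform censoring horizon solving (1 - exp(-x)) / x = censor_frac
  # per class (x = hazard * horizon)
  horizon <- vapply(hazards, function(h) {
    if (censor_frac <= 0) return(Inf)
    x <- stats::uniroot(function(x) (1 - exp(-x)) / x - censor_frac,
                        c(1e-8, 1e4))$root
    x / h
  }, numeric(1))
  t_cens <- stats::runif(n_samples, 0, horizon[cls])
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  clinical <- tibble::tibble(sample = samples,
                             time = pmax(time, 1e-3), event = event,
                             class_label = sprintf("Class%d", cls))
  truth <- list(
    class_assignments = stats::setNames(sprintf("Class%d", cls), samples),
    planted_edges = tibble::tibble(tf = net$tf, target = net$target,
                                   p = planted_p),
    signature_genes = stats::setNames(sig_genes,
                                      sprintf("Class%d",
                                              seq_len(n_classes))),
    hazards = hazards, on_states = on,
    off_rate_overall = mean(!on), seed = as.integer(seed))
  list(expr = expr, clinical = clinical, truth = truth)
}

#' Toy regulon network matched to [generate_toy_gem()]
#'
#' TFs with graded planted probabilities, each gating the single gene of
#' one chain step (every chain step is growth-limiting in series, so a
#' knockout of the i-th TF caps growth at its planted probability times
#' the wildtype optimum), plus a TF with planted probability 1 whose
#' knockout is inert.
#'
#' @param planted Named numeric vector: TF name -> planted
#'   P(target ON | TF OFF) on successive chain genes. The last entry gates
#'   a chain gene too when its p < 1; entries with p = 1 are attached to
#'   the first non-essential isozyme gene. Default
#'   `c(TF_lethal = 0, TF_quarter = 0.25, TF_half = 0.5, TF_inert = 1)`
#'   needs a toy GEM with `n_chain >= 3`.
#' @return List with `net` (edge tibble) and `planted_p` (per edge).
#' @export
toy_regulon_net <- function(planted = c(TF_lethal = 0, TF_quarter = 0.25,
                                        TF_half = 0.5, TF_inert = 1)) {
  gating <- names(planted)[planted < 1]
  inert <- names(planted)[planted >= 1]
  targets <- c(sprintf("gchain%d", seq_along(gating)),
               rep("giso1_a", length(inert)))
  net <- tibble::tibble(tf = c(gating, inert),
                        target = targets,
                        sign = "activation",
                        confidence = "standard",
                        source_tag = "synthetic")
  list(net = net, planted_p = unname(planted[c(gating, inert)]))
}

#' Write a self-contained synthetic fixture bundle
#'
#' Generates the toy metabolic model, regulon edge list, expression
#' cohort, clinical table and machine-readable ground truth, and writes
#' them as plain-text files (`model.xml`, `expr.tsv`, `edges.tsv`,
#' `clinical.tsv`, `truth.json`).
#'
#' @param dir Output directory (created if missing).
#' @param scale `"tiny"` (30 samples; seconds) or `"demo"` (200 samples).
#' @param seed Integer master seed.
#' @return Invisibly, a list with the generated objects and `files`.
#' @export
write_fixture_bundle <- function(dir, scale = c("tiny", "demo"),
                                 seed = 1L) {
  scale <- match.arg(scale)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_samples <- if (scale == "tiny") 30L else 200L
  gem <- generate_toy_gem(seed = seed,
                          sbml_path = file.path(dir, "model.xml"))
  reg <- toy_regulon_net()
  cohort <- simulate_expression_cohort(reg$net, reg$planted_p, n_samples,
                                       seed = seed + 1L)
  files <- c(model = file.path(dir, "model.xml"),
             expr = file.path(dir, "expr.tsv"),
             edges = file.path(dir, "edges.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_matrix(cohort$expr, files["expr"])
  write_network_edges(reg$net, files["edges"])
  write_clinical_table(cohort$clinical, files["clinical"])
  truth <- c(gem["truth"], list(cohort = cohort$truth[
    setdiff(names(cohort$truth), "on_states")]))
  truth$cohort$planted_edges <- as.data.frame(truth$cohort$planted_edges)
  # named vectors must become JSON objects, not bare arrays
  truth$cohort$class_assignments <-
    as.list(truth$cohort$class_assignments)
  truth$cohort$hazards <- as.numeric(truth$cohort$hazards)
  jsonlite::write_json(truth, files["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(gem = gem, net = reg$net, planted_p = reg$planted_p,
                 cohort = cohort, files = files))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 = identical partitions, ~0 = random agreement.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
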