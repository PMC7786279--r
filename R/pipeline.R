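#' Validate and default-fill a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a plain list. Unknown keys are
#' rejected; thresholds are range-checked. Defaults: binarization quantile
#' 0.33, sign-aware constraint mode, NMF ranks 2:10 with 200 runs,
#' |log2FC| >= 1 at p <= 0.05 for DEGs, growth-ratio impact/neutral
#' thresholds 0.98, essentiality cutoff 0.01 with "at least half"
#' consensus, zero-flux epsilon 1e-6.
#'
#' @param config Path to a YAML or JSON config file, or a named list.
#' @return A validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    model = NULL, expr = NULL, edges = NULL, edges_b = NULL,
    clinical = NULL,
    quantile = 0.33, sign_mode = "sign_aware", min_off_samples = 5,
    ranks = 2:10, n_runs = 200L, nmf_max_iter = 500L, nmf_tol = 1e-5,
    lfc_min = 1, p_max = 0.05, use_adjusted = FALSE,
    impact_threshold = 0.98, neutral_threshold = 0.98,
    essential_cutoff = 0.01, min_fraction = 0.5, epsilon = 1e-6,
    majority = 0.5, poor_class = NULL, nmf_genes = "all", seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (is.character(cfg$ranks) && grepl(":", cfg$ranks)) {
    parts <- as.integer(strsplit(cfg$ranks, ":")[[1]])
    cfg$ranks <- seq(parts[1], parts[2])
  }
  check_range <- function(key, lo, hi) {
    v <- cfg[[key]]
    if (!is.numeric(v) || any(v < lo) || any(v > hi))
      stop(sprintf("config key '%s' out of range [%g, %g]", key, lo, hi),
           call. = FALSE)
  }
  check_range("quantile", 0, 1)
  check_range("min_fraction", 0, 1)
  check_range("majority", 0, 1)
  check_range("p_max", 0, 1)
  check_range("essential_cutoff", 0, 1)
  check_range("impact_threshold", 0, 2)
  check_range("neutral_threshold", 0, 2)
  check_range("lfc_min", 0, Inf)
  check_range("epsilon", 0, Inf)
  check_range("ranks", 2, 50)
  if (!cfg$sign_mode %in% c("sign_aware", "prom_pure"))
    stop("config key 'sign_mode' must be sign_aware or prom_pure",
         call. = FALSE)
  if (!cfg$nmf_genes %in% c("all", "network"))
    stop("config key 'nmf_genes' must be 'all' or 'network'",
         call. = FALSE)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the integrated regulatory-metabolic pipeline end to end
#'
#' Stages: read inputs -> merge/deduplicate the regulatory network ->
#' label edge signs by expression correlation -> binarize expression ->
#' estimate P(target ON | TF OFF) -> TF-knockout growth screen -> NMF
#' consensus stratification with rank selection -> Kaplan-Meier/log-rank
#' survival evaluation -> moderated-t DEGs of the poor-prognosis class
#' (intersection of its two pairwise contrasts) -> per-class essentiality
#' consensus -> four-type flux-reprogramming classification. Per-class
#' patient models are derived from the base model by scaling GPR-gated
#' bounds with within-class gene ON-frequencies
#' ([scale_bounds_by_activity()]).
#'
#' Every stage writes a TSV/JSON output under `out_dir`; `manifest.json`
#' records files, MD5 hashes, parameters and the seed. A stage failure
#' aborts with the stage name; earlier outputs are kept.
#'
#' @param config A [validate_config()] result (or something coercible).
#' @param out_dir Output directory for the report bundle.
#' @return Invisibly, a list with all stage results and `manifest`.
#' @export
run_full_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character()
  results <- list()
  stage <- function(name, file, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    outputs[[name]] <<- file
    results[[name]] <<- res
    res
  }
  pth <- function(f) file.path(out_dir, f)

  stage("config", "config.json", function() {
    jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                         pth("config.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    cfg
  })

  model <- read_sbml_model(cfg$model)
  expr <- read_expression_matrix(cfg$expr)

  net <- stage("network", "network.tsv", function() {
    net <- read_network_edges(cfg$edges)
    if (!is.null(cfg$edges_b))
      net <- merge_networks_consensus(net, read_network_edges(cfg$edges_b))
    write_network_edges(net, pth("network.tsv"))
    net
  })

  net <- stage("signed_network", "signed_network.tsv", function() {
    net <- sign_edges_by_correlation(net, expr)
    write_network_edges(net, pth("signed_network.tsv"))
    net
  })

  bin <- binarize_expression(expr, cfg$quantile)

  probs <- stage("probabilities", "probabilities.tsv", function() {
    pr <- suppressWarnings(
      estimate_conditional_probabilities(bin, net, cfg$min_off_samples))
    utils::write.table(as.data.frame(pr), pth("probabilities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pr
  })

  screen <- stage("tf_screen", "tf_screen.tsv", function() {
    sc <- suppressWarnings(
      screen_tf_knockouts(model, probs, sign_mode = cfg$sign_mode))
    utils::write.table(as.data.frame(sc), pth("tf_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sc
  })

  cc <- NULL
  metrics <- stage("rank_metrics", "rank_metrics.tsv", function() {
    panel <- if (cfg$nmf_genes == "network")
      unique(c(net$tf, net$target, model$gene_ids)) else NULL
    V <- prepare_nmf_input(expr, panel)
    cc <<- nmf_consensus_cluster(V, ranks = cfg$ranks, n_runs = cfg$n_runs,
                                 seed = cfg$seed,
                                 max_iter = cfg$nmf_max_iter,
                                 tol = cfg$nmf_tol)
    m <- consensus_metrics(cc)
    utils::write.table(as.data.frame(m), pth("rank_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    m
  })

  classes <- stage("classes", "classes.tsv", function() {
    best <- select_rank(metrics)
    labels <- cc[[as.character(best)]]$labels
    cl <- tibble::tibble(sample = names(labels),
                         class = sprintf("Class%d", labels))
    utils::write.table(as.data.frame(cl), pth("classes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cl
  })

  surv <- stage("survival", "survival.json", function() {
    clinical <- read_clinical_table(cfg$clinical)
    cl <- dplyr::inner_join(clinical, classes, by = "sample")
    if (!nrow(cl)) stop("no overlap between clinical and expression samples")
    km <- kaplan_meier(cl, cl$class)
    lr <- logrank_test(cl, cl$class)
    jsonlite::write_json(
      list(chi_square = lr$chi_square, df = lr$df, p_value = lr$p_value,
           n_per_class = as.list(table(cl$class))),
      pth("survival.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(km = km, logrank = lr, merged = cl)
  })

  poor <- cfg$poor_class
  if (is.null(poor)) {
    # poor-prognosis class: highest naive event rate per unit follow-up
    cl <- surv$merged
    rates <- tapply(cl$event, cl$class, sum) /
      tapply(cl$time, cl$class, sum)
    poor <- names(which.max(rates))
  }

  degs <- stage("degs", "degs.tsv", function() {
    by_class <- split(classes$sample, classes$class)
    others <- setdiff(names(by_class), poor)
    expr_cols <- intersect(unlist(by_class), colnames(expr))
    contrasts <- lapply(others, function(o) {
      tab <- moderated_t_test(expr,
                              intersect(by_class[[poor]], expr_cols),
                              intersect(by_class[[o]], expr_cols))
      select_degs(tab, cfg$lfc_min, cfg$p_max, cfg$use_adjusted)
    })
    sig <- if (length(contrasts) >= 2)
      intersect_contrasts(contrasts[[1]], contrasts[[2]])
    else contrasts[[1]]
    out <- tibble::tibble(
      gene = c(sig$up, sig$down),
      direction = rep(c("up", "down"), c(length(sig$up),
                                         length(sig$down))))
    utils::write.table(as.data.frame(out), pth("degs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sig
  })

  # per-class patient models: base model with GPR-gated bounds scaled by
  # within-class gene ON-frequencies
  class_models <- NULL
  ess <- stage("essentiality", "essentiality.tsv", function() {
    fva <- flux_variability(model, 0)
    by_class <- split(classes$sample, classes$class)
    class_models <<- lapply(by_class, function(smp) {
      smp <- intersect(smp, colnames(bin$calls))
      act <- rowMeans(bin$calls[intersect(rownames(bin$calls),
                                          model$gene_ids), smp,
                                drop = FALSE])
      scale_bounds_by_activity(model, act, fva)
    })
    patient_models <- stats::setNames(
      class_models[classes$class], classes$sample)
    em <- suppressWarnings(cohort_essentiality(patient_models))
    per_class <- lapply(by_class, function(smp)
      consensus_essential_genes(em, smp, cfg$essential_cutoff,
                                cfg$min_fraction))
    out <- tibble::as_tibble(as.data.frame(em$ratios)) |>
      dplyr::mutate(gene = rownames(em$ratios), .before = 1)
    utils::write.table(as.data.frame(out), pth("essentiality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(matrix = em, per_class = per_class,
         exclusive = if (length(per_class) >= 2)
           class_exclusive_genes(per_class) else NULL)
  })

  patterns <- stage("flux_patterns", "flux_patterns.tsv", function() {
    patient_models <- stats::setNames(
      class_models[classes$class], classes$sample)
    ft <- cohort_flux_table(patient_models)
    labs <- stats::setNames(classes$class, classes$sample)
    fp <- classify_flux_patterns(ft, labs, poor, cfg$epsilon,
                                 cfg$majority)
    utils::write.table(as.data.frame(fp), pth("flux_patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fp
  })

  files <- file.path(out_dir, unlist(outputs))
  manifest <- list(
    seed = cfg$seed,
    poor_class = poor,
    inputs = lapply(
      stats::setNames(nm = c("model", "expr", "edges", "clinical")),
      function(k) list(path = cfg[[k]],
                       md5 = unname(tools::md5sum(cfg[[k]])))),
    stages = purrr::imap(outputs, function(f, nm)
      list(file = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest, poor_class = poor)))
}
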