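#' Single-gene-deletion screens across a cohort of patient models
#'
#' Runs [single_gene_deletion_screen()] for every patient model over the
#' union of their gene sets. Genes absent from a patient's model are
#' recorded as ratio 1 (deleting a gene the model does not carry is a
#' no-op) and marked in the absence mask. Patients whose model cannot grow
#' are excluded with a warning.
#'
#' @param models Named list of [metabolic_model()] objects (one per
#'   patient).
#' @return List of class `essentiality_matrix`: `ratios` (gene x patient),
#'   `absent` (logical mask, same shape), `wildtype_growth` (per patient),
#'   `excluded` (non-growing patients).
#' @export
cohort_essentiality <- function(models) {
  stopifnot(is.list(models), length(models) > 0)
  if (is.null(names(models)))
    names(models) <- paste0("P", seq_along(models))
  genes <- sort(unique(unlist(lapply(models, `[[`, "gene_ids"))))
  ratios <- matrix(1, length(genes), length(models),
                   dimnames = list(genes, names(models)))
  absent <- matrix(FALSE, length(genes), length(models),
                   dimnames = list(genes, names(models)))
  wt <- stats::setNames(rep(NA_real_, length(models)), names(models))
  excluded <- character()
  for (p in names(models)) {
    scr <- tryCatch(single_gene_deletion_screen(models[[p]]),
                    error = function(e) NULL)
    if (is.null(scr)) {
      warning("patient model '", p, "' cannot grow; excluded",
              call. = FALSE)
      excluded <- c(excluded, p)
      absent[, p] <- TRUE
      next
    }
    wt[p] <- attr(scr, "wildtype_growth")
    ratios[scr$gene, p] <- scr$growth_ratio
    absent[setdiff(genes, scr$gene), p] <- TRUE
  }
  structure(list(ratios = ratios, absent = absent, wildtype_growth = wt,
                 excluded = excluded),
            class = "essentiality_matrix")
}

#' Consensus essential genes of a patient class
#'
#' A gene qualifies when its deletion is near-lethal (growth ratio below
#' `essential_cutoff`) in at least `ceiling(min_fraction * n)` of the
#' class's patients whose model carries the gene; genes whose knockout has
#' no influence in any patient of the class (ratio ~ 1 everywhere) are
#' excluded regardless.
#'
#' @param ess An `essentiality_matrix` from [cohort_essentiality()].
#' @param patients Patient identifiers forming the class.
#' @param essential_cutoff Growth-ratio cutoff for "essential"
#'   (default 0.01).
#' @param min_fraction Required fraction of class patients (default 0.5,
#'   i.e. "at least half").
#' @return Character vector of consensus-essential genes (sorted).
#' @export
consensus_essential_genes <- function(ess, patients,
                                      essential_cutoff = 0.01,
                                      min_fraction = 0.5) {
  stopifnot(inherits(ess, "essentiality_matrix"), length(patients) >= 1)
  patients <- intersect(patients, colnames(ess$ratios))
  R <- ess$ratios[, patients, drop = FALSE]
  M <- ess$absent[, patients, drop = FALSE]
  need <- ceiling(min_fraction * length(patients))
  n_ess <- rowSums(R < essential_cutoff & !M)
  influential <- rowSums(R < 1 - 1e-9 & !M) > 0
  sort(rownames(R)[n_ess >= need & influential])
}

#' Shared and class-exclusive gene sets
#'
#' @param per_class_lists Named list of character vectors (consensus
#'   essential genes per class).
#' @return List with `shared` (in every class), `exclusive` (per class:
#'   genes in that class only) and `pairwise_shared` (per class pair).
#' @export
class_exclusive_genes <- function(per_class_lists) {
  stopifnot(length(per_class_lists) >= 2)
  classes <- names(per_class_lists)
  shared <- Reduce(intersect, per_class_lists)
  exclusive <- lapply(classes, function(cl)
    sort(setdiff(per_class_lists[[cl]],
                 unlist(per_class_lists[setdiff(classes, cl)]))))
  names(exclusive) <- classes
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(pr)
    sort(intersect(per_class_lists[[pr[1]]], per_class_lists[[pr[2]]])))
  names(pairwise) <- vapply(pairs, paste, character(1), collapse = "&")
  list(shared = sort(shared), exclusive = exclusive,
       pairwise_shared = pairwise)
}

#' Categorize a flux value as negative, zero or positive
#'
#' @param v Numeric flux value(s).
#' @param epsilon Magnitude below which a flux counts as zero
#'   (default 1e-6).
#' @return Character vector in `{"neg", "zero", "pos"}`.
#' @export
flux_category <- function(v, epsilon = 1e-6) {
  dplyr::case_when(abs(v) <= epsilon ~ "zero",
                   v > epsilon ~ "pos",
                   TRUE ~ "neg")
}

#' Classify per-reaction flux reprogramming between patient classes
#'
#' For each reaction, every class must have a strict-majority flux
#' category (neg/zero/pos) over its patients; reactions where the
#' poor-prognosis class's majority category departs from a common category
#' in all other classes fall into four types:
#' type 1 = negative elsewhere, positive in the poor class;
#' type 2 = positive elsewhere, negative in the poor class;
#' type 3 = one non-zero category elsewhere, zero in the poor class;
#' type 4 = zero elsewhere, non-zero in the poor class.
#' Anything else (including any class without a strict majority) is
#' `"none"`. Patients lacking the reaction (NA flux) are excluded from
#' that reaction's majority denominators.
#'
#' @param flux_table Numeric reaction-by-patient matrix (NA = reaction
#'   absent from that patient's model).
#' @param class_labels Named vector patient -> class label.
#' @param poor_class Label of the poor-prognosis class.
#' @param epsilon Zero-flux magnitude threshold (default 1e-6).
#' @param majority Fraction that must be strictly exceeded for a class
#'   majority (default 0.5).
#' @return Tibble of class `flux_patterns`: `reaction`, `pattern_type`
#'   (`"1"`..`"4"` or `"none"`), one `category_<class>` and
#'   `fraction_<class>` column per class.
#' @export
classify_flux_patterns <- function(flux_table, class_labels, poor_class,
                                   epsilon = 1e-6, majority = 0.5) {
  stopifnot(is.matrix(flux_table), poor_class %in% class_labels)
  classes <- unique(class_labels)
  other <- setdiff(classes, poor_class)
  if (length(other) < 1) stop("need at least one non-poor class",
                              call. = FALSE)
  patients <- colnames(flux_table)
  if (is.null(patients) || !all(patients %in% names(class_labels)))
    stop("flux_table columns must be named by patients in class_labels",
         call. = FALSE)

  per_rxn <- lapply(rownames(flux_table), function(rid) {
    v <- flux_table[rid, ]
    maj <- lapply(classes, function(cl) {
      vi <- v[patients[class_labels[patients] == cl]]
      vi <- vi[!is.na(vi)]
      if (!length(vi)) return(list(cat = NA_character_, frac = NA_real_))
      cats <- flux_category(vi, epsilon)
      tab <- table(cats)
      top <- which.max(tab)
      frac <- as.numeric(tab[top]) / length(vi)
      list(cat = if (frac > majority) names(tab)[top] else NA_character_,
           frac = frac)
    })
    names(maj) <- classes
    cats <- vapply(maj, `[[`, character(1), "cat")
    fracs <- vapply(maj, `[[`, numeric(1), "frac")
    type <- flux_pattern_type(cats[other], cats[poor_class])
    c(list(reaction = rid, pattern_type = type),
      stats::setNames(as.list(cats), paste0("category_", classes)),
      stats::setNames(as.list(fracs), paste0("fraction_", classes)))
  })
  out <- dplyr::bind_rows(lapply(per_rxn, tibble::as_tibble))
  class(out) <- c("flux_patterns", class(out))
  out
}

# Map (non-poor category set, poor category) to pattern types 1-4.
flux_pattern_type <- function(other_cats, poor_cat) {
  if (anyNA(other_cats) || is.na(poor_cat)) return("none")
  if (length(unique(other_cats)) != 1) return("none")
  oc <- other_cats[1]
  if (oc == "neg" && poor_cat == "pos") return("1")
  if (oc == "pos" && poor_cat == "neg") return("2")
  if (oc %in% c("neg", "pos") && poor_cat == "zero") return("3")
  if (oc == "zero" && poor_cat %in% c("neg", "pos")) return("4")
  "none"
}

#' Per-patient flux table from a cohort of models
#'
#' Computes a reproducible (parsimonious) flux vector per patient model
#' and assembles the reaction-by-patient matrix over the union of
#' reactions, with NA where a reaction is absent from a patient's model.
#'
#' @param models Named list of [metabolic_model()] objects.
#' @param parsimonious Use [parsimonious_fluxes()] (default) or plain FBA.
#' @return Numeric reaction-by-patient matrix.
#' @export
cohort_flux_table <- function(models, parsimonious = TRUE) {
  if (is.null(names(models)))
    names(models) <- paste0("P", seq_along(models))
  rxns <- sort(unique(unlist(lapply(models, function(m)
    names(m$reactions)))))
  out <- matrix(NA_real_, length(rxns), length(models),
                dimnames = list(rxns, names(models)))
  for (p in names(models)) {
    res <- if (parsimonious) parsimonious_fluxes(models[[p]])
           else optimize_growth(models[[p]])
    if (res$status == "optimal") out[names(res$fluxes), p] <- res$fluxes
  }
  out
}
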