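#' Read a constraint-based model from SBML
#'
#' Supports SBML Level 3 with the flux-balance-constraints (fbc) extension
#' (bounds as referenced parameters, gene associations as
#' `geneProductAssociation` trees, objective from the active fbc objective)
#' and the older COBRA Level 2 dialect (bounds and objective coefficient as
#' `kineticLaw` parameters, GPR in a `GENE_ASSOCIATION:` note). Reactions
#' without explicit bounds default to `[-1000, 1000]` when reversible and
#' `[0, 1000]` otherwise.
#'
#' @param path Path to an SBML file (Level 2 or 3).
#' @return A [metabolic_model()].
#' @export
read_sbml_model <- function(path) {
  stopifnot(file.exists(path))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  model_node <- xml_first(doc, "model")
  if (is.na(model_node)) stop("not an SBML model: ", path, call. = FALSE)
  model_id <- attr_or(model_node, "id", "model")

  # fbc gene products: internal id -> label
  gp_nodes <- xml_all(doc, "geneProduct")
  gp_map <- character()
  if (length(gp_nodes)) {
    gp_id <- vapply(gp_nodes, attr_or, character(1), name = "id")
    gp_lab <- vapply(gp_nodes, function(n)
      attr_or(n, "label", attr_or(n, "id")), character(1))
    gp_map <- stats::setNames(gp_lab, gp_id)
  }

  # global parameters (fbc bounds refer to these)
  par_nodes <- xml_all(doc, "parameter")
  par_nodes <- par_nodes[vapply(par_nodes, function(n)
    is.na(xml2::xml_find_first(n, "ancestor::*[local-name()='kineticLaw']")),
    logical(1))]
  par_val <- stats::setNames(
    vapply(par_nodes, function(n) as.numeric(attr_or(n, "value", "NA")),
           numeric(1)),
    vapply(par_nodes, attr_or, character(1), name = "id"))

  rxn_nodes <- xml_all(doc, "reaction")
  if (!length(rxn_nodes)) stop("SBML model has no reactions", call. = FALSE)

  reactions <- lapply(rxn_nodes, sbml_parse_reaction,
                      par_val = par_val, gp_map = gp_map)
  obj_coef <- vapply(reactions, function(r) r$objective_coefficient,
                     numeric(1))
  reactions <- lapply(reactions, function(r) {
    r$objective_coefficient <- NULL
    r
  })

  objective <- sbml_find_objective(doc, obj_coef,
                                   vapply(reactions, `[[`, character(1),
                                          "id"))
  if (is.null(objective))
    stop(sprintf("no objective reaction found in SBML model '%s'", model_id),
         call. = FALSE)

  reactions <- lapply(reactions, function(r)
    reaction(r$id, r$stoichiometry, r$lower_bound, r$upper_bound, r$gpr))
  metabolic_model(reactions, objective, id = model_id)
}

sbml_parse_reaction <- function(node, par_val, gp_map) {
  id <- attr_or(node, "id")
  reversible <- !identical(tolower(attr_or(node, "reversible", "true")),
                           "false")
  st <- c(sbml_species_refs(node, "listOfReactants", -1),
          sbml_species_refs(node, "listOfProducts", +1))
  st <- tapply_sum(st)

  lb <- ub <- NA_real_
  lb_ref <- attr_or(node, "lowerFluxBound", NA)
  ub_ref <- attr_or(node, "upperFluxBound", NA)
  if (!is.na(lb_ref)) lb <- unname(par_val[lb_ref])
  if (!is.na(ub_ref)) ub <- unname(par_val[ub_ref])

  # COBRA L2 dialect: kineticLaw local parameters
  obj_coef <- 0
  kl <- xml_first(node, "kineticLaw")
  if (!is.na(kl)) {
    for (p in xml_all(kl, "parameter")) {
      pid <- toupper(attr_or(p, "id", ""))
      val <- as.numeric(attr_or(p, "value", "NA"))
      if (pid == "LOWER_BOUND" && is.na(lb)) lb <- val
      if (pid == "UPPER_BOUND" && is.na(ub)) ub <- val
      if (pid == "OBJECTIVE_COEFFICIENT" && !is.na(val)) obj_coef <- val
    }
  }
  if (is.na(lb)) lb <- if (reversible) -1000 else 0
  if (is.na(ub)) ub <- 1000

  gpr <- sbml_parse_gpa(node, gp_map)
  if (is.null(gpr)) {
    notes <- xml2::xml_text(xml_first(node, "notes"))
    if (!is.na(notes) && grepl("GENE_ASSOCIATION", notes)) {
      rule <- sub(".*GENE_ASSOCIATION:\\s*([^\n<]*).*", "\\1", notes)
      gpr <- tryCatch(parse_gpr(trimws(rule)), error = function(e)
        stop(sprintf("unparseable GPR for reaction '%s': %s", id,
                     conditionMessage(e)), call. = FALSE))
    }
  }
  list(id = id, stoichiometry = st, lower_bound = lb, upper_bound = ub,
       gpr = gpr, objective_coefficient = obj_coef)
}

sbml_species_refs <- function(rxn_node, list_name, sign) {
  lst <- xml_first(rxn_node, list_name)
  if (is.na(lst)) return(numeric())
  refs <- xml_all(lst, "speciesReference")
  if (!length(refs)) return(numeric())
  stats::setNames(
    sign * vapply(refs, function(n)
      as.numeric(attr_or(n, "stoichiometry", "1")), numeric(1)),
    vapply(refs, attr_or, character(1), name = "species"))
}

tapply_sum <- function(x) {
  if (!length(x)) return(numeric())
  out <- tapply(x, names(x), sum)
  out <- out[abs(out) > 0]
  stats::setNames(as.numeric(out), names(out))
}

sbml_parse_gpa <- function(rxn_node, gp_map) {
  gpa <- xml_first(rxn_node, "geneProductAssociation")
  if (is.na(gpa)) return(NULL)
  kids <- xml2::xml_children(gpa)
  if (!length(kids)) return(NULL)
  sbml_gpa_tree(kids[[1]], gp_map)
}

sbml_gpa_tree <- function(node, gp_map) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- attr_or(node, "geneProduct")
    lab <- if (ref %in% names(gp_map)) unname(gp_map[ref]) else ref
    return(structure(list(kind = "gene", gene = lab), class = "gpr"))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), sbml_gpa_tree, gp_map = gp_map)
    return(gpr_node(nm, kids))
  }
  stop("unrecognised geneProductAssociation node: ", nm, call. = FALSE)
}

sbml_find_objective <- function(doc, obj_coef, rxn_ids) {
  fo <- xml_all(doc, "fluxObjective")
  if (length(fo)) {
    ref <- attr_or(fo[[1]], "reaction")
    if (!is.na(ref) && ref %in% rxn_ids) return(ref)
  }
  hit <- which(obj_coef != 0)
  if (length(hit)) return(rxn_ids[hit[1]])
  NULL
}

xml_first <- function(node, local) {
  xml2::xml_find_first(node, sprintf(".//*[local-name()='%s']", local))
}
xml_all <- function(node, local) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", local))
}
attr_or <- function(node, name, default = NA_character_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

#' Write a model to SBML Level 3 with the fbc extension
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  L <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", esc(model$id)),
    "    <listOfCompartments>",
    "      <compartment id=\"c\" constant=\"true\"/>",
    "    </listOfCompartments>")

  if (length(model$metabolites)) {
    L <- c(L, "    <listOfSpecies>",
           sprintf(paste0("      <species id=\"%s\" compartment=\"c\" ",
                          "hasOnlySubstanceUnits=\"false\" ",
                          "boundaryCondition=\"false\" constant=\"false\"/>"),
                   esc(model$metabolites)),
           "    </listOfSpecies>")
  }

  rxns <- model$reactions
  L <- c(L, "    <listOfParameters>",
         unlist(lapply(rxns, function(r) c(
           sprintf("      <parameter id=\"%s_lb\" value=\"%s\" constant=\"true\"/>",
                   esc(r$id), num(r$lower_bound)),
           sprintf("      <parameter id=\"%s_ub\" value=\"%s\" constant=\"true\"/>",
                   esc(r$id), num(r$upper_bound))))),
         "    </listOfParameters>",
         "    <listOfReactions>")

  for (r in rxns) {
    L <- c(L, sprintf(paste0("      <reaction id=\"%s\" reversible=\"%s\" ",
                             "fast=\"false\" fbc:lowerFluxBound=\"%s_lb\" ",
                             "fbc:upperFluxBound=\"%s_ub\">"),
                      esc(r$id),
                      if (r$lower_bound < 0) "true" else "false",
                      esc(r$id), esc(r$id)))
    st <- r$stoichiometry
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac))
      L <- c(L, "        <listOfReactants>",
             sprintf(paste0("          <speciesReference species=\"%s\" ",
                            "stoichiometry=\"%s\" constant=\"true\"/>"),
                     esc(names(reac)), num(-as.numeric(reac))),
             "        </listOfReactants>")
    if (length(prod))
      L <- c(L, "        <listOfProducts>",
             sprintf(paste0("          <speciesReference species=\"%s\" ",
                            "stoichiometry=\"%s\" constant=\"true\"/>"),
                     esc(names(prod)), num(as.numeric(prod))),
             "        </listOfProducts>")
    if (!is.null(r$gpr))
      L <- c(L, "        <fbc:geneProductAssociation>",
             sbml_gpa_xml(r$gpr, indent = 10L),
             "        </fbc:geneProductAssociation>")
    L <- c(L, "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>",
         "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
         "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
         "        <fbc:listOfFluxObjectives>",
         sprintf(paste0("          <fbc:fluxObjective fbc:reaction=\"%s\" ",
                        "fbc:coefficient=\"1\"/>"),
                 esc(model$objective_reaction)),
         "        </fbc:listOfFluxObjectives>",
         "      </fbc:objective>",
         "    </fbc:listOfObjectives>")
  if (length(model$gene_ids))
    L <- c(L, "    <fbc:listOfGeneProducts>",
           sprintf(paste0("      <fbc:geneProduct fbc:id=\"%s\" ",
                          "fbc:label=\"%s\"/>"),
                   esc(model$gene_ids), esc(model$gene_ids)),
           "    </fbc:listOfGeneProducts>")
  L <- c(L, "  </model>", "</sbml>")
  writeLines(L, path)
  invisible(path)
}

sbml_gpa_xml <- function(gpr, indent) {
  pad <- strrep(" ", indent)
  if (gpr$kind == "gene")
    return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"%s\"/>",
                   pad, gpr$gene))
  tag <- paste0("fbc:", gpr$kind)
  c(sprintf("%s<%s>", pad, tag),
    unlist(lapply(gpr$children, sbml_gpa_xml, indent = indent + 2L)),
    sprintf("%s</%s>", pad, tag))
}
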