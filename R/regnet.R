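#' Merge two inferred regulatory networks by consensus
#'
#' The merged edge set is the union of the two inputs; edges predicted by
#' both inference methods are tagged `confidence = "high"`, the rest
#' `"standard"`.
#'
#' @param net_a,net_b Edge tibbles (`tf`, `target`, `sign`, ...).
#' @return Merged edge tibble sorted by (tf, target).
#' @export
merge_networks_consensus <- function(net_a, net_b) {
  key_a <- paste(net_a$tf, net_a$target, sep = "\r")
  key_b <- paste(net_b$tf, net_b$target, sep = "\r")
  both <- dplyr::bind_rows(net_a, net_b)
  both <- suppressMessages(dedup_edges(both))
  key <- paste(both$tf, both$target, sep = "\r")
  both$confidence <- ifelse(key %in% key_a & key %in% key_b,
                            "high", "standard")
  dplyr::arrange(both, .data$tf, .data$target)
}

#' Nodes private to one network, with their induced subnetwork
#'
#' Removes from network `a` every node that also appears in network `b`;
#' the survivors are the TFs/genes present only in `a`, returned together
#' with the edges of `a` whose two endpoints both survive.
#'
#' @param net_a,net_b Edge tibbles.
#' @return List with `nodes` (character vector) and `subnetwork`
#'   (edge tibble).
#' @export
network_node_difference <- function(net_a, net_b) {
  nodes_a <- unique(c(net_a$tf, net_a$target))
  nodes_b <- unique(c(net_b$tf, net_b$target))
  only_a <- sort(setdiff(nodes_a, nodes_b))
  sub <- net_a[net_a$tf %in% only_a & net_a$target %in% only_a, ,
               drop = FALSE]
  list(nodes = only_a, subnetwork = sub)
}

#' Rank network hubs by total degree
#'
#' Total degree = in-degree + out-degree over the directed edge list; ties
#' are broken lexicographically by node name. Betweenness centrality is
#' available as an alternative hub score.
#'
#' @param net Edge tibble.
#' @param k Number of top nodes to return (default: all).
#' @param score `"degree"` (default) or `"betweenness"`.
#' @return Tibble with columns `node`, `degree` (and `betweenness` when
#'   requested), ordered by decreasing score.
#' @export
rank_hubs <- function(net, k = NULL, score = c("degree", "betweenness")) {
  score <- match.arg(score)
  if (!nrow(net)) stop("cannot rank hubs of an empty network", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$tf, to = net$target), directed = TRUE)
  deg <- igraph::degree(g, mode = "all")
  out <- tibble::tibble(node = names(deg), degree = as.integer(deg))
  if (score == "betweenness")
    out$betweenness <- as.numeric(igraph::betweenness(g))
  ord <- order(-out[[if (score == "degree") "degree" else "betweenness"]],
               out$node)
  out <- out[ord, ]
  if (!is.null(k)) out <- utils::head(out, k)
  out
}

#' Label edge signs from TF-target expression correlation
#'
#' Spearman correlation across samples between each TF and its target:
#' positive -> `activation`, negative -> `inhibition`; correlations below
#' `min_abs_rho` in magnitude, or pairs not measured, stay `unknown`.
#'
#' @param net Edge tibble.
#' @param expr Numeric gene-by-sample matrix.
#' @param min_abs_rho Minimum |rho| to call a direction (default 0.05).
#' @return `net` with an updated `sign` column and a new `rho` column.
#' @export
sign_edges_by_correlation <- function(net, expr, min_abs_rho = 0.05) {
  rho <- purrr::map2_dbl(net$tf, net$target, function(tf, tg) {
    if (!tf %in% rownames(expr) || !tg %in% rownames(expr))
      return(NA_real_)
    stats::cor(expr[tf, ], expr[tg, ], method = "spearman")
  })
  sign <- dplyr::case_when(
    is.na(rho) | abs(rho) < min_abs_rho ~ "unknown",
    rho > 0 ~ "activation",
    TRUE ~ "inhibition")
  net$sign <- sign
  net$rho <- rho
  net
}
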