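#' Read a gene-by-sample expression matrix from TSV
#'
#' First column holds gene identifiers, the header row sample identifiers.
#' Duplicate gene rows are collapsed by their mean; the number of collapsed
#' rows is recorded in attribute `n_collapsed`.
#'
#' @param path TSV path (UTF-8, header).
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  stopifnot(file.exists(path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop("ragged TSV: line ", which(nf != nf[1])[1], " has ",
         nf[nf != nf[1]][1], " fields, expected ", nf[1], call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs gene column + >=1 sample",
                          call. = FALSE)
  genes <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path,
                              call. = FALSE)
  n_dup <- sum(duplicated(genes))
  if (n_dup > 0L) {
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
    message(n_dup, " duplicate gene rows collapsed by mean")
  }
  rownames(vals) <- genes
  storage.mode(vals) <- "double"
  if (any(!is.finite(vals))) stop("non-finite expression values in ", path,
                                  call. = FALSE)
  attr(vals, "n_collapsed") <- n_dup
  vals
}

#' Write an expression matrix to TSV
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TF-to-target regulatory edge list from TSV
#'
#' Requires `tf` and `target` columns; optional `sign`
#' (`activation`/`inhibition`), `confidence` (`high`/`standard`) and free
#' columns are carried through. Duplicate (tf, target) pairs are collapsed
#' keeping the first sign that is not `unknown`; the count is in attribute
#' `n_deduplicated`. Self-loops are permitted but flagged in attribute
#' `self_loops`.
#'
#' @param path TSV path.
#' @return Tibble with columns `tf`, `target`, `sign`, `confidence`,
#'   `source_tag`.
#' @export
read_network_edges <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("tf", "target") %in% names(df)))
    stop("edge TSV must have 'tf' and 'target' columns", call. = FALSE)
  net <- tibble::tibble(
    tf = as.character(df$tf),
    target = as.character(df$target),
    sign = if ("sign" %in% names(df)) as.character(df$sign) else "unknown",
    confidence = if ("confidence" %in% names(df))
      as.character(df$confidence) else "standard",
    source_tag = if ("source_tag" %in% names(df))
      as.character(df$source_tag) else basename(path)
  )
  bad <- !net$sign %in% c("activation", "inhibition", "unknown")
  net$sign[bad] <- "unknown"
  net <- dedup_edges(net)
  attr(net, "self_loops") <- sum(net$tf == net$target)
  net
}

dedup_edges <- function(net) {
  key <- paste(net$tf, net$target, sep = "\r")
  n_dup <- sum(duplicated(key))
  if (n_dup > 0L) {
    # keep the first non-unknown sign per pair
    net <- net |>
      dplyr::group_by(.data$tf, .data$target) |>
      dplyr::summarise(
        sign = {
          s <- .data$sign[.data$sign != "unknown"]
          if (length(s)) s[1] else "unknown"
        },
        confidence = .data$confidence[1],
        source_tag = .data$source_tag[1],
        .groups = "drop")
    message(n_dup, " duplicate edges collapsed")
  }
  attr(net, "n_deduplicated") <- n_dup
  net
}

#' Write a regulatory edge list to TSV
#' @param net Edge tibble (`tf`, `target`, `sign`, `confidence`, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(net, path) {
  utils::write.table(as.data.frame(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a clinical survival table from TSV
#'
#' Requires `sample`, `time` (days) and `event` (1 = death, 0 = censored)
#' columns; an optional `class_label` column is kept. Rows with
#' non-positive time are dropped with a warning; their count is in
#' attribute `n_dropped`.
#'
#' @param path TSV path.
#' @return Tibble with columns `sample`, `time`, `event`
#'   (+ `class_label` if present).
#' @export
read_clinical_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(df)))
    stop("clinical TSV must have 'sample', 'time', 'event' columns",
         call. = FALSE)
  ev <- df$event
  if (!all(ev %in% c(0, 1)))
    stop("event values must be 0 (censored) or 1 (death); found: ",
         paste(unique(ev[!ev %in% c(0, 1)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicate sample identifiers in clinical table", call. = FALSE)
  keep <- df$time > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    warning(n_dropped, " records with non-positive time dropped",
            call. = FALSE)
  out <- tibble::tibble(sample = as.character(df$sample[keep]),
                        time = as.numeric(df$time[keep]),
                        event = as.integer(df$event[keep]))
  if ("class_label" %in% names(df))
    out$class_label <- as.character(df$class_label[keep])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a clinical table to TSV
#' @param clinical Clinical tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(as.data.frame(clinical), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a regulatory network for external viewers
#'
#' SIF uses the interaction word `regulates`; GraphML carries `sign` and
#' `confidence` edge attributes (readable back via
#' [read_network_graphml()]).
#'
#' @param net Edge tibble.
#' @param path Output path.
#' @param format `"SIF"` or `"GraphML"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("SIF", "GraphML")) {
  if (!nrow(net)) stop("cannot export an empty network", call. = FALSE)
  format <- match.arg(toupper(format[1]), c("SIF", "GRAPHML"))
  if (format == "SIF") {
    writeLines(paste(net$tf, "regulates", net$target, sep = "\t"), path)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = net$tf, to = net$target,
                 sign = net$sign, confidence = net$confidence),
      directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network exported as GraphML back into an edge tibble
#' @param path GraphML path.
#' @return Tibble with columns `tf`, `target`, `sign`, `confidence`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  tibble::tibble(tf = el$from, target = el$to,
                 sign = if ("sign" %in% names(el)) el$sign else "unknown",
                 confidence = if ("confidence" %in% names(el))
                   el$confidence else "standard")
}
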