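#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative gene-by-sample matrix V into W (gene x rank)
#' and H (rank x sample) minimizing the generalized Kullback-Leibler
#' divergence D(V || WH) (default) or the Frobenius norm, with the classic
#' multiplicative update rules. The divergence is non-increasing across
#' iterations; iteration stops when its relative change drops below `tol`
#' or `max_iter` is reached.
#'
#' @param V Nonnegative numeric matrix without all-zero rows.
#' @param rank Factorization rank (number of latent patterns).
#' @param seed Integer seed for the random uniform initialization.
#' @param max_iter Maximum multiplicative updates (default 2000).
#' @param tol Relative divergence-change convergence tolerance
#'   (default 1e-6).
#' @param method `"kl"` or `"frobenius"`.
#' @return List with `W`, `H`, `divergence` (final), `n_iter`, `converged`.
#' @export
nmf_factorize <- function(V, rank, seed = 1L, max_iter = 2000L,
                          tol = 1e-6, method = c("kl", "frobenius")) {
  method <- match.arg(method)
  stopifnot(is.matrix(V), rank >= 1)
  if (any(V < 0)) stop("NMF requires a nonnegative matrix", call. = FALSE)
  if (any(rowSums(V) == 0))
    stop("NMF input has all-zero rows; drop them first", call. = FALSE)
  n <- nrow(V); m <- ncol(V)
  eps <- 1e-16
  set.seed(seed)
  W <- matrix(stats::runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(stats::runif(rank * m, 0.1, 1), rank, m)

  div <- function() {
    WH <- W %*% H
    if (method == "kl")
      sum(V * log((V + eps) / (WH + eps)) - V + WH)
    else sum((V - WH)^2) / 2
  }
  d_prev <- div()
  trace <- d_prev
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (method == "kl") {
      WH <- W %*% H + eps
      H <- H * (t(W) %*% (V / WH)) / (colSums(W) + eps)
      WH <- W %*% H + eps
      W <- W * ((V / WH) %*% t(H)) / rep(rowSums(H) + eps, each = n)
    } else {
      H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
    }
    if (it %% 10L == 0L || it == max_iter) {
      d_now <- div()
      trace <- c(trace, d_now)
      if (abs(d_prev - d_now) <= tol * max(abs(d_prev), eps)) {
        converged <- TRUE
        d_prev <- d_now
        break
      }
      d_prev <- d_now
    }
  }
  list(W = W, H = H, divergence = d_prev, n_iter = it,
       converged = converged, divergence_trace = trace)
}

#' NMF consensus clustering across random restarts
#'
#' For each candidate rank, runs `n_runs` randomly initialized NMF
#' factorizations; each run assigns samples to the latent pattern with the
#' largest H coefficient, and the consensus matrix records how often two
#' samples co-cluster. Final labels cut the average-linkage dendrogram of
#' 1 - consensus at `rank` clusters. Rank stability is scored by the
#' cophenetic correlation and the average silhouette width.
#'
#' @param V Nonnegative gene-by-sample matrix.
#' @param ranks Integer vector of candidate ranks (default `2:10`).
#' @param n_runs Random restarts per rank (default 200).
#' @param seed Master seed; per-run seeds are derived as
#'   `seed + 1000 * rank + run`.
#' @param max_iter,tol Per-run NMF settings (defaults 500 / 1e-5: restarts
#'   trade per-run precision for ensemble size).
#' @return List of per-rank `consensus_clustering` objects (named by rank):
#'   fields `rank`, `consensus_matrix`, `labels`, `cophenetic`,
#'   `silhouette`, `n_runs`, `seed`.
#' @export
nmf_consensus_cluster <- function(V, ranks = 2:10, n_runs = 200L,
                                  seed = 1L, max_iter = 500L, tol = 1e-5) {
  stopifnot(ncol(V) >= max(ranks) + 1)
  samples <- colnames(V)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(V)))
  out <- lapply(ranks, function(r) {
    C <- matrix(0, ncol(V), ncol(V))
    for (run in seq_len(n_runs)) {
      fit <- nmf_factorize(V, r, seed = seed + 1000L * r + run,
                           max_iter = max_iter, tol = tol)
      lab <- apply(fit$H, 2, which.max)
      C <- C + outer(lab, lab, `==`)
    }
    C <- C / n_runs
    dimnames(C) <- list(samples, samples)
    hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
    labels <- stats::cutree(hc, k = r)
    names(labels) <- samples
    n_found <- length(unique(labels))
    structure(
      list(rank = r, consensus_matrix = C, labels = labels,
           cophenetic = cophenetic_correlation(C),
           silhouette = if (n_found >= 2)
             average_silhouette_width(labels, 1 - C) else NA_real_,
           n_classes_found = n_found, n_runs = n_runs, seed = seed),
      class = "consensus_clustering")
  })
  names(out) <- as.character(ranks)
  out
}

#' @export
print.consensus_clustering <- function(x, ...) {
  cat(sprintf(
    "<consensus_clustering> rank %d (%d runs): cophenetic %.4f, silhouette %.4f\n",
    x$rank, x$n_runs, x$cophenetic, x$silhouette))
  invisible(x)
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the consensus dissimilarities
#' (1 - consensus, upper triangle) and the cophenetic distances of their
#' average-linkage dendrogram; values near 1 indicate stable clustering.
#'
#' @param consensus_matrix Symmetric sample-by-sample matrix in `[0, 1]`.
#' @return Correlation in `[-1, 1]`; `NA` with a warning when either
#'   distance set is constant (correlation undefined).
#' @export
cophenetic_correlation <- function(consensus_matrix) {
  d <- stats::as.dist(1 - consensus_matrix)
  if (stats::sd(d) == 0) {
    warning("cophenetic correlation undefined for a constant consensus",
            call. = FALSE)
    return(NA_real_)
  }
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cophenetic(hc)
  if (stats::sd(coph) == 0) {
    # a perfect block matrix collapses to two distance levels; if the
    # dendrogram heights are constant the ordinary correlation is 0/0
    return(if (isTRUE(all.equal(as.numeric(d), as.numeric(coph)))) 1
           else NA_real_)
  }
  stats::cor(as.numeric(d), as.numeric(coph))
}

#' Average silhouette width under an arbitrary distance
#'
#' Standard silhouette: for sample i, a(i) is the mean distance to its own
#' cluster, b(i) the smallest mean distance to another cluster, and
#' s(i) = (b - a) / max(a, b); singletons score 0. Returns the mean over
#' samples.
#'
#' @param labels Integer/character cluster labels per sample.
#' @param distance Square distance matrix (e.g. 1 - consensus) or `dist`.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
average_silhouette_width <- function(labels, distance) {
  D <- as.matrix(distance)
  n <- length(labels)
  stopifnot(nrow(D) == n)
  cl <- unique(labels)
  if (length(cl) < 2) stop("silhouette needs >= 2 clusters", call. = FALSE)
  if (all(table(labels) == 1))
    stop("silhouette undefined for singleton-only clustering", call. = FALSE)
  s <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, labels[i]), function(k)
      mean(D[i, labels == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Select the clustering rank from stability metrics
#'
#' Picks the rank with the highest cophenetic correlation; ties go to the
#' higher silhouette, then to the smaller rank.
#'
#' @param metrics Tibble/data frame with columns `rank`, `cophenetic`,
#'   `silhouette` (e.g. from [consensus_metrics()]).
#' @return The selected rank (integer).
#' @export
select_rank <- function(metrics) {
  stopifnot(nrow(metrics) >= 2)
  ord <- order(-metrics$cophenetic, -metrics$silhouette, metrics$rank)
  as.integer(metrics$rank[ord[1]])
}

#' Prepare an expression submatrix for NMF
#'
#' Restricts the matrix to a gene panel (e.g. the genes of the integrated
#' regulatory-metabolic network), drops unmeasured panel genes, min-shifts
#' to nonnegative when log-scale input contains negative values (with a
#' message) and removes all-zero rows.
#'
#' @param expr Numeric gene-by-sample matrix.
#' @param genes Optional character vector restricting the rows.
#' @return Nonnegative matrix ready for [nmf_consensus_cluster()].
#' @export
prepare_nmf_input <- function(expr, genes = NULL) {
  if (!is.null(genes)) {
    keep <- intersect(genes, rownames(expr))
    if (!length(keep)) stop("no panel genes measured", call. = FALSE)
    expr <- expr[keep, , drop = FALSE]
  }
  mn <- min(expr)
  if (mn < 0) {
    message("min-shifting expression by ", format(-mn, digits = 4),
            " to nonnegative")
    expr <- expr - mn
  }
  expr[rowSums(expr) > 0, , drop = FALSE]
}

#' Collect per-rank stability metrics from a consensus run
#' @param cc_list Result of [nmf_consensus_cluster()].
#' @return Tibble with columns `rank`, `cophenetic`, `silhouette`.
#' @export
consensus_metrics <- function(cc_list) {
  tibble::tibble(
    rank = vapply(cc_list, `[[`, numeric(1), "rank"),
    cophenetic = vapply(cc_list, `[[`, numeric(1), "cophenetic"),
    silhouette = vapply(cc_list, `[[`, numeric(1), "silhouette"))
}
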