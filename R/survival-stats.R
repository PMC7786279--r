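#' Kaplan-Meier product-limit survival curves
#'
#' Estimates S(t) per group as the product over distinct event times of
#' (1 - d_t / n_t), with d_t the deaths and n_t the number at risk at time
#' t; tied events at the same time are handled jointly. Censoring removes
#' subjects from the risk set just after their censoring time.
#'
#' @param clinical Tibble with `time` (days, > 0) and `event`
#'   (1 death / 0 censored) columns.
#' @param group Optional vector of group labels (one per record) or the
#'   name of a column in `clinical`; default: a single pooled group.
#' @return Tibble of class `km_curves`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (rows at each distinct observed
#'   time, survival non-increasing within group, starting from 1 at the
#'   first row's time).
#' @export
kaplan_meier <- function(clinical, group = NULL) {
  stopifnot(nrow(clinical) >= 1)
  g <- resolve_group(clinical, group)
  out <- purrr::map_dfr(unique(g), function(gr) {
    tt <- clinical$time[g == gr]
    ev <- clinical$event[g == gr]
    times <- sort(unique(tt))
    n_risk <- vapply(times, function(t) sum(tt >= t), numeric(1))
    n_event <- vapply(times, function(t) sum(tt == t & ev == 1), numeric(1))
    n_cens <- vapply(times, function(t) sum(tt == t & ev == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    tibble::tibble(group = as.character(gr), time = times,
                   n_risk = as.integer(n_risk),
                   n_event = as.integer(n_event),
                   n_censor = as.integer(n_cens), survival = surv)
  })
  class(out) <- c("km_curves", class(out))
  out
}

resolve_group <- function(clinical, group) {
  if (is.null(group)) return(rep("all", nrow(clinical)))
  if (is.character(group) && length(group) == 1 &&
      group %in% names(clinical))
    return(as.character(clinical[[group]]))
  stopifnot(length(group) == nrow(clinical))
  as.character(group)
}

#' k-sample log-rank test
#'
#' At each distinct event time, compares the observed deaths per group with
#' those expected under a common hazard (hypergeometric expectation and
#' covariance); the quadratic form over k - 1 groups is chi-squared with
#' k - 1 degrees of freedom under the null of identical survival.
#'
#' @param clinical Tibble with `time` and `event` columns.
#' @param group Group labels per record, or a column name in `clinical`.
#' @return List of class `logrank_test`: `chi_square`, `df`, `p_value`,
#'   `observed` and `expected` per group.
#' @export
logrank_test <- function(clinical, group) {
  g <- factor(resolve_group(clinical, group))
  if (nlevels(g) < 2) stop("log-rank test needs >= 2 groups", call. = FALSE)
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)
  if (sum(clinical$event) == 0)
    stop("log-rank test needs >= 1 event", call. = FALSE)
  tt <- clinical$time
  ev <- clinical$event
  k <- nlevels(g)
  times <- sort(unique(tt[ev == 1]))

  O <- E <- stats::setNames(numeric(k), levels(g))
  V <- matrix(0, k, k, dimnames = list(levels(g), levels(g)))
  for (t in times) {
    at_risk <- tt >= t
    n_t <- sum(at_risk)
    d_t <- sum(tt == t & ev == 1)
    n_jt <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1))
    d_jt <- vapply(levels(g), function(l)
      sum(tt == t & ev == 1 & g == l), numeric(1))
    O <- O + d_jt
    E <- E + d_t * n_jt / n_t
    if (n_t > 1) {
      frac <- n_jt / n_t
      Vt <- d_t * (n_t - d_t) / (n_t - 1) *
        (diag(frac, k) - outer(frac, frac))
      V <- V + Vt
    }
  }
  z <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(as.numeric(t(z) %*% solve(Vk, z)),
                  error = function(e) NA_real_)
  if (is.na(chi)) { # singular covariance (e.g. a group with no risk overlap)
    chi <- as.numeric(t(z) %*% pseudo_inverse(Vk) %*% z)
  }
  structure(list(chi_square = chi, df = k - 1,
                 p_value = stats::pchisq(chi, df = k - 1,
                                         lower.tail = FALSE),
                 observed = O, expected = E),
            class = "logrank_test")
}

# Moore-Penrose pseudoinverse via SVD, used when the log-rank covariance is singular
pseudo_inverse <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("k-sample log-rank: chi^2 = %.4f, df = %d, p = %.3g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' @rdname kaplan_meier
#' @param object A `km_curves` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "overall survival",
                  colour = "class") +
    ggplot2::theme_minimal()
}
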