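# Internal linear-programming backend.
#
# Solves   max/min  c'v   s.t.  A v = b,  lb <= v <= ub
# via pracma::linprog after shifting x = v - lb so x >= 0 (linprog's
# native domain), with upper bounds as inequality rows. Fixed variables
# (lb == ub) are substituted out first: they are constants, and the
# degenerate rows they would add slow and destabilize the pivoting. All
# variables must have finite bounds, which constraint-based models
# guarantee (absent SBML bounds default to +/-1000).
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n,
            is.null(A) || ncol(A) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds", call. = FALSE)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, value = NA_real_))

  width <- ub - lb
  free <- width > 1e-12
  x_full <- lb
  b_shift <- if (is.null(A)) numeric() else as.numeric(b - A %*% lb)
  if (!any(free)) {
    feasible <- !length(b_shift) || all(abs(b_shift) <= 1e-9)
    return(if (feasible)
      list(status = "optimal", x = x_full, value = sum(obj * x_full))
      else list(status = "infeasible", x = NULL, value = NA_real_))
  }
  nf <- sum(free)
  Aeq <- if (is.null(A)) NULL else A[, free, drop = FALSE]
  res <- tryCatch(
    pracma::linprog(cc = obj[free],
                    A = diag(nf), b = width[free],
                    Aeq = Aeq, beq = if (is.null(A)) NULL else b_shift,
                    maximize = maximize,
                    maxiter = 500L + 50L * (nf + length(b_shift)),
                    bigM = 1e5),
    error = function(e) NULL
  )
  if (is.null(res) || res$errno != 1 || anyNA(res$x))
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  x_full[free] <- res$x + lb[free]
  list(status = "optimal", x = x_full, value = sum(obj * x_full))
}
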