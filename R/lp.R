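# Linear-programming core -----------------------------------------------------
#
# The solver is a self-contained bounded-variable two-phase primal simplex
# (src/simplex.cpp): dense revised simplex with an explicitly maintained
# basis inverse, deterministic pivoting, and periodic refactorisation.
# Problems at the scale handled here (tens to a few hundred reactions) solve
# in well under a millisecond, which matters because the knockout screen,
# flux variability analysis and the evolutionary sensitivity analysis each
# issue thousands of solves.

#' Solve a linear program with bounded variables
#'
#' Solves `min/max c'x` subject to `A x (=, <=, >=) rhs` and `lb <= x <= ub`.
#' Row duals are returned with the convention that for a maximisation
#' problem `y[i] = d(objective)/d(rhs[i])`.
#'
#' @param obj objective coefficient vector (length n).
#' @param A constraint matrix (m x n).
#' @param rhs right-hand side (length m).
#' @param sense character vector of `"="`, `"<="`, `">="` per row (recycled).
#' @param lb,ub variable bounds (may be `-Inf`/`Inf`).
#' @param maximize logical.
#' @param tol pivot/optimality tolerance on the solver scale.
#' @param max_iter simplex iteration cap.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective`, `x` (length n), and `y` (row duals, length m).
#' @export
solve_lp <- function(obj, A, rhs, sense = "=", lb, ub, maximize = FALSE,
                     tol = 1e-9, max_iter = 100000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n,
            length(ub) == n)
  sense <- rep(sense, length.out = m)
  if (any(lb > ub + tol)) stop("solve_lp: lb > ub")
  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # append slack columns for inequality rows
  ineq <- which(sense != "=")
  ns <- length(ineq)
  if (ns) {
    Sl <- matrix(0, m, ns)
    sl_lb <- numeric(ns); sl_ub <- numeric(ns)
    for (k in seq_along(ineq)) {
      Sl[ineq[k], k] <- 1
      if (sense[ineq[k]] == "<=") { sl_lb[k] <- 0;    sl_ub[k] <- Inf }
      else                        { sl_lb[k] <- -Inf; sl_ub[k] <- 0 }
    }
    A2 <- cbind(A, Sl)
    l2 <- c(as.numeric(lb), sl_lb); u2 <- c(as.numeric(ub), sl_ub)
    c2 <- c(cc, numeric(ns))
  } else {
    A2 <- A; l2 <- as.numeric(lb); u2 <- as.numeric(ub); c2 <- cc
  }
  res <- .cpp_simplex(A2, as.numeric(rhs), c2, l2, u2, tol,
                      as.integer(max_iter))
  if (res$status %in% c("maxiter", "singular")) {
    stop("solve_lp: simplex failed (", res$status, ")")
  }
  if (res$status == "optimal") {
    x <- as.numeric(res$x)[seq_len(n)]
    names(x) <- colnames(A)
    y <- as.numeric(res$y)
    if (maximize) y <- -y
    names(y) <- rownames(A)
    list(status = "optimal", objective = sum(as.numeric(obj) * x),
         x = x, y = y)
  } else {
    list(status = res$status, objective = NA_real_,
         x = stats::setNames(rep(NA_real_, n), colnames(A)),
         y = stats::setNames(rep(NA_real_, m), rownames(A)))
  }
}
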