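#' @useDynLib psomcs, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.sense_int <- function(sense) {
  s <- match(sense, c("<=", "=", ">="))
  if (anyNA(s)) stop("constraint sense must be one of '<=', '=', '>='")
  as.integer(s - 2L)
}

#' Solve a linear program
#'
#' Minimizes (or maximizes) \code{obj \%*\% x} subject to row constraints
#' \code{A x (sense) rhs} and variable bounds \code{lb <= x <= ub}, using
#' the package's dense two-phase simplex.  Infeasibility and unboundedness
#' are reported distinctly.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (may have zero rows).
#' @param sense character vector per row: \code{"<="}, \code{"="}, \code{">="}.
#' @param rhs right-hand sides.
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed.
#' @param maximize logical; maximize instead of minimize.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}), and for optimal solutions \code{objective} and
#'   \code{x}.
#' @export
solve_lp <- function(obj, A, sense, rhs, lb = rep(-Inf, length(obj)),
                     ub = rep(Inf, length(obj)), maximize = FALSE) {
  n <- length(obj)
  A <- as.matrix(A)
  if (nrow(A) == 0L) {  # bounds-only problem: give the core one inert row
    A <- matrix(0, 1L, n)
    sense <- "<="
    rhs <- 1
  }
  stopifnot(ncol(A) == n, nrow(A) == length(rhs), nrow(A) == length(sense),
            length(lb) == n, length(ub) == n)
  cc <- if (maximize) -obj else obj
  res <- .lp_simplex_cpp(A, as.numeric(rhs), .sense_int(sense),
                         as.numeric(cc), as.numeric(lb), as.numeric(ub))
  st <- res$status
  if (st == 3L) stop("simplex iteration limit reached")
  if (st == 1L) return(list(status = "infeasible"))
  if (st == 2L) return(list(status = "unbounded"))
  list(status = "optimal",
       objective = if (maximize) -res$objective else res$objective,
       x = as.numeric(res$x))
}

#' Solve a mixed-integer linear program by branch and bound
#'
#' Depth-first branch and bound over binary variables on top of
#' \code{\link{solve_lp}}.  Branching selects the most fractional binary;
#' the nearest-integer child is explored first.  With
#' \code{integral_obj = TRUE} (objective integer-valued on every feasible
#' integer point, e.g. a cardinality objective) LP bounds are rounded up
#' before pruning.
#'
#' @inheritParams solve_lp
#' @param binary integer indices of binary variables.
#' @param node_limit maximum branch-and-bound nodes before giving up.
#' @param integral_obj logical; see Details.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"budget"}), \code{objective}, \code{x}, \code{nodes}.
#' @export
solve_milp <- function(obj, A, sense, rhs, lb, ub, binary,
                       maximize = FALSE, node_limit = 200000L,
                       integral_obj = FALSE) {
  n <- length(obj)
  if (maximize) {
    res <- solve_milp(-obj, A, sense, rhs, lb, ub, binary,
                      maximize = FALSE, node_limit = node_limit,
                      integral_obj = integral_obj)
    if (!is.null(res$objective)) res$objective <- -res$objective
    return(res)
  }
  int_tol <- 1e-6
  inc <- NULL
  inc_obj <- Inf
  nodes <- 0L
  # each stack entry: list(lb, ub)
  stack <- list(list(lb = as.numeric(lb), ub = as.numeric(ub)))
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit) {
      return(list(status = "budget", objective = inc_obj, x = inc,
                  nodes = nodes))
    }
    rel <- solve_lp(obj, A, sense, rhs, nd$lb, nd$ub)
    if (rel$status == "infeasible") next
    if (rel$status == "unbounded") {
      if (is.null(inc)) return(list(status = "unbounded", nodes = nodes))
      next
    }
    bound <- rel$objective
    if (integral_obj) bound <- ceiling(bound - 1e-6)
    if (bound >= inc_obj - 1e-9) next
    frac <- abs(rel$x[binary] - round(rel$x[binary]))
    if (all(frac < int_tol)) {
      inc <- rel$x
      inc[binary] <- round(inc[binary])
      inc_obj <- rel$objective
      next
    }
    j <- binary[which.max(frac)]
    v <- rel$x[j]
    up <- nd; up$lb[j] <- 1; up$ub[j] <- 1
    dn <- nd; dn$lb[j] <- 0; dn$ub[j] <- 0
    # push the less promising child first (LIFO explores the other first)
    if (v >= 0.5) {
      stack[[length(stack) + 1L]] <- dn
      stack[[length(stack) + 1L]] <- up
    } else {
      stack[[length(stack) + 1L]] <- up
      stack[[length(stack) + 1L]] <- dn
    }
  }
  if (is.null(inc)) return(list(status = "infeasible", nodes = nodes))
  list(status = "optimal", objective = inc_obj, x = inc, nodes = nodes)
}
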