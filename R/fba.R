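# Linear-programming services over metabolic networks: FBA, FVA, yield
# bounds, linear flux regions and production envelopes.  All solves go
# through solve_lp(); steady state is always N r = 0 with the network's
# bounds, optional fixed fluxes, and r_i = 0 for knockouts.

.UNBOUNDED_SENTINEL <- 1e3  # serialized in place of +/-Inf in FVA output

.objective_vector <- function(net, objective) {
  n <- length(net$reaction_ids)
  v <- numeric(n)
  if (is.character(objective)) {
    v[.rxn_index(net, objective)] <- 1
  } else if (!is.null(names(objective))) {
    v[.rxn_index(net, names(objective))] <- as.numeric(objective)
  } else {
    stopifnot(length(objective) == n)
    v <- as.numeric(objective)
  }
  v
}

.net_bounds <- function(net, fixed = NULL, knockouts = character()) {
  lb <- net$lower_bound
  ub <- net$upper_bound
  if (length(knockouts)) {
    i <- .rxn_index(net, knockouts)
    lb[i] <- 0
    ub[i] <- 0
  }
  if (!is.null(fixed) && length(fixed)) {
    i <- .rxn_index(net, names(fixed))
    lb[i] <- as.numeric(fixed)
    ub[i] <- as.numeric(fixed)
  }
  list(lb = lb, ub = ub)
}

#' Flux balance analysis
#'
#' Optimizes a linear flux objective subject to \code{N r = 0}, the
#' network bounds, optional fixed fluxes and knockouts.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param objective reaction id, named coefficient vector, or full-length
#'   numeric vector.
#' @param sense \code{"max"} or \code{"min"}.
#' @param fixed named list/vector of fluxes to fix.
#' @param knockouts reaction ids forced to zero flux.
#' @param extraA,extra_sense,extra_rhs optional additional linear rows.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}), \code{objective}, and named \code{fluxes}.
#' @export
fba_optimize <- function(net, objective, sense = c("max", "min"),
                         fixed = NULL, knockouts = character(),
                         extraA = NULL, extra_sense = NULL,
                         extra_rhs = NULL) {
  sense <- match.arg(sense)
  m <- length(net$metabolite_ids)
  A <- net$stoich
  rsense <- rep("=", m)
  rhs <- rep(0, m)
  if (!is.null(extraA)) {
    extraA <- matrix(extraA, ncol = ncol(A))
    A <- rbind(A, extraA)
    rsense <- c(rsense, extra_sense)
    rhs <- c(rhs, extra_rhs)
  }
  bd <- .net_bounds(net, fixed, knockouts)
  res <- solve_lp(.objective_vector(net, objective), A, rsense, rhs,
                  bd$lb, bd$ub, maximize = (sense == "max"))
  if (res$status != "optimal") return(list(status = res$status))
  fl <- res$x
  names(fl) <- net$reaction_ids
  list(status = "optimal", objective = res$objective, fluxes = fl)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux under the FBA constraints.
#' Directions in which the LP is unbounded are reported as the sentinel
#' \code{+/-1e3} rather than infinity.
#'
#' @inheritParams fba_optimize
#' @param reactions reaction ids to scan (default all).
#' @return data.frame with columns \code{reaction}, \code{min}, \code{max}.
#' @export
fva <- function(net, reactions = net$reaction_ids, fixed = NULL,
                knockouts = character(), extraA = NULL,
                extra_sense = NULL, extra_rhs = NULL) {
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    lo <- fba_optimize(net, reactions[k], "min", fixed, knockouts,
                       extraA, extra_sense, extra_rhs)
    hi <- fba_optimize(net, reactions[k], "max", fixed, knockouts,
                       extraA, extra_sense, extra_rhs)
    if (lo$status == "infeasible" || hi$status == "infeasible") {
      stop("FVA on an infeasible model")
    }
    out$min[k] <- if (lo$status == "unbounded") -.UNBOUNDED_SENTINEL else lo$objective
    out$max[k] <- if (hi$status == "unbounded") .UNBOUNDED_SENTINEL else hi$objective
  }
  out
}

#' Achievable yield ranges for ratio objectives
#'
#' For each objective (numerator reaction over a set of denominator
#' reactions) the total denominator flux is fixed to 1 and the numerator
#' minimized/maximized, giving the \code{[min, max]} yield range used to
#' initialize swarm particles.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param objective_ratios list of lists with elements \code{numerator}
#'   (one reaction id) and \code{denominators} (reaction ids).
#' @param knockouts reaction ids forced to zero.
#' @return data.frame with columns \code{numerator}, \code{min}, \code{max}.
#' @export
yield_bounds <- function(net, objective_ratios, knockouts = character()) {
  out <- data.frame(numerator = vapply(objective_ratios, `[[`, "",
                                       "numerator"),
                    min = NA_real_, max = NA_real_, stringsAsFactors = FALSE)
  n <- length(net$reaction_ids)
  for (k in seq_along(objective_ratios)) {
    ob <- objective_ratios[[k]]
    den <- numeric(n)
    den[.rxn_index(net, ob$denominators)] <- 1
    for (s in c("min", "max")) {
      r <- fba_optimize(net, ob$numerator, s, knockouts = knockouts,
                        extraA = den, extra_sense = "=", extra_rhs = 1)
      if (r$status == "infeasible")
        stop("denominator of objective '", ob$numerator,
             "' cannot carry unit flux")
      out[[s]][k] <- if (r$status == "unbounded") {
        if (s == "min") -.UNBOUNDED_SENTINEL else .UNBOUNDED_SENTINEL
      } else r$objective
    }
  }
  out
}

#' Define a linear flux region
#'
#' A polyhedral region \code{A r <= b} over the network's flux space.
#' Rows flagged \code{strict} are interpreted as strict inequalities
#' (\code{A r < b}), which matters both for feasibility checks and for
#' the dual construction.
#'
#' @param A coefficient matrix (rows are constraints).
#' @param b right-hand side.
#' @param strict logical per row.
#' @return object of class \code{linear_region}.
#' @export
linear_region <- function(A, b, strict = rep(FALSE, length(b))) {
  if (!is.matrix(A)) A <- matrix(A, nrow = length(b))
  stopifnot(nrow(A) == length(b), length(strict) == length(b),
            all(is.finite(A)), all(is.finite(b)))
  structure(list(A = A, b = as.numeric(b), strict = as.logical(strict)),
            class = "linear_region")
}

#' Is a linear flux region feasible?
#'
#' Tests whether a flux vector exists satisfying steady state, bounds,
#' knockouts and the region's rows (strict rows strictly).  Strictness is
#' decided by maximizing a common slack margin on the strict rows; the
#' region counts as feasible when the margin exceeds \code{1e-7}.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param region a \code{\link{linear_region}} (may have zero rows).
#' @param knockouts reaction ids forced to zero.
#' @return logical.
#' @export
region_feasible <- function(net, region, knockouts = character()) {
  n <- length(net$reaction_ids)
  m <- length(net$metabolite_ids)
  stopifnot(ncol(region$A) == n)
  bd <- .net_bounds(net, knockouts = knockouts)
  t_rows <- nrow(region$A)
  n_strict <- sum(region$strict)
  if (n_strict == 0L) {
    A <- rbind(net$stoich, region$A)
    res <- solve_lp(numeric(n), A,
                    c(rep("=", m), rep("<=", t_rows)),
                    c(rep(0, m), region$b), bd$lb, bd$ub)
    return(res$status == "optimal")
  }
  # extra variable eps in [0,1]; strict rows become  a.r + eps <= b
  eps_col <- as.numeric(region$strict)
  A <- cbind(rbind(net$stoich, region$A), c(rep(0, m), eps_col))
  obj <- c(numeric(n), 1)
  res <- solve_lp(obj, A, c(rep("=", m), rep("<=", t_rows)),
                  c(rep(0, m), region$b),
                  c(bd$lb, 0), c(bd$ub, 1), maximize = TRUE)
  res$status == "optimal" && res$objective > 1e-7
}

#' Production envelope of a (knockout) strain
#'
#' For \code{n_points} growth values between 0 and the maximal growth
#' flux, computes the FVA minimum and maximum of the product flux; the
#' substrate reference (if given) is fixed to unit total uptake.  The
#' product range on the maximal-growth face is attached as attribute
#' \code{"max_growth_face"}.  With \code{growth = NULL} the envelope
#' degenerates to the single overall product range.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param product product reaction id.
#' @param growth growth/biomass reaction id, or \code{NULL}.
#' @param knockouts reaction ids forced to zero.
#' @param n_points number of growth grid points (>= 2).
#' @param reference reaction ids whose summed flux is fixed to 1.
#' @return data.frame with columns \code{growth}, \code{product_min},
#'   \code{product_max} (rows infeasible at a grid value carry \code{NA}).
#' @export
production_envelope <- function(net, product, growth = NULL,
                                knockouts = character(), n_points = 20L,
                                reference = NULL) {
  n <- length(net$reaction_ids)
  extraA <- NULL
  extra_sense <- NULL
  extra_rhs <- NULL
  if (!is.null(reference)) {
    ref <- numeric(n)
    ref[.rxn_index(net, reference)] <- 1
    extraA <- matrix(ref, 1)
    extra_sense <- "="
    extra_rhs <- 1
  }
  prange <- function(fixed) {
    lo <- fba_optimize(net, product, "min", fixed, knockouts,
                       extraA, extra_sense, extra_rhs)
    hi <- fba_optimize(net, product, "max", fixed, knockouts,
                       extraA, extra_sense, extra_rhs)
    if (lo$status != "optimal" || hi$status != "optimal") return(c(NA, NA))
    c(lo$objective, hi$objective)
  }
  if (is.null(growth)) {
    pr <- prange(NULL)
    out <- data.frame(growth = NA_real_, product_min = pr[1],
                      product_max = pr[2])
    attr(out, "max_growth_face") <- pr
    return(out)
  }
  if (n_points < 2L) stop("n_points must be >= 2")
  gmax <- fba_optimize(net, growth, "max", knockouts = knockouts,
                       extraA = extraA, extra_sense = extra_sense,
                       extra_rhs = extra_rhs)
  if (gmax$status == "infeasible") stop("infeasible model in envelope")
  gtop <- if (gmax$status == "unbounded") .UNBOUNDED_SENTINEL else gmax$objective
  grid <- seq(0, gtop, length.out = n_points)
  out <- data.frame(growth = grid, product_min = NA_real_,
                    product_max = NA_real_)
  for (k in seq_len(n_points)) {
    fx <- list(grid[k])
    names(fx) <- growth
    pr <- prange(fx)
    out$product_min[k] <- pr[1]
    out$product_max[k] <- pr[2]
  }
  fx <- list(gtop)
  names(fx) <- growth
  attr(out, "max_growth_face") <- prange(fx)
  out
}
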