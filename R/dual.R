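# The dual MILP for constrained minimal cut sets.
#
# A knockout set S renders the target region
#     { r : N r = 0, r_i >= 0 (i irreversible), r_i = 0 (i in S), T r <= t }
# infeasible exactly when a Farkas-type certificate exists:
#     N^T u + vp - vn + T^T w  = 0   (reversible rows)
#                              >= 0  (irreversible rows)
#     vp, vn, w >= 0,  support(vp - vn) restricted to S,
# together with a strictness condition on t^T w.  Minimizing the support
# of (vp, vn) with binary indicators zp, zn therefore yields a smallest
# cut set; embedding a primal block N r = 0, D r <= d with the coupling
# r_i = 0 whenever zp_i + zn_i = 1 keeps the desired region alive.
#
# Strict target rows (product yield strictly below the threshold) use the
# full transposition-theorem disjunction, selected by one auxiliary
# binary delta:
#     branch delta = 1:  t^T w <= -c                  (certificate weight
#                                                      on the rhs)
#     branch delta = 0:  t^T w <= 0 and sum of strict-row weights >= c
# The second branch is what certifies infeasibility when the threshold
# sits exactly on the boundary of the feasible yield range.

#' Build the dual MILP for one intervention problem
#'
#' Assembles the block system, indicator linking (big-M), direction
#' exclusivity, flux/knockout coupling, and the cardinality cap into a
#' MILP instance minimizing the knockout support.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param problem an \code{intervention_problem} from
#'   \code{\link{build_intervention}}.
#' @param max_cardinality cap on the cut-set size.
#' @param M big-M constant for indicator linking and dual bounds.  Too
#'   small an M can silently exclude cut sets whose certificates need
#'   large dual weights; the default matches the flux-bound scale.
#' @param c_strict the positive strictness constant (any value > 0 gives
#'   the same supports; fixed to 1).
#' @return object of class \code{dual_milp}: the MILP arrays plus index
#'   maps (\code{vars}, \code{row_groups}) and the originating problem.
#' @export
build_dual <- function(net, problem, max_cardinality = 5L, M = 1e3,
                       c_strict = 1) {
  stopifnot(inherits(problem, "intervention_problem"))
  n <- length(net$reaction_ids)
  m <- length(net$metabolite_ids)
  Tm <- problem$target$A
  tv <- problem$target$b
  strict <- problem$target$strict
  Dm <- problem$desired$A
  dv <- problem$desired$b
  if (ncol(Tm) != n || ncol(Dm) != n)
    stop("region dimensions do not match the network")
  t_rows <- nrow(Tm)
  d_rows <- nrow(Dm)
  if (t_rows < 1L) stop("target region must have at least one row")
  has_strict <- any(strict)

  # variable layout
  iu <- seq_len(m)
  ivp <- m + seq_len(n)
  ivn <- m + n + seq_len(n)
  iw <- m + 2L * n + seq_len(t_rows)
  ir <- m + 2L * n + t_rows + seq_len(n)
  izp <- m + 3L * n + t_rows + seq_len(n)
  izn <- m + 4L * n + t_rows + seq_len(n)
  nv <- m + 5L * n + t_rows
  idelta <- if (has_strict) nv + 1L else integer()
  nv <- nv + length(idelta)

  lb <- numeric(nv)
  ub <- numeric(nv)
  lb[iu] <- -M;            ub[iu] <- M
  lb[ivp] <- 0;            ub[ivp] <- M
  lb[ivn] <- 0;            ub[ivn] <- M
  lb[iw] <- 0;             ub[iw] <- M
  lb[ir] <- net$lower_bound
  ub[ir] <- net$upper_bound
  lb[izp] <- 0;            ub[izp] <- as.numeric(net$knockout_allowed)
  lb[izn] <- 0;            ub[izn] <- as.numeric(net$knockout_allowed)
  if (has_strict) { lb[idelta] <- 0; ub[idelta] <- 1 }

  rows <- list()
  sense <- character()
  rhs <- numeric()
  group <- character()
  add_row <- function(ind, val, sn, rh, gr) {
    row <- numeric(nv)
    row[ind] <- val
    rows[[length(rows) + 1L]] <<- row
    sense[length(sense) + 1L] <<- sn
    rhs[length(rhs) + 1L] <<- rh
    group[length(group) + 1L] <<- gr
  }

  # (a) dual rows, one per reaction
  for (i in seq_len(n)) {
    ind <- c(iu, ivp[i], ivn[i], iw)
    val <- c(net$stoich[, i], 1, -1, Tm[, i])
    add_row(ind, val, if (net$reversible[i]) "=" else ">=", 0, "dual")
  }
  # (b) strictness on t^T w
  if (has_strict) {
    add_row(c(iw, idelta), c(tv, c_strict), "<=", 0, "strict")
    add_row(c(iw[strict], idelta), c(rep(1, sum(strict)), c_strict),
            ">=", c_strict, "strict_aux")
  } else {
    add_row(iw, tv, "<=", -c_strict, "strict")
  }
  # (c) primal steady state
  for (i in seq_len(m)) add_row(ir, net$stoich[i, ], "=", 0, "primal")
  # (d) desired region
  for (i in seq_len(d_rows)) add_row(ir, Dm[i, ], "<=", dv[i], "desired")
  # (e) indicator linking vp <= M zp, vn <= M zn
  for (i in seq_len(n)) {
    add_row(c(ivp[i], izp[i]), c(1, -M), "<=", 0, "link")
    add_row(c(ivn[i], izn[i]), c(1, -M), "<=", 0, "link")
  }
  # (f) direction exclusivity
  for (i in seq_len(n)) add_row(c(izp[i], izn[i]), c(1, 1), "<=", 1, "excl")
  # (g) flux/knockout coupling r_i = 0 if zp_i or zn_i
  for (i in seq_len(n)) {
    if (net$upper_bound[i] > 0)
      add_row(c(ir[i], izp[i], izn[i]),
              c(1, net$upper_bound[i], net$upper_bound[i]),
              "<=", net$upper_bound[i], "couple")
    if (net$lower_bound[i] < 0)
      add_row(c(ir[i], izp[i], izn[i]),
              c(-1, -net$lower_bound[i], -net$lower_bound[i]),
              "<=", -net$lower_bound[i], "couple")
  }
  # (h) cardinality cap
  add_row(c(izp, izn), rep(1, 2L * n), "<=", max_cardinality, "cap")

  obj <- numeric(nv)
  obj[c(izp, izn)] <- 1

  structure(list(obj = obj, A = do.call(rbind, rows), sense = sense,
                 rhs = rhs, lb = lb, ub = ub,
                 binary = c(izp, izn, idelta),
                 vars = list(u = iu, vp = ivp, vn = ivn, w = iw, r = ir,
                             zp = izp, zn = izn, delta = idelta),
                 row_groups = group, net = net, problem = problem,
                 max_cardinality = max_cardinality),
            class = "dual_milp")
}

#' Solve the dual MILP for one cMCS
#'
#' Returns one minimum-cardinality solution of the dual system, after
#' appending a no-good cut \code{sum_{i in S}(zp_i + zn_i) <= |S| - 1}
#' for every previously found cut set in \code{exclusions}.  Iterating
#' with growing exclusions enumerates the minimum-cardinality stratum and
#' eventually reports infeasibility.
#'
#' @param dual a \code{dual_milp} from \code{\link{build_dual}}.
#' @param exclusions list of character vectors (earlier cut sets).
#' @param node_limit branch-and-bound node budget; exceeding it yields
#'   status \code{"budget"}, distinct from \code{"infeasible"}.
#' @return a \code{cutset} object (reactions, cardinality, unvalidated),
#'   or a list with \code{status = "infeasible"} / \code{"budget"}.
#' @export
solve_cmcs <- function(dual, exclusions = list(), node_limit = 200000L) {
  stopifnot(inherits(dual, "dual_milp"))
  A <- dual$A
  sense <- dual$sense
  rhs <- dual$rhs
  net <- dual$net
  for (S in exclusions) {
    i <- .rxn_index(net, S)
    row <- numeric(ncol(A))
    row[dual$vars$zp[i]] <- 1
    row[dual$vars$zn[i]] <- 1
    A <- rbind(A, row)
    sense <- c(sense, "<=")
    rhs <- c(rhs, length(S) - 1)
  }
  res <- solve_milp(dual$obj, A, sense, rhs, dual$lb, dual$ub,
                    dual$binary, node_limit = node_limit,
                    integral_obj = TRUE)
  if (res$status == "budget") return(list(status = "budget"))
  if (res$status != "optimal") return(list(status = "infeasible"))
  z <- res$x[dual$vars$zp] + res$x[dual$vars$zn]
  reactions <- net$reaction_ids[z > 0.5]
  new_cutset(reactions)
}

new_cutset <- function(reactions, valid = NA, minimal = NA,
                       witness_flux = NULL) {
  structure(list(reactions = sort(as.character(reactions)),
                 cardinality = length(reactions),
                 valid = valid, minimal = minimal,
                 witness_flux = witness_flux,
                 status = "solved"),
            class = "cutset")
}

#' @export
print.cutset <- function(x, ...) {
  cat("cut set {", paste(x$reactions, collapse = ", "), "} cardinality ",
      x$cardinality, " valid=", x$valid, " minimal=", x$minimal, "\n",
      sep = "")
  invisible(x)
}

# feasible point of a region under knockouts, or NULL
.region_point <- function(net, region, knockouts = character()) {
  n <- length(net$reaction_ids)
  m <- length(net$metabolite_ids)
  bd <- .net_bounds(net, knockouts = knockouts)
  A <- rbind(net$stoich, region$A)
  res <- solve_lp(numeric(n), A,
                  c(rep("=", m), rep("<=", nrow(region$A))),
                  c(rep(0, m), region$b), bd$lb, bd$ub)
  if (res$status != "optimal") return(NULL)
  fl <- res$x
  names(fl) <- net$reaction_ids
  fl
}

#' Validate a cut set against an intervention problem
#'
#' A cut set is valid when its knockout makes the (strict) target region
#' infeasible while the desired region stays feasible.  Both checks are
#' plain LPs, independent of the dual construction.  A surviving
#' desired-region flux vector is stored as the witness.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param problem an \code{intervention_problem}.
#' @param cs a \code{cutset} (or character vector of reaction ids).
#' @return the \code{cutset} with \code{valid} and \code{witness_flux} set.
#' @export
validate_cutset <- function(net, problem, cs) {
  if (!inherits(cs, "cutset")) cs <- new_cutset(cs)
  target_gone <- !region_feasible(net, problem$target, cs$reactions)
  witness <- .region_point(net, problem$desired, cs$reactions)
  cs$valid <- target_gone && !is.null(witness)
  cs$witness_flux <- witness
  cs
}

#' Check subset-minimality of a valid cut set
#'
#' Removing any single reaction from a minimal cut set must leave the
#' target region feasible (supersets of cut sets still cut, so
#' single-element removal is a sufficient test).
#'
#' @inheritParams validate_cutset
#' @return the \code{cutset} with \code{minimal} set.
#' @export
check_minimality <- function(net, problem, cs) {
  stopifnot(inherits(cs, "cutset"), isTRUE(cs$valid))
  minimal <- TRUE
  for (drop in seq_along(cs$reactions)) {
    sub <- cs$reactions[-drop]
    sub_valid <- !region_feasible(net, problem$target, sub) &&
      region_feasible(net, problem$desired, sub)
    if (sub_valid) { minimal <- FALSE; break }
  }
  cs$minimal <- minimal
  cs
}

#' Enumerate the minimum-cardinality cMCS stratum
#'
#' Repeatedly calls \code{\link{solve_cmcs}} with no-good exclusions until
#' the reported cardinality rises above the first optimum (or the MILP
#' goes infeasible), validating each solution.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param problem an \code{intervention_problem}.
#' @param max_cardinality cap on cut-set size.
#' @param limit safety cap on the number of enumerated sets.
#' @param ... passed to \code{\link{build_dual}}.
#' @return list of validated \code{cutset}s (possibly empty).
#' @export
enumerate_min_cmcs <- function(net, problem, max_cardinality = 5L,
                               limit = 100L, ...) {
  dual <- build_dual(net, problem, max_cardinality, ...)
  found <- list()
  excl <- list()
  first_card <- NULL
  repeat {
    cs <- solve_cmcs(dual, exclusions = excl)
    if (!inherits(cs, "cutset")) break
    if (is.null(first_card)) first_card <- cs$cardinality
    if (cs$cardinality > first_card) break
    cs <- validate_cutset(net, problem, cs)
    if (cs$valid) cs <- check_minimality(net, problem, cs)
    found[[length(found) + 1L]] <- cs
    excl[[length(excl) + 1L]] <- cs$reactions
    if (length(found) >= limit) break
    if (cs$cardinality == 0L) break  # empty cut set: nothing to exclude
  }
  found
}
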