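# Fixtures and ground truth: the small worked-example network, a random
# network generator, and brute-force oracles for cMCS and optimal
# designs.  The oracles only use plain LP feasibility checks, never the
# dual construction, so they are an independent reference for the MILP.

#' The 9-reaction worked-example network
#'
#' Three substrate inputs (R1, R2 feed A and B, R3 feeds A), the product
#' secretion R4 (from A), internal conversions R5: A->C, R6: B->C,
#' R7: B->A, and two byproduct secretions R8 (B) and R9 (C).  Its printed
#' behaviors: the maximal R4 yield on unit total substrate uptake is 1;
#' knocking out \{R2, R9\} blocks all flux through R5 and R6 and forces a
#' guaranteed minimal R4 yield of 1; without knockouts the minimal R4
#' yield is 0.
#'
#' @return a \code{\link{metabolic_network}} with 3 metabolites and 9
#'   reactions, all irreversible.
#' @export
toy_network <- function() {
  rx <- list(
    R1 = c(A = 1),
    R2 = c(B = 1),
    R3 = c(A = 1),
    R4 = c(A = -1),
    R5 = c(A = -1, C = 1),
    R6 = c(B = -1, C = 1),
    R7 = c(B = -1, A = 1),
    R8 = c(B = -1),
    R9 = c(C = -1)
  )
  mets <- c("A", "B", "C")
  S <- matrix(0, 3, length(rx), dimnames = list(mets, names(rx)))
  for (j in seq_along(rx)) S[names(rx[[j]]), j] <- rx[[j]]
  metabolic_network(S, names(rx), mets, reversible = rep(FALSE, length(rx)))
}

#' Design spec of the worked example
#'
#' One-dimensional design: maximize the guaranteed yield of R4 per unit
#' total substrate uptake (R1 + R2 + R3).
#'
#' @return a \code{\link{design_spec}}.
#' @export
toy_design <- function() {
  design_spec(
    objectives = list(list(name = "R4_yield", numerator = "R4",
                           role = "product_min_yield")),
    reference = c("R1", "R2", "R3"))
}

#' Generate a random consistent metabolic network
#'
#' Builds a guaranteed-consistent spine (one uptake exchange, a linear
#' chain through all metabolites, one terminal secretion), adds further
#' secretions and random internal reactions (substrate index < product
#' index, so no internal cycles), and verifies by FBA that unit uptake
#' supports nonzero secretion.  Deterministic per seed; the caller's RNG
#' state is preserved.
#'
#' @param m number of metabolites (>= 2).
#' @param n number of reactions (>= m + 1).
#' @param n_exchange total exchange reactions (1 uptake plus secretions).
#' @param frac_reversible fraction of extra internal reactions drawn
#'   reversible.
#' @param branching probability that an extra internal reaction couples
#'   two substrates or two products.
#' @param seed integer seed.
#' @param max_tries attempts before giving up.
#' @return a \code{\link{metabolic_network}}.
#' @export
generate_random_network <- function(m, n, n_exchange = 3L,
                                    frac_reversible = 0.15,
                                    branching = 0.5, seed = 1L,
                                    max_tries = 50L) {
  stopifnot(m >= 2, n >= m + 1, n_exchange >= 2,
            n >= m + n_exchange - 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  mets <- paste0("M", seq_len(m))
  for (attempt in seq_len(max_tries)) {
    set.seed((seed + 7919L * (attempt - 1L)) %% .Machine$integer.max)
    rxn <- list()
    rev <- logical()
    add <- function(co, r = FALSE) {
      rxn[[length(rxn) + 1L]] <<- co
      rev[length(rev) + 1L] <<- r
    }
    add(c(M1 = 1))                                  # uptake
    for (i in seq_len(m - 1)) {
      co <- c(-1, 1)
      names(co) <- mets[c(i, i + 1)]
      add(co)
    }
    co <- c(-1); names(co) <- mets[m]; add(co)      # spine secretion
    n_sec_extra <- n_exchange - 2L
    if (n_sec_extra > 0) {
      src <- sample(2:m, n_sec_extra, replace = TRUE)
      for (s in src) { co <- c(-1); names(co) <- mets[s]; add(co) }
    }
    # Every metabolite carries an integer weight (think carbon count,
    # non-increasing along the spine so the chain is weight-feasible) and
    # every extra reaction conserves or loses weight (reversibles conserve
    # it exactly).  Weighted mass balance then bounds all yields per unit
    # uptake, ruling out amplifying cycles, while cleavage reactions
    # (a -> b + c) create the obligatory-byproduct structure that makes
    # growth-coupled designs possible at all.
    w <- sort(sample(1:3, m, replace = TRUE), decreasing = TRUE)
    n_extra <- n - length(rxn)
    for (k in seq_len(n_extra)) {
      co <- NULL
      r <- FALSE
      if (runif(1) < branching && m >= 3) {
        for (try in 1:20) {
          picks <- sample(seq_len(m), 3)
          if (runif(1) < 0.5 && w[picks[1]] >= w[picks[2]] + w[picks[3]]) {
            co <- c(-1, 1, 1)               # cleavage a -> b + c
          } else if (w[picks[1]] + w[picks[2]] >= w[picks[3]]) {
            co <- c(-1, -1, 1)              # condensation a + b -> c
          } else next
          names(co) <- mets[picks]
          break
        }
      }
      if (is.null(co)) {                    # conversion a -> b
        for (try in 1:20) {
          picks <- sample(seq_len(m), 2)
          if (w[picks[1]] >= w[picks[2]]) break
        }
        picks <- sort(picks)                # sorted weights: always feasible
        co <- c(-1, 1)
        names(co) <- mets[picks]
        r <- w[picks[1]] == w[picks[2]] && runif(1) < frac_reversible
      }
      add(co, r)
    }
    ids <- paste0("R", seq_along(rxn))
    S <- matrix(0, m, length(rxn), dimnames = list(mets, ids))
    for (j in seq_along(rxn)) S[names(rxn[[j]]), j] <- rxn[[j]]
    net <- metabolic_network(S, ids, mets, rev)
    # consistency: unit uptake must allow nonzero total secretion
    sec <- net$reaction_ids[net$is_exchange][-1]
    obj <- stats::setNames(rep(1, length(sec)), sec)
    r <- fba_optimize(net, obj, "max", fixed = list(R1 = 1))
    if (r$status == "optimal" && r$objective > 1e-6) return(net)
  }
  stop("failed to generate a consistent network in ", max_tries, " tries")
}

#' Brute-force catalogue of minimal valid cut sets
#'
#' Exhaustively tests every knockout-allowed reaction subset of size
#' \code{0..max_k} with the two LP checks of \code{\link{validate_cutset}}
#' (target infeasible, desired feasible), keeping valid subsets that
#' contain no smaller valid subset.  Completely independent of the dual
#' MILP; used as its correctness oracle.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param problem an \code{intervention_problem}.
#' @param max_k maximum subset size.
#' @param guard cap on the number of LP feasibility pairs.
#' @return list of character vectors (each a minimal valid cut set),
#'   ordered by cardinality.
#' @export
brute_force_cmcs <- function(net, problem, max_k, guard = 2e5) {
  cand <- net$reaction_ids[net$knockout_allowed]
  total <- sum(choose(length(cand), 0:max_k))
  if (total > guard)
    stop("subset enumeration would need ", total, " LP pairs (guard ",
         guard, ")")
  is_valid <- function(S) {
    !region_feasible(net, problem$target, S) &&
      region_feasible(net, problem$desired, S)
  }
  found <- list()
  if (is_valid(character())) return(list(character()))
  for (k in seq_len(max_k)) {
    if (k > length(cand)) break
    for (idx in utils::combn(length(cand), k, simplify = FALSE)) {
      S <- cand[idx]
      if (any(vapply(found, function(f) all(f %in% S), TRUE))) next
      if (is_valid(S)) found[[length(found) + 1L]] <- sort(S)
    }
  }
  found
}

#' Brute-force optimal design over a threshold grid
#'
#' Evaluates the design fitness at every point of a per-dimension grid
#' spanning the achievable yield ranges, using
#' \code{\link{brute_force_cmcs}} at each point.  The grid optimum is the
#' recovery target for the particle swarm.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param spec a \code{\link{design_spec}} with \code{j <= 2}.
#' @param grid_points grid resolution per dimension.
#' @param max_k maximum cut-set size.
#' @param guard passed to \code{\link{brute_force_cmcs}}.
#' @return list with \code{x}, \code{cutset}, \code{fitness} of the grid
#'   optimum, the \code{bounds} used, and the full \code{grid} data.frame.
#' @export
brute_force_optimal_design <- function(net, spec, grid_points = 21L,
                                       max_k = 5L, guard = 2e5) {
  stopifnot(spec$j <= 2)
  ratios <- lapply(spec$objectives, function(o)
    list(numerator = o$numerator, denominators = o$denominators))
  bounds <- yield_bounds(net, ratios)
  n <- length(net$reaction_ids)
  axes <- lapply(seq_len(spec$j), function(k)
    seq(bounds$min[k], bounds$max[k], length.out = grid_points))
  grid <- do.call(expand.grid, axes)
  names(grid) <- paste0("x", seq_len(spec$j))
  grid$cardinality <- NA_integer_
  grid$fitness <- 0
  best <- list(x = NULL, cutset = NULL, fitness = -Inf)
  for (i in seq_len(nrow(grid))) {
    x <- as.numeric(grid[i, seq_len(spec$j)])
    problem <- build_intervention(spec, x, net)
    fit <- 0
    cs <- NULL
    if (region_feasible(net, problem$desired)) {
      catalogue <- brute_force_cmcs(net, problem, max_k, guard)
      if (length(catalogue)) {
        sizes <- lengths(catalogue)
        cs <- catalogue[[which.min(sizes)]]
        grid$cardinality[i] <- min(sizes)
        fit <- fitness(x, new_cutset(cs, valid = TRUE),
                       x_max = bounds$max, n = n)
      }
    }
    grid$fitness[i] <- fit
    if (fit > best$fitness + 1e-12) {
      best <- list(x = x, cutset = cs, fitness = fit)
    }
  }
  best$bounds <- bounds
  best$grid <- grid
  best
}
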