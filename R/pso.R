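# Particle swarm over design-threshold space.  Constriction-coefficient
# dynamics, ring-plus-random informant topology, fitness from the dual
# MILP, synchronous iterations, and stagnation-based stopping.

#' Particle swarm configuration
#'
#' Defaults follow common PSO practice: constriction coefficient
#' chi = 0.7298 and acceleration constants phi1 = phi2 = 2.  Swarm size
#' and iteration count are the only problem-specific knobs (the worked
#' example uses 4 particles; 10 particles / 40 iterations is a good
#' default for medium- and genome-scale models).
#'
#' @param n_particles swarm size (>= 2).
#' @param max_iterations iteration cap (0 = initial evaluation only).
#' @param chi constriction coefficient in (0, 1).
#' @param phi1,phi2 cognitive / social acceleration constants (> 0).
#' @param stagnation_window stop after this many iterations without
#'   global-best improvement.
#' @param seed integer seed controlling all randomness of the run.
#' @param max_cardinality cut-set size cap passed to the dual MILP.
#' @param node_limit branch-and-bound budget per MILP solve.
#' @return object of class \code{pso_config}.
#' @export
pso_config <- function(n_particles = 10L, max_iterations = 40L,
                       chi = 0.7298, phi1 = 2, phi2 = 2,
                       stagnation_window = 10L, seed = 1L,
                       max_cardinality = 5L, node_limit = 200000L) {
  stopifnot(n_particles >= 2, max_iterations >= 0,
            chi > 0, chi < 1, phi1 > 0, phi2 > 0,
            stagnation_window >= 1)
  structure(list(n_particles = as.integer(n_particles),
                 max_iterations = as.integer(max_iterations),
                 chi = chi, phi1 = phi1, phi2 = phi2,
                 stagnation_window = as.integer(stagnation_window),
                 seed = as.integer(seed),
                 max_cardinality = as.integer(max_cardinality),
                 node_limit = as.integer(node_limit)),
            class = "pso_config")
}

#' Design fitness of a threshold vector and its cut set
#'
#' \code{F(x) = (1 - |cMCS| / n) * prod_i x_i / x_i(max)}: high
#' guaranteed yields with few knockouts score best.  An infeasible MILP
#' or invalid cut set scores 0.
#'
#' @param x threshold vector (componentwise >= 0).
#' @param cs a \code{cutset}, or anything else to denote infeasibility.
#' @param x_max per-dimension achievable maxima (> 0).
#' @param n reaction count of the network the cut set lives in.
#' @return numeric fitness in [0, 1] whenever \code{x <= x_max}.
#' @export
fitness <- function(x, cs, x_max, n) {
  if (any(x_max <= 0)) stop("degenerate objective: x_max must be > 0")
  if (!inherits(cs, "cutset")) return(0)
  if (!isTRUE(cs$valid) && !is.na(cs$valid)) return(0)
  (1 - cs$cardinality / n) * prod(x / x_max)
}

#' Constriction velocity update
#'
#' \code{v <- chi * (v + phi1 b1 (p - x) + phi2 b2 (g - x))} with
#' \code{b1, b2} uniform in (0, 1] per dimension.
#'
#' @param v current velocity.
#' @param x current position.
#' @param p personal-best position.
#' @param g guide (neighborhood-best) position.
#' @param cfg a \code{\link{pso_config}}.
#' @param beta1,beta2 optional fixed random factors (for testing);
#'   drawn from the RNG when \code{NULL}.
#' @return new velocity vector.
#' @export
update_velocity <- function(v, x, p, g, cfg, beta1 = NULL, beta2 = NULL) {
  j <- length(x)
  if (is.null(beta1)) beta1 <- 1 - stats::runif(j)  # (0, 1]
  if (is.null(beta2)) beta2 <- 1 - stats::runif(j)
  cfg$chi * (v + cfg$phi1 * beta1 * (p - x) + cfg$phi2 * beta2 * (g - x))
}

#' Position update with bound clamping
#'
#' \code{x <- x + v}, then clamped to the per-dimension bounds; clamped
#' dimensions get their velocity zeroed so particles do not push against
#' the wall.
#'
#' @param x position.
#' @param v (already updated) velocity.
#' @param lower,upper per-dimension bounds.
#' @return list with new \code{x} and \code{v}.
#' @export
update_position <- function(x, v, lower, upper) {
  x2 <- x + v
  lo <- x2 < lower
  hi <- x2 > upper
  x2[lo] <- lower[lo]
  x2[hi] <- upper[hi]
  v[lo | hi] <- 0
  list(x = x2, v = v)
}

#' Evaluate one particle position
#'
#' Composes \code{\link{build_intervention}}, \code{\link{build_dual}},
#' \code{\link{solve_cmcs}}, \code{\link{validate_cutset}} and
#' \code{\link{fitness}}.  Results are memoized per position in
#' \code{cache} (the swarm repeatedly revisits clamped corners).
#'
#' @param x threshold vector.
#' @param spec a \code{\link{design_spec}}.
#' @param net a \code{\link{metabolic_network}}.
#' @param cfg a \code{\link{pso_config}}.
#' @param x_max per-dimension yield maxima.
#' @param cache an environment, or \code{NULL} to disable memoization.
#' @return list with \code{cutset} (or \code{NULL}), \code{fitness},
#'   \code{status} (\code{"ok"}, \code{"infeasible"}, \code{"budget"}).
#' @export
evaluate_particle <- function(x, spec, net, cfg, x_max, cache = NULL) {
  key <- paste(signif(x, 12), collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  problem <- build_intervention(spec, x, net)
  dual <- build_dual(net, problem, cfg$max_cardinality)
  cs <- solve_cmcs(dual, node_limit = cfg$node_limit)
  if (!inherits(cs, "cutset")) {
    out <- list(cutset = NULL, fitness = 0, status = cs$status)
  } else {
    cs <- validate_cutset(net, problem, cs)
    out <- list(cutset = cs,
                fitness = fitness(x, cs, x_max, length(net$reaction_ids)),
                status = "ok")
  }
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Run the particle swarm design search
#'
#' Positions are initialized uniformly inside the achievable yield
#' ranges (computed by \code{\link{yield_bounds}}), velocities uniformly
#' in +/- the range width.  Each particle's guide is the best personal
#' best among itself, its four fixed ring neighbours (indices +/-1, +/-2
#' modulo swarm size) and one random informant redrawn every iteration.
#' Iterations are synchronous: all evaluations, then all updates.  The
#' run stops at \code{max_iterations} or after
#' \code{stagnation_window} iterations without global-best improvement.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param spec a \code{\link{design_spec}}.
#' @param cfg a \code{\link{pso_config}}.
#' @param bounds optional precomputed \code{\link{yield_bounds}} result.
#' @return object of class \code{design_result}: global best position
#'   \code{g}, \code{g_fitness}, \code{best_cutset}, non-decreasing
#'   \code{fitness_trace}, an \code{evaluations} data.frame and the MILP
#'   call log.
#' @export
run_pso <- function(net, spec, cfg, bounds = NULL) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(cfg$seed)
  j <- spec$j
  if (is.null(bounds)) {
    ratios <- lapply(spec$objectives, function(o)
      list(numerator = o$numerator, denominators = o$denominators))
    bounds <- yield_bounds(net, ratios)
  }
  lower <- bounds$min
  upper <- bounds$max
  width <- upper - lower
  np <- cfg$n_particles

  W <- matrix(width, np, j, byrow = TRUE)
  X <- matrix(lower, np, j, byrow = TRUE) +
    matrix(stats::runif(np * j), np, j) * W
  V <- matrix(stats::runif(np * j, -1, 1), np, j) * W
  P <- X
  p_fit <- rep(-Inf, np)
  p_cut <- vector("list", np)
  ring <- lapply(seq_len(np), function(i)
    unique(((i + c(-2, -1, 1, 2) - 1) %% np) + 1))

  cache <- new.env(parent = emptyenv())
  log_rows <- list()
  evals <- list()
  eval_all <- function(iter) {
    for (i in seq_len(np)) {
      r <- evaluate_particle(X[i, ], spec, net, cfg, upper, cache)
      card <- if (!is.null(r$cutset)) r$cutset$cardinality else NA_integer_
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        iteration = iter, particle = i,
        position = paste(signif(X[i, ], 8), collapse = ","),
        status = r$status, cardinality = card, fitness = r$fitness)
      evals[[length(evals) + 1L]] <<- list(x = X[i, ], cutset = r$cutset,
                                           fitness = r$fitness)
      if (r$fitness > p_fit[i]) {
        p_fit[i] <<- r$fitness
        P[i, ] <<- X[i, ]
        p_cut[[i]] <<- r$cutset
      }
    }
  }

  eval_all(0L)
  gi <- which.max(p_fit)
  g_fit <- p_fit[gi]
  g_pos <- P[gi, ]
  g_cut <- p_cut[[gi]]
  trace <- g_fit
  stagnant <- 0L

  iter <- 0L
  while (iter < cfg$max_iterations) {
    iter <- iter + 1L
    for (i in seq_len(np)) {
      informants <- c(i, ring[[i]], sample(np, 1))
      guide <- informants[which.max(p_fit[informants])]
      V[i, ] <- update_velocity(V[i, ], X[i, ], P[i, ], P[guide, ], cfg)
      upd <- update_position(X[i, ], V[i, ], lower, upper)
      X[i, ] <- upd$x
      V[i, ] <- upd$v
    }
    eval_all(iter)
    gi <- which.max(p_fit)
    if (p_fit[gi] > g_fit + 1e-12) {
      g_fit <- p_fit[gi]
      g_pos <- P[gi, ]
      g_cut <- p_cut[[gi]]
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    trace <- c(trace, g_fit)
    if (stagnant >= cfg$stagnation_window) break
  }

  structure(list(g = g_pos, g_fitness = g_fit, best_cutset = g_cut,
                 fitness_trace = trace,
                 evaluations = evals,
                 milp_log = do.call(rbind, log_rows),
                 bounds = bounds, config = cfg),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("design result: best fitness", format(x$g_fitness, digits = 6),
      "at x = (", paste(signif(x$g, 6), collapse = ", "), ")\n")
  if (!is.null(x$best_cutset)) print(x$best_cutset)
  cat("iterations:", length(x$fitness_trace) - 1L,
      " MILP calls:", nrow(x$milp_log), "\n")
  invisible(x)
}
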