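# Network reduction and compression.
#
# reduce_to_condition() closes uptake exchanges outside a growth medium and
# strips blocked reactions; compress_subsets() merges reactions whose
# steady-state fluxes are proportional (detected from the null space of N)
# into single columns; apply_knockout_exclusions() narrows the set of
# knockout candidates the dual MILP may use.

.BLOCKED_TOL <- 1e-9   # |flux| below this across FVA counts as blocked
.SUBSET_TOL <- 1e-8    # relative tolerance for null-space proportionality

#' Reduce a network to a growth condition
#'
#' Closes the uptake direction of every exchange reaction outside
#' \code{medium}, then removes reactions that can no longer carry any flux
#' (FVA range numerically \code{[0,0]}) together with orphaned
#' metabolites.  Reversibility flags are tightened to match the new
#' bounds so downstream dual constructions see correct sign constraints.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param medium character vector of exchange reaction ids kept open.
#' @return the reduced \code{\link{metabolic_network}}.
#' @export
reduce_to_condition <- function(net, medium) {
  i_med <- .rxn_index(net, medium)
  if (any(!net$is_exchange[i_med]))
    stop("medium contains non-exchange reaction(s): ",
         paste(medium[!net$is_exchange[i_med]], collapse = ", "))
  for (j in which(net$is_exchange)) {
    if (j %in% i_med) next
    sigma <- net$stoich[which(net$stoich[, j] != 0), j]
    if (sigma > 0) net$upper_bound[j] <- min(net$upper_bound[j], 0)
    else net$lower_bound[j] <- max(net$lower_bound[j], 0)
  }
  net$reversible <- net$reversible & net$lower_bound < 0
  ranges <- fva(net)
  keep <- !(abs(ranges$min) < .BLOCKED_TOL & abs(ranges$max) < .BLOCKED_TOL)
  if (!any(keep)) {
    # nothing can carry flux: return an empty network shell
    return(structure(list(
      stoich = net$stoich[0, 0, drop = FALSE], reaction_ids = character(),
      metabolite_ids = character(), reversible = logical(),
      lower_bound = numeric(), upper_bound = numeric(),
      is_exchange = logical(), is_spontaneous = logical(),
      knockout_allowed = logical()), class = "metabolic_network"))
  }
  .subset_network(net, which(keep))
}

#' Compress proportional reactions into subsets
#'
#' Reactions whose fluxes are proportional in every steady-state solution
#' (their rows in a null-space basis of \code{N} are parallel) are merged
#' into a single column.  The merged column is \code{sum_j c_j N[, j]}
#' where \code{r_j = c_j q} is the fixed flux ratio to the subset
#' representative; bounds are intersected accordingly.  A subset is
#' knockout-allowed if at least one member is, and spontaneous only if
#' every member is.
#'
#' @param net a \code{\link{metabolic_network}} with no blocked reactions.
#' @return list with elements \code{network} (compressed) and \code{map}
#'   (a \code{compression_map}: per compressed reaction the original
#'   member ids and scaling coefficients).
#' @export
compress_subsets <- function(net) {
  n <- length(net$reaction_ids)
  K <- .null_space(net$stoich)
  if (ncol(K) == 0L)
    stop("network admits only the zero flux vector; nothing to compress")
  nrm <- sqrt(rowSums(K^2))
  if (any(nrm < .SUBSET_TOL))
    stop("blocked reaction(s) present; reduce the network first: ",
         paste(net$reaction_ids[nrm < .SUBSET_TOL], collapse = ", "))
  group <- integer(n)
  coef <- numeric(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (group[i] != 0L) next
    g <- g + 1L
    group[i] <- g
    coef[i] <- 1
    for (j in seq_len(n)) {
      if (group[j] != 0L) next
      cosang <- sum(K[i, ] * K[j, ]) / (nrm[i] * nrm[j])
      if (abs(abs(cosang) - 1) < .SUBSET_TOL) {
        group[j] <- g
        coef[j] <- sum(K[j, ] * K[i, ]) / sum(K[i, ]^2)  # r_j = coef * r_i
      }
    }
  }
  n_new <- g
  S <- matrix(0, length(net$metabolite_ids), n_new)
  ids <- character(n_new)
  lb <- numeric(n_new)
  ub <- numeric(n_new)
  rev <- logical(n_new)
  spont <- logical(n_new)
  ko <- logical(n_new)
  exch <- logical(n_new)
  subsets <- vector("list", n_new)
  for (k in seq_len(n_new)) {
    mem <- which(group == k)
    cvec <- coef[mem]
    S[, k] <- net$stoich[, mem, drop = FALSE] %*% cvec
    ids[k] <- paste(net$reaction_ids[mem], collapse = "/")
    qlb <- -Inf
    qub <- Inf
    for (t in seq_along(mem)) {
      b1 <- net$lower_bound[mem[t]] / cvec[t]
      b2 <- net$upper_bound[mem[t]] / cvec[t]
      qlb <- max(qlb, min(b1, b2))
      qub <- min(qub, max(b1, b2))
    }
    lb[k] <- qlb
    ub[k] <- qub
    rev[k] <- qlb < 0
    spont[k] <- all(net$is_spontaneous[mem])
    ko[k] <- any(net$knockout_allowed[mem])
    exch[k] <- any(net$is_exchange[mem])
    subsets[[k]] <- data.frame(reaction = net$reaction_ids[mem],
                               coef = cvec,
                               knockout_allowed = net$knockout_allowed[mem],
                               stringsAsFactors = FALSE)
  }
  keep_met <- rowSums(abs(S) > .SUBSET_TOL) > 0
  S[abs(S) < .SUBSET_TOL] <- 0
  cnet <- metabolic_network(S[keep_met, , drop = FALSE], ids,
                            net$metabolite_ids[keep_met], rev, lb, ub,
                            spont, ko)
  cnet$is_exchange <- exch  # structural detection can mislabel merged columns
  names(subsets) <- ids
  map <- structure(list(subset_members = subsets,
                        removed_blocked = character()),
                   class = "compression_map")
  list(network = cnet, map = map)
}

.null_space <- function(N, tol = 1e-10) {
  if (nrow(N) == 0L) return(diag(ncol(N)))
  s <- svd(N, nu = 0, nv = ncol(N))
  d <- s$d
  rank <- sum(d > tol * max(d, 1))
  if (rank >= ncol(N)) return(matrix(0, ncol(N), 0))
  s$v[, (rank + 1):ncol(N), drop = FALSE]
}

#' Translate a linear objective to a compressed network
#'
#' Given coefficients over original reactions, returns the equivalent
#' named coefficients over compressed reactions (using the fixed flux
#' ratios of each subset).
#'
#' @param map a \code{compression_map}.
#' @param v named numeric vector over original reaction ids.
#' @return named numeric vector over compressed reaction ids.
#' @export
compress_objective <- function(map, v) {
  out <- vapply(map$subset_members, function(df) {
    sum(df$coef * ifelse(df$reaction %in% names(v), v[df$reaction], 0))
  }, 0)
  out[out != 0]
}

#' Expand a compressed cut set to original reactions
#'
#' Each compressed reaction in the cut set is replaced by its first
#' knockout-allowed member (knocking out any one member silences the
#' whole subset, since member fluxes are proportional).
#'
#' @param map a \code{compression_map}.
#' @param reactions compressed reaction ids.
#' @return character vector of original reaction ids.
#' @export
decompress_cutset <- function(map, reactions) {
  vapply(reactions, function(id) {
    df <- map$subset_members[[id]]
    if (is.null(df)) return(id)  # identity-mapped
    cand <- df$reaction[df$knockout_allowed]
    if (!length(cand)) cand <- df$reaction
    cand[1]
  }, "", USE.NAMES = FALSE)
}

#' Exclude reactions from knockout consideration
#'
#' Marks as non-knockable: exchange reactions, spontaneous reactions, an
#' explicit extra list, and every reaction whose single knockout forces
#' the maximal flux of any protected reaction below \code{threshold}
#' (essentiality, decided by one LP per reaction and protected target).
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param extra_excluded reaction ids to exclude unconditionally.
#' @param protect_essential_for reaction ids whose producibility must
#'   survive any allowed knockout.
#' @param reference optional reaction ids whose summed flux is fixed to 1
#'   during the essentiality LPs (unit substrate uptake).
#' @param threshold essentiality cutoff on the protected maximal flux.
#' @return the network with \code{knockout_allowed} narrowed.
#' @export
apply_knockout_exclusions <- function(net, extra_excluded = character(),
                                      protect_essential_for = character(),
                                      reference = NULL, threshold = 1e-6) {
  ko <- net$knockout_allowed
  ko[net$is_exchange] <- FALSE
  ko[net$is_spontaneous] <- FALSE
  if (length(extra_excluded)) ko[.rxn_index(net, extra_excluded)] <- FALSE
  if (length(protect_essential_for)) {
    .rxn_index(net, protect_essential_for)
    extraA <- NULL
    extra_sense <- NULL
    extra_rhs <- NULL
    if (!is.null(reference)) {
      ref <- numeric(length(net$reaction_ids))
      ref[.rxn_index(net, reference)] <- 1
      extraA <- matrix(ref, 1)
      extra_sense <- "="
      extra_rhs <- 1
    }
    for (p in protect_essential_for) {
      for (j in seq_along(net$reaction_ids)) {
        if (!ko[j]) next
        r <- fba_optimize(net, p, "max", knockouts = net$reaction_ids[j],
                          extraA = extraA, extra_sense = extra_sense,
                          extra_rhs = extra_rhs)
        if (r$status == "infeasible" ||
            (r$status == "optimal" && r$objective < threshold)) {
          ko[j] <- FALSE
        }
      }
    }
  }
  net$knockout_allowed <- ko
  net
}
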