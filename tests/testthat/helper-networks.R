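# Shared fixtures built in code.

# uptake -> M1 -> ... -> Mk -> secretion; returns the network and the ids
chain_network <- function(k = 2L) {
  mets <- paste0("M", seq_len(k))
  ids <- c("R_up", paste0("R_int", seq_len(k - 1)), "R_out")
  S <- matrix(0, k, k + 1, dimnames = list(mets, ids))
  S[1, 1] <- 1
  for (i in seq_len(k - 1)) {
    S[i, i + 1] <- -1
    S[i + 1, i + 1] <- 1
  }
  S[k, k + 1] <- -1
  metabolic_network(S, ids, mets, reversible = rep(FALSE, k + 1))
}

# uptake -> A, two parallel routes A -> B -> P and A -> C -> P, P ->
diamond_network <- function() {
  mets <- c("A", "B", "C", "P")
  ids <- c("R_up", "R_ab", "R_ac", "R_bp", "R_cp", "R_out")
  S <- matrix(0, 4, 6, dimnames = list(mets, ids))
  S["A", "R_up"] <- 1
  S["A", "R_ab"] <- -1; S["B", "R_ab"] <- 1
  S["A", "R_ac"] <- -1; S["C", "R_ac"] <- 1
  S["B", "R_bp"] <- -1; S["P", "R_bp"] <- 1
  S["C", "R_cp"] <- -1; S["P", "R_cp"] <- 1
  S["P", "R_out"] <- -1
  metabolic_network(S, ids, mets, reversible = rep(FALSE, 6))
}

# a single-product design over a random network's first uptake; the
# product is the last secretion (the spine terminus exists by construction)
random_design_instance <- function(seed, m = 6L, n = 10L, n_exchange = 3L,
                                   ...) {
  net <- generate_random_network(m, n, n_exchange, seed = seed, ...)
  sec <- net$reaction_ids[net$is_exchange][-1]
  spec <- design_spec(list(list(name = "prod", numerator = sec[length(sec)],
                                role = "product_min_yield")),
                      reference = "R1")
  list(net = net, spec = spec, product = sec[length(sec)])
}

# target region "unit uptake and strictly positive flux through rxn"
positive_flux_problem <- function(net, rxn, uptake) {
  n <- length(net$reaction_ids)
  s <- numeric(n)
  s[match(uptake, net$reaction_ids)] <- 1
  p <- numeric(n)
  p[match(rxn, net$reaction_ids)] <- 1
  structure(list(
    target = linear_region(rbind(s, -s, -p), c(1, -1, 0),
                           c(FALSE, FALSE, TRUE)),
    desired = linear_region(matrix(0, 0, n), numeric(0)),
    x = NA_real_), class = "intervention_problem")
}

new_cutset_for_test <- function(card) {
  structure(list(reactions = paste0("K", seq_len(card)),
                 cardinality = card, valid = TRUE, minimal = NA,
                 witness_flux = NULL, status = "solved"),
            class = "cutset")
}

named_row <- function(net, v) {
  x <- numeric(length(net$reaction_ids))
  x[match(names(v), net$reaction_ids)] <- v
  x
}

lp_oracle_script <- function() {
  system.file("oracle", "lp_oracle.py", package = "psomcs")
}

toy_min_stratum <- list(c("R2", "R5"), c("R2", "R9"), c("R8", "R9"))

# FVA minimum of R4 on the toy network at unit total uptake under knockouts
toy_min_yield <- function(net, knockouts) {
  r <- fba_optimize(net, "R4", "min", knockouts = knockouts,
                    extraA = as.numeric(net$reaction_ids %in%
                                          c("R1", "R2", "R3")),
                    extra_sense = "=", extra_rhs = 1)
  if (r$status != "optimal") return(NA_real_)
  r$objective
}
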