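test_that("the dual instance has the block structure's dimensions", {
  net <- toy_network()
  pr <- build_intervention(toy_design(), 0.8, net)
  dual <- build_dual(net, pr, 5)
  n <- 9L; m <- 3L
  t_rows <- nrow(pr$target$A)
  d_rows <- nrow(pr$desired$A)
  # continuous block: u (m) + vp,vn (2n) + w (t_rows) + r (n)
  expect_length(dual$vars$u, m)
  expect_length(dual$vars$vp, n)
  expect_length(dual$vars$vn, n)
  expect_length(dual$vars$w, t_rows)
  expect_length(dual$vars$r, n)
  expect_length(dual$binary, 2L * n + 1L)  # zp, zn + strictness selector
  # block rows: n dual + m primal + d_rows desired + 1 strictness
  expect_identical(sum(dual$row_groups == "dual"), n)
  expect_identical(sum(dual$row_groups == "primal"), m)
  expect_identical(sum(dual$row_groups == "desired"), d_rows)
  expect_identical(sum(dual$row_groups == "strict"), 1L)
})

test_that("knockout-excluded reactions have their indicators fixed to zero", {
  net <- toy_network()
  net$knockout_allowed[net$reaction_ids %in% c("R2", "R9")] <- FALSE
  pr <- build_intervention(toy_design(), 0.8, net)
  dual <- build_dual(net, pr, 5)
  i <- match(c("R2", "R9"), net$reaction_ids)
  expect_equal(dual$ub[dual$vars$zp[i]], c(0, 0))
  expect_equal(dual$ub[dual$vars$zn[i]], c(0, 0))
})

test_that("a zero cardinality cap with a nonempty undesired region is infeasible", {
  net <- toy_network()
  pr <- build_intervention(toy_design(), 0.8, net)
  cs <- solve_cmcs(build_dual(net, pr, 0L))
  expect_identical(cs$status, "infeasible")
})

test_that("chain with positive-product target and free desired region: any singleton cuts", {
  net <- chain_network(2)
  pr <- positive_flux_problem(net, "R_out", "R_up")
  oracle <- brute_force_cmcs(net, pr, 3)
  expect_identical(sort(lengths(oracle)), rep(1L, 3L))
  found <- enumerate_min_cmcs(net, pr, 3)
  expect_setequal(vapply(found, function(cs) cs$reactions, ""),
                  unlist(oracle))
  expect_true(all(vapply(found, function(cs) cs$valid, TRUE)))
})

test_that("the worked example's dual MILP at x = 1 returns the printed cut set", {
  net <- toy_network()
  pr <- build_intervention(toy_design(), 1, net)
  dual <- build_dual(net, pr, 5)
  cs <- solve_cmcs(dual)
  expect_identical(cs$cardinality, 2L)
  expect_identical(cs$reactions, c("R2", "R9"))
  # excluding it yields a different set of cardinality >= 2
  cs2 <- solve_cmcs(dual, exclusions = list(cs$reactions))
  expect_gte(cs2$cardinality, 2L)
  expect_false(setequal(cs2$reactions, cs$reactions))
})

test_that("validation and minimality flags follow the two-LP semantics", {
  net <- toy_network()
  pr <- build_intervention(toy_design(), 1, net)
  # empty cut set with a nonempty undesired region
  expect_false(validate_cutset(net, pr, character())$valid)
  cs <- validate_cutset(net, pr, c("R2", "R9"))
  expect_true(cs$valid)
  expect_equal(unname(cs$witness_flux["R4"]), 1, tolerance = 1e-7)
  expect_true(check_minimality(net, pr, cs)$minimal)
  # a padded superset is valid but not minimal
  pad <- validate_cutset(net, pr, c("R2", "R9", "R5"))
  expect_true(pad$valid)
  expect_false(check_minimality(net, pr, pad)$minimal)
  # a cut that also kills the desired region is a plain MCS, not a cMCS
  allcut <- validate_cutset(net, pr, c("R1", "R2", "R3"))
  expect_false(allcut$valid)
})

test_that("MILP solutions agree with the brute-force oracle on random designs", {
  # smaller rehearsal of the acceptance-scale equivalence: every MILP
  # solution is valid and minimal, cardinalities match the oracle, and
  # no-good exhaustion recovers the full minimum stratum
  set.seed(99)
  for (s in 1:8) {
    m <- sample(4:8, 1)
    n <- sample((m + 2):12, 1)
    inst <- random_design_instance(s, m = m, n = n)
    yb <- yield_bounds(inst$net, list(list(numerator = inst$product,
                                           denominators = "R1")))
    if (yb$max[1] <= 1e-6) next
    x <- yb$min[1] + 0.7 * (yb$max[1] - yb$min[1])
    pr <- build_intervention(inst$spec, x, inst$net)
    oracle <- brute_force_cmcs(inst$net, pr, 4)
    found <- enumerate_min_cmcs(inst$net, pr, 4)
    if (!length(oracle)) {
      expect_length(found, 0L)
      next
    }
    o_min <- min(lengths(oracle))
    expect_identical(found[[1]]$cardinality, o_min,
                     label = paste("seed", s))
    expect_setequal(
      vapply(found, function(cs) paste(cs$reactions, collapse = ","), ""),
      vapply(Filter(function(S) length(S) == o_min, oracle),
             paste, "", collapse = ","))
    expect_true(all(vapply(found, function(cs)
      isTRUE(cs$valid) && isTRUE(cs$minimal), TRUE)),
      label = paste("seed", s))
  }
})
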