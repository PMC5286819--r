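test_that("FBA conserves mass along a chain and reports knockouts distinctly", {
  net <- chain_network(2)
  r <- fba_optimize(net, "R_out", "max", fixed = list(R_up = 1))
  expect_identical(r$status, "optimal")
  expect_equal(r$objective, 1)
  expect_equal(unname(r$fluxes["R_int1"]), 1)
  # knocking out the internal step with uptake still forced to 1
  r2 <- fba_optimize(net, "R_out", "max", fixed = list(R_up = 1),
                     knockouts = "R_int1")
  expect_identical(r2$status, "infeasible")
  # with free uptake the optimum collapses to 0 instead
  r3 <- fba_optimize(net, "R_out", "max", knockouts = "R_int1")
  expect_equal(r3$objective, 0)
})

test_that("maximal R4 yield of the worked example is 1", {
  net <- toy_network()
  yb <- yield_bounds(net, list(list(numerator = "R4",
                                    denominators = c("R1", "R2", "R3"))))
  expect_equal(yb$max, 1)
  expect_equal(yb$min, 0)
})

test_that("yield bounds: single-route network has min = max; dead denominators error", {
  net <- chain_network(3)
  yb <- yield_bounds(net, list(list(numerator = "R_out",
                                    denominators = "R_up")))
  expect_equal(yb$min, yb$max)
  expect_equal(yb$max, 1)
  expect_error(
    yield_bounds(net, list(list(numerator = "R_up",
                                denominators = "R_out")),
                 knockouts = "R_int1"),
    "cannot carry")
})

test_that("yield bounds bracket the yields of random feasible flux vectors", {
  set.seed(31)
  for (s in 1:5) {
    inst <- random_design_instance(s)
    net <- inst$net
    yb <- yield_bounds(net, list(list(numerator = inst$product,
                                      denominators = "R1")))
    n <- length(net$reaction_ids)
    for (k in 1:4) {  # random LP vertices of the unit-uptake polytope
      obj <- rnorm(n)
      r <- fba_optimize(net, obj, "max", fixed = list(R1 = 1))
      if (r$status != "optimal") next
      y <- unname(r$fluxes[inst$product])
      expect_gte(y, yb$min - 1e-7)
      expect_lte(y, yb$max + 1e-7)
    }
  }
})

test_that("region feasibility matches the region semantics", {
  net <- toy_network()
  n <- length(net$reaction_ids)
  # empty region on a consistent network
  expect_true(region_feasible(net, linear_region(matrix(0, 0, n),
                                                 numeric(0))))
  # unit uptake after knocking out all uptakes
  s <- as.numeric(net$reaction_ids %in% c("R1", "R2", "R3"))
  norm_only <- linear_region(rbind(s, -s), c(1, -1))
  expect_true(region_feasible(net, norm_only))
  expect_false(region_feasible(net, norm_only,
                               knockouts = c("R1", "R2", "R3")))
  # strictly sub-maximal R4 yield is impossible once R2, R9 are cut
  spec <- toy_design()
  pr <- build_intervention(spec, 1, net)
  expect_true(region_feasible(net, pr$target))
  expect_false(region_feasible(net, pr$target, knockouts = c("R2", "R9")))
})

test_that("FVA ranges sandwich random feasible solutions and use the unbounded sentinel", {
  set.seed(55)
  inst <- random_design_instance(3)
  net <- inst$net
  ranges <- fva(net, fixed = list(R1 = 1))
  n <- length(net$reaction_ids)
  for (k in 1:5) {
    r <- fba_optimize(net, rnorm(n), "max", fixed = list(R1 = 1))
    if (r$status != "optimal") next
    expect_true(all(r$fluxes >= ranges$min - 1e-6))
    expect_true(all(r$fluxes <= ranges$max + 1e-6))
  }
  # a two-reaction futile cycle is unbounded: sentinel, not Inf
  mets <- "A"
  S <- matrix(c(1, -1, 1, -1), 1, 4,
              dimnames = list(mets, c("R_up", "R_f", "R_b", "R_out")))
  S[1, ] <- c(1, -1, 1, -1)
  loopnet <- metabolic_network(S, c("R_up", "R_f", "R_b", "R_out"), mets,
                               rep(FALSE, 4),
                               upper_bound = rep(Inf, 4))
  rng <- fva(loopnet, reactions = c("R_f", "R_b"), fixed = list(R_up = 1))
  expect_equal(rng$max, c(1e3, 1e3))
})

test_that("production envelopes: coupling, wild-type slack, monotone closure", {
  net <- toy_network()
  ref <- c("R1", "R2", "R3")
  # fully coupled knockout strain: min = max = 1 at unit uptake
  env <- production_envelope(net, "R4", growth = NULL,
                             knockouts = c("R2", "R9"), reference = ref)
  expect_equal(env$product_min, 1)
  expect_equal(env$product_max, 1)
  # wild type has alternative sinks: product min 0
  env0 <- production_envelope(net, "R4", growth = NULL, reference = ref)
  expect_equal(env0$product_min, 0)
  expect_equal(env0$product_max, 1)
  # grid form: envelope area never grows when knockouts are added
  env_wt <- production_envelope(net, "R4", growth = "R8", n_points = 5,
                                reference = ref)
  env_ko <- production_envelope(net, "R4", growth = "R8", n_points = 5,
                                knockouts = "R5", reference = ref)
  # compare on the shared feasible growth values of the knockout strain
  for (i in seq_len(nrow(env_ko))) {
    g <- env_ko$growth[i]
    if (is.na(env_ko$product_min[i]) || g > max(env_wt$growth)) next
    wt_min <- approx(env_wt$growth, env_wt$product_min, g)$y
    wt_max <- approx(env_wt$growth, env_wt$product_max, g)$y
    expect_gte(env_ko$product_min[i], wt_min - 1e-6)
    expect_lte(env_ko$product_max[i], wt_max + 1e-6)
  }
})

test_that("doubling a metabolite row leaves yield bounds unchanged", {
  inst <- random_design_instance(8)
  net <- inst$net
  ratios <- list(list(numerator = inst$product, denominators = "R1"))
  yb1 <- yield_bounds(net, ratios)
  net2 <- net
  net2$stoich[2, ] <- 2 * net2$stoich[2, ]
  yb2 <- yield_bounds(net2, ratios)
  expect_equal(yb1$min, yb2$min, tolerance = 1e-9)
  expect_equal(yb1$max, yb2$max, tolerance = 1e-9)
})
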