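test_that("closing an uptake removes the branch it feeds", {
  net <- toy_network()
  red <- reduce_to_condition(net, c("R1", "R3", "R4", "R8", "R9"))
  # R2 closed: B unreachable, so R6, R7, R8 die with it; C still fed by R5
  expect_setequal(red$reaction_ids, c("R1", "R3", "R4", "R5", "R9"))
  expect_false("B" %in% red$metabolite_ids)
  # feasibility maps back: any reduced flux is feasible in the closed parent
  r <- fba_optimize(red, "R4", "max", fixed = list(R1 = 1))
  full <- fba_optimize(net, "R4", "max",
                       fixed = as.list(c(R1 = 1, R2 = 0)))
  expect_equal(r$objective, full$objective)
})

test_that("keeping every exchange open changes nothing; an empty medium kills everything", {
  net <- toy_network()
  red <- reduce_to_condition(net, net$reaction_ids[net$is_exchange])
  expect_identical(red$reaction_ids, net$reaction_ids)
  red0 <- reduce_to_condition(net, character())
  expect_length(red0$reaction_ids, 0L)
  expect_error(reduce_to_condition(net, "R99"), "unknown reaction")
  expect_error(reduce_to_condition(net, "R5"), "non-exchange")
})

test_that("proportional reactions merge into subsets; branch points do not", {
  # spine with a branch: R_up -> A, A -> B -> C -> out, plus A -> out2
  mets <- c("A", "B", "C")
  ids <- c("R_up", "R1", "R2", "R_out", "R_alt")
  S <- matrix(0, 3, 5, dimnames = list(mets, ids))
  S["A", "R_up"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "R2"] <- -1; S["C", "R2"] <- 1
  S["C", "R_out"] <- -1
  S["A", "R_alt"] <- -1
  net <- metabolic_network(S, ids, mets, rep(FALSE, 5))
  cm <- compress_subsets(net)
  sizes <- vapply(cm$map$subset_members, nrow, 0L)
  expect_setequal(unname(sizes), c(1L, 3L, 1L))        # {R1,R2,R_out} merge
  merged <- names(sizes)[sizes == 3L]
  expect_setequal(cm$map$subset_members[[merged]]$reaction,
                  c("R1", "R2", "R_out"))
  expect_equal(cm$map$subset_members[[merged]]$coef, c(1, 1, 1))
  # decompression picks a representative member
  expect_true(decompress_cutset(cm$map, merged) %in% c("R1", "R2", "R_out"))
})

test_that("compression preserves FBA optima on random networks", {
  set.seed(17)
  for (s in 1:20) {
    m_s <- sample(4:7, 1)
    inst <- random_design_instance(s, m = m_s, n = sample((m_s + 3):12, 1))
    net <- reduce_to_condition(inst$net,
                               inst$net$reaction_ids[inst$net$is_exchange])
    if (!inst$product %in% net$reaction_ids) next
    cm <- tryCatch(compress_subsets(net), error = function(e) NULL)
    if (is.null(cm)) next
    obj <- stats::setNames(1, inst$product)
    cobj <- compress_objective(cm$map, obj)
    uref <- compress_objective(cm$map, c(R1 = 1))
    r1 <- fba_optimize(net, obj, "max", fixed = list(R1 = 1))
    r2 <- fba_optimize(cm$network, cobj, "max",
                       extraA = named_row(cm$network, uref),
                       extra_sense = "=", extra_rhs = 1)
    expect_identical(r1$status, r2$status, label = paste("seed", s))
    if (r1$status == "optimal")
      expect_equal(r1$objective, r2$objective, tolerance = 1e-7,
                   label = paste("seed", s))
  }
})

test_that("knockout exclusions: chains are all essential, diamonds are not", {
  net <- chain_network(2)
  exc <- apply_knockout_exclusions(net, protect_essential_for = "R_out")
  expect_false(any(exc$knockout_allowed))
  dia <- diamond_network()
  exc2 <- apply_knockout_exclusions(dia, protect_essential_for = "R_out")
  # both parallel branches stay knockable, exchanges and shared steps do not
  expect_setequal(dia$reaction_ids[exc2$knockout_allowed],
                  c("R_ab", "R_ac", "R_bp", "R_cp"))
  # with no protections, only exchanges (and spontaneous) are excluded
  exc3 <- apply_knockout_exclusions(dia)
  expect_identical(exc3$knockout_allowed, unname(!dia$is_exchange))
  expect_error(apply_knockout_exclusions(dia, extra_excluded = "nope"),
               "unknown reaction")
})

test_that("enlarging the protected set never enlarges the knockable set", {
  for (s in c(2, 9)) {
    inst <- random_design_instance(s, n_exchange = 4)
    net <- inst$net
    sec <- net$reaction_ids[net$is_exchange][-1]
    a <- apply_knockout_exclusions(net, protect_essential_for = sec[1])
    b <- apply_knockout_exclusions(net,
                                   protect_essential_for = sec[1:2])
    expect_true(all(which(b$knockout_allowed) %in%
                    which(a$knockout_allowed)))
  }
})
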