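test_that("essentiality screens match the constructed network", {
  m <- tiny_model()
  # the only route is the full chain: everything on it is essential for
  # maximal product when product formation is the objective
  m <- set_bounds(m, "EX_p_e", 0.5, 10)   # demand makes the chain required
  ess <- find_essential_reactions(m, objective = "EX_p_e")
  expect_setequal(ess, c("EX_s_e", "TR_s", "CONV", "TR_p"))
  # a duplicated parallel reaction removes essentiality of both copies
  m2 <- tiny_model()
  m2 <- add_rxn(m2, "CONV_b", c(s_c = -1, p_c = 1), lb = 0, ub = 10,
                genes = "g2")
  m2 <- set_bounds(m2, "EX_p_e", 0.5, 10)
  ess2 <- find_essential_reactions(m2, objective = "EX_p_e")
  expect_false("CONV" %in% ess2)
  expect_false("CONV_b" %in% ess2)
  # brute-force equivalence on the acetogen: single-deletion screen
  a <- demo_acetogen()
  ess3 <- find_essential_reactions(a)
  oracle <- Filter(function(r) {
    mm <- set_bounds(a, r, 0, 0)
    s <- solve_fba(mm, objective = "BIOMASS", sense = "max")
    s$status != "optimal" || s$objective_value < 1e-6
  }, setdiff(a$reactions$id, "BIOMASS"))
  expect_setequal(ess3, oracle)
})

test_that("gene essentiality respects isoenzyme OR logic", {
  m <- tiny_model()                      # CONV carries gene g1
  m <- set_bounds(m, "EX_p_e", 0.5, 10)
  expect_equal(find_essential_genes(m, objective = "EX_p_e"), "g1")
  # make CONV an isoenzyme pair: no single gene deletion kills it
  m$reactions$genes[m$reactions$id == "CONV"] <- "g1 or g2"
  expect_length(find_essential_genes(m, objective = "EX_p_e"), 0)
  # complex (AND) makes both subunits essential
  m$reactions$genes[m$reactions$id == "CONV"] <- "g1 and g2"
  expect_setequal(find_essential_genes(m, objective = "EX_p_e"),
                  c("g1", "g2"))
})

test_that("candidate filtering follows the four exclusion rules", {
  a <- demo_acetogen()
  cand <- knockout_candidates(a)
  expect_setequal(cand, c("AOR", "FDH", "SUCOVF"))
  # without the extracellular exclusion, transports reappear
  cand2 <- knockout_candidates(a, filter = knockout_filter(
    exclude_extracellular = FALSE, exclude_geneless = FALSE))
  expect_true("TR_ac" %in% cand2)
  expect_true(length(cand2) > length(cand))
})

test_that("optknock finds the growth-coupling deletion (oracle check)", {
  d <- design_fixture(with_r3 = FALSE)
  res <- optknock(d, target = "EX_et_e", max_knockouts = 1)
  expect_equal(res[[1]]$knocked_reactions, "R1")
  expect_equal(res[[1]]$optimistic_target_flux, 10, tolerance = 1e-6)
  expect_equal(res[[1]]$wild_type_flux, 0, tolerance = 1e-6)
  bf <- brute_force_designs(d, knockout_candidates(d), "EX_et_e",
                            "GROWTH", 1, "optimistic")
  expect_equal(res[[1]]$optimistic_target_flux, bf$value, tolerance = 1e-6)
  expect_true(list(res[[1]]$knocked_reactions) %in% bf$sets)
})

test_that("robustknock guards against alternative optima", {
  d <- design_fixture(with_r3 = TRUE)
  # after knocking R1 the optimal face is degenerate: optknock is
  # optimistic, robustknock reports the guaranteed zero
  ev <- cofba:::evaluate_design(d, "R1", "EX_et_e", "GROWTH")
  expect_equal(ev$optimistic, 10, tolerance = 1e-6)
  expect_equal(ev$guaranteed, 0, tolerance = 1e-6)
  # robustknock at k = 2 removes the silent alternative as well
  res <- robustknock(d, target = "EX_et_e", max_knockouts = 2)
  expect_setequal(res[[1]]$knocked_reactions, c("R1", "R3"))
  expect_equal(res[[1]]$guaranteed_target_flux, 10, tolerance = 1e-6)
  bf <- brute_force_designs(d, knockout_candidates(d), "EX_et_e",
                            "GROWTH", 2, "guaranteed")
  expect_equal(res[[1]]$guaranteed_target_flux, bf$value, tolerance = 1e-6)
  # invariants across all returned designs
  for (r in res) {
    expect_lte(r$guaranteed_target_flux,
               r$optimistic_target_flux + 1e-9)
    expect_lt(r$dual_gap, 1e-6)
  }
})

test_that("acetogen ethanol-forcing design matches exhaustive enumeration", {
  a <- demo_acetogen()
  cand <- knockout_candidates(a)
  res <- robustknock(a, target = "EX_etoh_e", max_knockouts = 2)
  bf <- brute_force_designs(a, cand, "EX_etoh_e", "BIOMASS", 2,
                            "guaranteed")
  expect_equal(res[[1]]$guaranteed_target_flux, bf$value, tolerance = 1e-6)
  expect_setequal(res[[1]]$knocked_reactions, c("FDH", "SUCOVF"))
  expect_gt(res[[1]]$guaranteed_target_flux, 0.5)
  # optknock agrees with its own oracle too
  res_ok <- optknock(a, target = "EX_etoh_e", max_knockouts = 2)
  bf_ok <- brute_force_designs(a, cand, "EX_etoh_e", "BIOMASS", 2,
                               "optimistic")
  expect_equal(res_ok[[1]]$optimistic_target_flux, bf_ok$value,
               tolerance = 1e-6)
})

test_that("degenerate and trivial design cases", {
  d <- design_fixture(with_r3 = FALSE)
  # zero knockout budget returns the wild type
  res0 <- optknock(d, target = "EX_et_e", max_knockouts = 0)
  expect_length(res0[[1]]$knocked_reactions, 0)
  # unique optimal flux vector: optknock and robustknock agree
  m <- tiny_model()
  m$reactions$genes[m$reactions$id == "CONV"] <- "g1"
  m$reactions$is_biomass[m$reactions$id == "CONV"] <- FALSE
  m <- set_bounds(m, "EX_p_e", 0, 10)
  m$objective <- list(reaction = "EX_p_e", direction = "max")
  ok <- optknock(m, target = "EX_p_e", max_knockouts = 1,
                 filter = knockout_filter(exclude_essential_reactions =
                                            FALSE))
  rk <- robustknock(m, target = "EX_p_e", max_knockouts = 1,
                    filter = knockout_filter(exclude_essential_reactions =
                                               FALSE))
  expect_equal(ok[[1]]$optimistic_target_flux,
               rk[[1]]$guaranteed_target_flux, tolerance = 1e-9)
})

test_that("filter monotonicity: shrinking candidates cannot help", {
  a <- demo_acetogen()
  full <- robustknock(a, target = "EX_etoh_e", max_knockouts = 2)
  # drop SUCOVF from the pool by tagging it geneless
  a2 <- a
  a2$reactions$genes[a2$reactions$id == "SUCOVF"] <- ""
  small <- robustknock(a2, target = "EX_etoh_e", max_knockouts = 2)
  expect_lte(small[[1]]$guaranteed_target_flux,
             full[[1]]$guaranteed_target_flux + 1e-9)
})

test_that("evaluate_mutant compares against the wild type", {
  a <- demo_acetogen()
  # empty knockout set reproduces the wild-type sample exactly
  base <- evaluate_mutant(a, knocked = character(0), n_samples = 200,
                          seed = 9)
  expect_equal(base$status, "optimal")
  expect_equal(base$mutant$mean, base$wild_type$mean)
  # deleting the electron overflows raises mean ethanol
  mut <- evaluate_mutant(a, knocked = c("FDH", "SUCOVF"), n_samples = 200,
                         seed = 9)
  et <- mut$comparison[mut$comparison$reaction == "EX_etoh_e", ]
  expect_gt(et$mut_mean, et$wt_mean)
  # deleting an essential reaction yields an infeasible-mutant result
  inf <- evaluate_mutant(a, knocked = "CODH", n_samples = 50, seed = 9)
  expect_equal(inf$status, "infeasible")
  expect_error(evaluate_mutant(a, knocked = "NOPE"), "unknown reaction")
})
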