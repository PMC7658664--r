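test_that("FBA optimum matches vertex enumeration on a small network", {
  m <- tiny_model()
  S <- as.matrix(stoichiometric_matrix(m))
  V <- enumerate_vertices(S, rep(0, nrow(S)), m$reactions$lb,
                          m$reactions$ub)
  cc <- as.numeric(colnames(S) == "EX_p_e")
  sol <- solve_fba(m, objective = "EX_p_e", sense = "max")
  expect_equal(sol$objective_value, max(V %*% cc), tolerance = 1e-6)
  # and on the design fixture (8 reactions)
  d <- design_fixture(with_r3 = FALSE)
  Sd <- as.matrix(stoichiometric_matrix(d))
  Vd <- enumerate_vertices(Sd, rep(0, nrow(Sd)), d$reactions$lb,
                           d$reactions$ub)
  for (obj in c("GROWTH", "EX_et_e")) {
    cd <- as.numeric(colnames(Sd) == obj)
    sd <- solve_fba(d, objective = obj, sense = "max")
    expect_equal(sd$objective_value, max(Vd %*% cd), tolerance = 1e-6)
    sd2 <- solve_fba(d, objective = obj, sense = "min")
    expect_equal(sd2$objective_value, min(Vd %*% cd), tolerance = 1e-6)
  }
})

test_that("steady state is asserted and LP scaling holds", {
  m <- tiny_model()
  sol <- solve_fba(m, objective = "EX_p_e", sense = "max")
  S <- as.matrix(stoichiometric_matrix(m))
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  expect_equal(sol$objective_value, 10)
  # doubling the homogeneous bounds doubles the optimum
  m2 <- m
  m2$reactions$lb <- 2 * m$reactions$lb
  m2$reactions$ub <- 2 * m$reactions$ub
  expect_equal(solve_fba(m2, objective = "EX_p_e",
                         sense = "max")$objective_value, 20)
  # nothing in, something out is infeasible
  m3 <- set_bounds(m, "EX_s_e", 0, 0)
  m3 <- set_bounds(m3, "EX_p_e", 1, 10)
  expect_equal(solve_fba(m3, objective = "EX_p_e", sense = "max")$status,
               "infeasible")
})

test_that("FVA: fixed points, nesting, and blocked routes", {
  cm <- make_toy_community()
  mdl <- apply_constraints(cm, build_constraints(cm, toy_scenario()))
  fv <- flux_variability(mdl, reactions = c("EX_co_e", "TR_co_ck"))
  # an exchange with equal bounds has a point range
  expect_equal(fv$min[1], -4.8, tolerance = 1e-9)
  expect_equal(fv$max[1], -4.8, tolerance = 1e-9)
  # the blocked cross-feed has range [0, 0]
  expect_equal(c(fv$min[2], fv$max[2]), c(0, 0), tolerance = 1e-9)
  # nesting under a tightening objective floor
  d <- design_fixture()
  f5 <- flux_variability(d, fraction_of_optimum = 0.5)
  f9 <- flux_variability(d, fraction_of_optimum = 0.9)
  expect_true(all(f9$min >= f5$min - 1e-7))
  expect_true(all(f9$max <= f5$max + 1e-7))
})

test_that("sampler: interval mean, determinism, envelope, validity", {
  # one-dimensional box: a single free cycle CONV in [0,10]... realised as
  # an open exchange chain; the sample mean approaches the chord midpoint
  m <- tiny_model()
  m <- set_bounds(m, "EX_s_e", -8, 0)    # uptake free in [0, 8]
  smp <- sample_fluxes(m, n = 3000, seed = 11)
  # flux through the chain is uniform on [0, 8]: mean 4, sd 8/sqrt(12)
  mc_err <- 3 * (8 / sqrt(12)) / sqrt(3000)
  expect_lt(abs(smp$mean[["CONV"]] - 4), mc_err)
  expect_gt(smp$sd[["CONV"]], 0)
  # determinism
  s1 <- sample_fluxes(m, n = 500, seed = 42)
  s2 <- sample_fluxes(m, n = 500, seed = 42)
  expect_identical(s1$samples, s2$samples)
  s3 <- sample_fluxes(m, n = 500, seed = 43)
  expect_false(identical(s1$samples, s3$samples))
  # every sampled point is steady-state and within bounds
  S <- as.matrix(stoichiometric_matrix(m))
  expect_lt(max(abs(S %*% t(s1$samples))), 1e-6)
  expect_true(all(t(s1$samples) >= m$reactions$lb - 1e-6))
  expect_true(all(t(s1$samples) <= m$reactions$ub + 1e-6))
  expect_error(sample_fluxes(m, n = 10), "seed")
})

test_that("sampler means stay within the FVA envelope on the community", {
  cm <- make_toy_community()
  cs <- build_constraints(cm, toy_scenario())
  smp <- sample_fluxes(cm, cs, n = 800, seed = 5)
  expect_true(all(smp$mean >= smp$fva$min - 1e-6))
  expect_true(all(smp$mean <= smp$fva$max + 1e-6))
})

test_that("infeasibility diagnosis finds the offending bounds", {
  # feasible set: all slacks zero
  m <- tiny_model()
  d0 <- diagnose_infeasibility(m)
  expect_true(attr(d0, "feasible"))
  expect_equal(sum(d0$slack), 0)
  # a single over-tight bound carries all the slack
  m2 <- set_bounds(m, "EX_p_e", 12, 20)  # demands more than supply allows
  d1 <- diagnose_infeasibility(m2)
  expect_false(attr(d1, "feasible"))
  offenders <- d1$reaction[d1$slack > 1e-6]
  expect_true("EX_p_e" %in% offenders)
  expect_equal(attr(d1, "total_slack"), 2, tolerance = 1e-6)
  # the ratio-stress community scenario concentrates slack on the
  # elongator's maintenance/biomass requirements
  cm <- block_cross_feed(make_toy_community(), "succ", "ck")
  cs <- build_constraints(cm, toy_scenario(phi_ck = 0.7, feeds = c(co = 4.8)))
  dd <- diagnose_infeasibility(cm, cs)
  expect_false(attr(dd, "feasible"))
  offenders <- dd$reaction[dd$slack > 1e-9]
  expect_true(all(offenders %in% c("ATPM_ck", "BIOMASS_ck")))
})
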