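test_that("generators emit balanced, deterministic, bounded networks", {
  a <- make_toy_acetogen()
  expect_lte(nrow(a$reactions), 20)
  expect_true(all(check_mass_balance(a)$balanced))
  k <- make_toy_elongator()
  expect_true(all(check_mass_balance(k)$balanced))
  # determinism under a fixed seed
  expect_identical(make_toy_acetogen(toy_network_spec("acetogen", seed = 7)),
                   make_toy_acetogen(toy_network_spec("acetogen", seed = 7)))
  expect_identical(make_toy_community(seed = 3), make_toy_community(seed = 3))
  # different seeds may shuffle gene labels but never stoichiometry
  a2 <- make_toy_acetogen(toy_network_spec("acetogen", seed = 8))
  expect_identical(a$stoich, a2$stoich)
})

test_that("acetogen closed forms: acetate 1/4 and ethanol 1/6 per CO", {
  a <- make_toy_acetogen()
  a <- set_bounds(a, "EX_co_e", -4, -4)
  a <- set_bounds(a, "EX_h2_e", 0, 0)
  for (r in c("EX_ac_e", "EX_etoh_e", "EX_succ_e")) {
    a <- set_bounds(a, r, 0, 1000)
  }
  expect_equal(solve_fba(a, objective = "EX_ac_e",
                         sense = "max")$objective_value, 1,
               tolerance = 1e-9)
  expect_equal(solve_fba(a, objective = "EX_etoh_e",
                         sense = "max")$objective_value, 4 / 6,
               tolerance = 1e-9)
  # H2 co-feed raises the max ethanol/acetate ratio (solventogenesis trend)
  a_h2 <- set_bounds(a, "EX_h2_e", -4, -4)
  r0 <- solve_fba(a, objective = "EX_etoh_e", sense = "max")$objective_value
  r1 <- solve_fba(a_h2, objective = "EX_etoh_e",
                  sense = "max")$objective_value
  expect_gt(r1, r0)
})

test_that("succinate route toggling", {
  a0 <- make_toy_acetogen(toy_network_spec("acetogen",
                                           include_succinate_route = FALSE))
  expect_false("SUCOVF" %in% a0$reactions$id)
  expect_false("succ_e" %in% a0$metabolites$id)
  k0 <- make_toy_elongator(toy_network_spec(
    "chain_elongator", include_succinate_route = FALSE))
  expect_false("SUCCROC" %in% k0$reactions$id)
  # with the route disabled, the community cannot touch succinate at all
  cm0 <- make_toy_community(include_succinate_route = FALSE)
  expect_false(any(grepl("^succ", cm0$metabolites$id)))
})

test_that("elongator substrate dependences are as designed", {
  k <- make_toy_elongator(toy_network_spec("chain_elongator",
                                           etoh_uptake_vmax = 10))
  medium <- function(m, open) {
    for (r in m$reactions$id[m$reactions$is_exchange]) {
      m <- set_bounds(m, r, 0, 1000)
    }
    m <- set_bounds(m, "EX_h2o_e", -1000, 1000)
    m <- set_bounds(m, "EX_co2_e", -1000, 1000)
    for (nm in names(open)) {
      m <- set_bounds(m, paste0("EX_", nm, "_e"), -open[[nm]], 0)
    }
    m
  }
  # ethanol alone (even with CO2) does not support growth
  g1 <- solve_fba(medium(k, c(etoh = 6)), objective = "BIOMASS",
                  sense = "max")
  expect_lt(abs(g1$objective_value), 1e-9)
  # acetate alone neither
  g2 <- solve_fba(medium(k, c(ac = 6)), objective = "BIOMASS",
                  sense = "max")
  expect_lt(abs(g2$objective_value), 1e-9)
  # ethanol + acetate + CO2 grow
  g3 <- solve_fba(medium(k, c(etoh = 6, ac = 2)), objective = "BIOMASS",
                  sense = "max")
  expect_gt(g3$objective_value, 1e-3)
  # closing CO2 uptake abolishes growth (CO2 is essential)
  m4 <- set_bounds(medium(k, c(etoh = 6, ac = 2)), "EX_co2_e", 0, 1000)
  g4 <- solve_fba(m4, objective = "BIOMASS", sense = "max")
  expect_lt(abs(g4$objective_value), 1e-9)
  # electron/carbon closed form: 2 hexanoate from 6 ethanol
  h <- solve_fba(medium(k, c(etoh = 6)), objective = "EX_hexa_e",
                 sense = "max")
  expect_equal(h$objective_value, 2, tolerance = 1e-9)
  # succinate strictly increases attainable hexanoate at equal feeds
  h_succ <- solve_fba(medium(k, c(etoh = 6, succ = 2)),
                      objective = "EX_hexa_e", sense = "max")
  expect_gt(h_succ$objective_value, h$objective_value + 0.1)
})

test_that("community shifts the acetogen toward ethanol consumption", {
  cm <- make_toy_community()
  sol <- solve_fba(cm, build_constraints(cm, toy_scenario()),
                   objective = "EX_hexa_e", sense = "max",
                   parsimonious = TRUE)
  produced <- sol$fluxes[["TR_etoh_out_c"]]
  net_out <- sol$fluxes[["EX_etoh_e"]]
  expect_gt(produced, 0.01)           # the acetogen makes ethanol
  expect_lt(net_out, produced / 2)    # but the community keeps most of it
})

test_that("scenario generation: grid shape, noise, reproducibility", {
  grid <- scenario_grid_spec(h2_feeds = c(0, 1.2, 2.4), noise_sd = 0.05,
                             seed = 21)
  cm <- make_toy_community(seed = 21)
  scen <- make_scenarios(grid, model = cm)
  expect_length(scen, 3)
  expect_true(all(vapply(scen, function(s) s$feeds[["co"]], numeric(1)) ==
                    4.8))
  # reproducible under the same seed
  scen2 <- make_scenarios(grid, model = cm)
  expect_equal(scen[[2]]$measured_products, scen2[[2]]$measured_products)
  # noiseless limit equals the generating optimum exactly
  g0 <- scenario_grid_spec(h2_feeds = 2.4, noise_sd = 0, seed = 21)
  s0 <- make_scenarios(g0, model = cm)[[1]]
  gen <- attr(s0, "generating_fluxes")
  for (p in names(s0$measured_products)) {
    expect_equal(s0$measured_products[[p]], gen[[paste0("EX_", p, "_e")]],
                 tolerance = 1e-12)
  }
})

test_that("noiseless constrain-solve round trip recovers the exchanges", {
  cm <- make_toy_community(seed = 2)
  grid <- scenario_grid_spec(h2_feeds = c(0, 2.4), noise_sd = 0, seed = 2)
  for (sc in make_scenarios(grid, model = cm)) {
    expect_false(isTRUE(attr(sc, "infeasible")))
    gen <- attr(sc, "generating_fluxes")
    sol <- solve_fba(cm, build_constraints(cm, sc),
                     objective = "EX_hexa_e", sense = "max",
                     parsimonious = TRUE)
    ex <- grep("^EX_", names(gen), value = TRUE)
    expect_equal(sol$fluxes[ex], gen[ex], tolerance = 1e-6)
  }
})

test_that("infeasible grid points are emitted and flagged", {
  cm <- make_toy_community(include_succinate_route = FALSE, seed = 4)
  grid <- scenario_grid_spec(h2_feeds = 0, noise_sd = 0, seed = 4,
                             biomass_ratios = list(c(ck = 0.7, c = 0.3)))
  scen <- make_scenarios(grid, model = cm)
  expect_length(scen, 1)
  expect_true(isTRUE(attr(scen[[1]], "infeasible")))
})

test_that("fixture emitter writes a runnable set of files", {
  dir <- withr::local_tempdir()
  paths <- write_fixtures(dir, seed = 1)
  expect_true(all(file.exists(paths)))
  m <- read_model(file.path(dir, "toy_acetogen.xml"), "sbml")
  expect_equal(m$id, "toy_acetogen")
  tab <- read.delim(file.path(dir, "scenarios.tsv"))
  expect_true(nrow(tab) >= 1)
  js <- jsonlite::read_json(file.path(dir, "merge_spec.json"),
                            simplifyVector = TRUE)
  expect_equal(js$tag_b, "ck")
})
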