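test_that("dilution rate is 1/HRT and rounds to the published rates", {
  expect_equal(round(dilution_rate(48), 3), 0.021)
  expect_equal(round(dilution_rate(36), 3), 0.028)
  expect_equal(dilution_rate(1), 1)
  expect_error(dilution_rate(0), "> 0")
  expect_error(dilution_rate(-5), "> 0")
})

test_that("concentration/rate conversion and its inverse", {
  r <- concentrations_to_rates(c(ac = 48), 48)
  expect_equal(r, c(ac = 1))
  expect_equal(concentrations_to_rates(numeric(0), 10), numeric(0))
  conc <- c(ac = 12.5, etoh = 3.3)
  expect_equal(concentrations_to_rates(conc, 36) * 36, conc)
  expect_error(concentrations_to_rates(c(ac = -1), 10), ">= 0")
})

test_that("build_constraints applies every stated rule", {
  cm <- make_toy_community()
  sc <- toy_scenario(feeds = c(co = 4.8, h2 = 2.4))
  sc$measured_products <- c(etoh = 1.0, hexa = 0.05)
  cs <- build_constraints(cm, sc)
  b <- cs$bounds
  row <- function(r) b[b$reaction == r, ]
  # (a) feed fixed at -feed
  expect_equal(row("EX_co_e")$lb, -4.8)
  expect_equal(row("EX_co_e")$ub, -4.8)
  # (b) product floor at 80% of the measurement
  expect_equal(row("EX_etoh_e")$lb, 0.8)
  expect_equal(row("EX_hexa_e")$lb, 0.04)
  # (c) biomass fixed at mu * X_T * phi per species
  mu <- dilution_rate(48)
  expect_equal(row("BIOMASS_c")$lb, mu * 0.4 * 0.315)
  expect_equal(row("BIOMASS_c")$ub, mu * 0.4 * 0.315)
  expect_equal(row("BIOMASS_ck")$lb, mu * 0.4 * 0.685)
  # (d) maintenance floor scaled by X_T * phi
  expect_equal(row("ATPM_ck")$lb, 0.45 * 0.4 * 0.685)
  expect_equal(row("ATPM_ck")$ub, 1000)
  # (e) cross-feed forced toward the consumer
  expect_equal(row("TR_succ_ck")$lb, 0)
  expect_equal(cs$growth_rate, mu)
  # medium closure: no uptake of products that are not fed
  expect_equal(row("EX_buty_e")$lb, 0)
  expect_error(build_constraints(cm, sc, product_floor = 1.2), "\\[0, 1\\]")
})

test_that("max-uptake mode relaxes feeds to a one-sided bound", {
  cm <- make_toy_community()
  sc <- toy_scenario()
  cs <- build_constraints(cm, sc, fix_feeds = FALSE)
  b <- cs$bounds
  expect_equal(b[b$reaction == "EX_co_e", c("lb", "ub")],
               data.frame(lb = -4.8, ub = 0,
                          row.names = which(b$reaction == "EX_co_e")))
})

test_that("solutions honour the equal-growth coupling", {
  cm <- make_toy_community()
  sc <- toy_scenario()
  cs <- build_constraints(cm, sc)
  sol <- solve_fba(cm, cs, objective = "EX_hexa_e", sense = "max")
  mu <- dilution_rate(48)
  expect_equal(unname(sol$fluxes[["BIOMASS_c"]]), mu * 0.4 * 0.315,
               tolerance = 1e-8)
  expect_equal(unname(sol$fluxes[["BIOMASS_ck"]]), mu * 0.4 * 0.685,
               tolerance = 1e-8)
  # hence equal specific growth rates after volume scaling
  q_c <- sol$fluxes[["BIOMASS_c"]] / (0.4 * 0.315)
  q_ck <- sol$fluxes[["BIOMASS_ck"]] / (0.4 * 0.685)
  expect_equal(q_c, q_ck, tolerance = 1e-9)
})

test_that("loosening the product floor only enlarges the feasible region", {
  cm <- make_toy_community()
  sc <- toy_scenario()
  sc$measured_products <- c(hexa = 0.05, buty = 0.02)
  tight <- apply_constraints(cm, build_constraints(cm, sc,
                                                   product_floor = 0.8))
  loose <- apply_constraints(cm, build_constraints(cm, sc,
                                                   product_floor = 0))
  scan <- c("EX_hexa_e", "EX_buty_e", "EX_succ_e", "TR_etoh_in_ck")
  ft <- flux_variability(tight, reactions = scan)
  fl <- flux_variability(loose, reactions = scan)
  expect_true(all(fl$min <= ft$min + 1e-7))
  expect_true(all(fl$max >= ft$max - 1e-7))
})

test_that("scenario constructor validates inputs", {
  ab <- species_abundance(c(ck = 0.5, c = 0.5))
  expect_error(chemostat_scenario(c(co = -1), hrt = 48,
                                  community_biomass = 0.4, abundance = ab),
               ">= 0")
  expect_error(chemostat_scenario(c(co = 1), hrt = 0,
                                  community_biomass = 0.4, abundance = ab))
})
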