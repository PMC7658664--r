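# Electron- and carbon-yield arithmetic. Expected values are the published
# yield-comparison rows, all re-derivable from the per-mole electron
# constants (CO/H2: 2, acetate: 8, succinate: 14, hexanoate: 32).

test_that("electron yields reproduce the published comparison rows", {
  # this-study row: CO 4.8 + H2 3.87 + succinate 1 -> hexanoate 0.59
  y1 <- electron_yield(c(co = 4.8, h2 = 3.87, succ = 1), "hexa", 0.59)
  expect_equal(round(y1, 2), 0.60)
  # syngas co-culture row with the 90% gas-consumption discount
  y2 <- electron_yield(c(co = 4.8, h2 = 5.3), "hexa", 0.15,
                       discount_gas = TRUE)
  expect_equal(round(y2, 2), 0.26)
  # CO/acetate co-culture row (discount applies to the gas only)
  y3 <- electron_yield(c(co = 6.5, ac = 2.5), "hexa", 0.15,
                       discount_gas = TRUE)
  expect_equal(round(y3, 2), 0.15)
  # high-rate co-culture row, no discount
  y4 <- electron_yield(c(co = 31.9, h2 = 79.1), "hexa", 0.48)
  expect_equal(round(y4, 2), 0.07)
})

test_that("gas discount off reproduces the plain formula exactly", {
  r <- c(co = 3, h2 = 2)
  plain <- 0.1 * 32 / (3 * 2 + 2 * 2)
  expect_equal(electron_yield(r, "hexa", 0.1), plain)
  lg <- electron_ledger(gas_consumption_fraction = 1)
  expect_equal(electron_yield(r, "hexa", 0.1, lg, discount_gas = TRUE),
               plain)
  expect_equal(electron_yield(r, "hexa", 0), 0)
})

test_that("electron yield error paths", {
  expect_error(electron_yield(c(xx = 1), "hexa", 0.1), "missing from")
  expect_error(electron_yield(c(co = 0), "hexa", 0.1), "zero electron")
  expect_error(electron_yield(c(co = -1), "hexa", 0.1), "non-negative")
  expect_error(electron_ledger(gas_consumption_fraction = 0), "\\(0, 1\\]")
})

test_that("carbon-normalised yields", {
  expect_equal(carbon_normalized_yield(0.1, c(co = 4.8)), 0.1 / 4.8)
  expect_equal(carbon_normalized_yield(0.1, c(co = 4.8, succ = 1)),
               0.1 / 8.8)
  # scale invariance
  expect_equal(carbon_normalized_yield(0.2, c(co = 9.6, succ = 2)),
               carbon_normalized_yield(0.1, c(co = 4.8, succ = 1)))
  expect_error(carbon_normalized_yield(0.1, numeric(0)), "nonempty")
  expect_error(carbon_normalized_yield(0.1, c(co = 0)), "zero carbon")
})

test_that("yields from balanced flux solutions stay within [0, 1]", {
  # electron conservation in the toy community guarantees this
  cm <- make_toy_community()
  sc <- toy_scenario()
  cs <- build_constraints(cm, sc)
  sol <- solve_fba(cm, cs, objective = "EX_hexa_e", sense = "max")
  y <- electron_yield(sc$feeds, "hexa", sol$objective_value)
  expect_gte(y, 0)
  expect_lte(y, 1)
})

test_that("yield_report formats rows at two decimals", {
  tab <- yield_report(list(
    list(label = "demo", substrates = c(co = 4.8, h2 = 3.87, succ = 1),
         product = "hexa", product_rate = 0.59)))
  expect_equal(tab$electron_yield, 0.60)
  expect_match(tab$substrates, "co=4.8")
})
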