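test_that("merge bookkeeping: counts, compartments, suffixes, aliases", {
  a <- make_toy_acetogen()
  k <- make_toy_elongator()
  cm <- make_toy_community()
  lg <- attr(cm, "merge_log")
  # |R_out| = |R_a| + |R_b| + |added| - |dropped|
  expect_equal(nrow(cm$reactions),
               nrow(a$reactions) + nrow(k$reactions) +
                 length(lg$added) - length(lg$dropped))
  expect_setequal(names(cm$compartments), c("c", "ck", "e"))
  # internal ids carry their species suffix
  comp_of <- setNames(cm$metabolites$compartment, cm$metabolites$id)
  internal <- cm$metabolites$id[cm$metabolites$compartment != "e"]
  expect_true(all(grepl("_(c|ck)$", internal)))
  # deduplicated exchanges are logged as aliases
  expect_true(length(lg$aliases) >= 5)
  # one biomass transport + exchange per species
  expect_true(all(c("TR_BIOMASS_c", "EX_BIOMASS_c_e", "TR_BIOMASS_ck",
                    "EX_BIOMASS_ck_e") %in% cm$reactions$id))
  # extracellular connectivity audit passes
  expect_length(audit_connectivity(cm), 0)
})

test_that("merging a model with itself doubles every internal id", {
  a <- make_toy_acetogen()
  spec <- merge_spec(species_a = a, tag_a = "x", species_b = a, tag_b = "y")
  cm <- merge_models(spec)
  xs <- cm$metabolites$id[cm$metabolites$compartment == "x"]
  ys <- cm$metabolites$id[cm$metabolites$compartment == "y"]
  expect_equal(sort(sub("_x$", "", xs)), sort(sub("_y$", "", ys)))
  expect_equal(length(xs), length(ys))
})

test_that("namespace map renames and collisions are detected", {
  a <- make_toy_acetogen()
  k <- make_toy_elongator()
  # rename the elongator's extracellular acetate, then map it back
  k$metabolites$id[k$metabolites$id == "ac_e"] <- "acet_e"
  k$stoich <- lapply(k$stoich, function(s) {
    names(s)[names(s) == "ac_e"] <- "acet_e"; s
  })
  nm <- data.frame(species = "b", from = "acet_e", to = "ac_e",
                   stringsAsFactors = FALSE)
  cm <- merge_models(merge_spec(a, "c", k, "ck", namespace_map = nm))
  expect_false("acet_e" %in% cm$metabolites$id)
  expect_true("ac_e" %in% cm$metabolites$id)
  # conflicting formulas under the same unified id must error
  k2 <- make_toy_elongator()
  k2$metabolites$formula[k2$metabolites$id == "ac_e"] <- "C3H6O2"
  expect_error(merge_models(merge_spec(a, "c", k2, "ck")),
               "collision")
})

test_that("routing rule for an absent metabolite errors", {
  a <- make_toy_acetogen()
  k <- make_toy_elongator()
  bad <- merge_spec(a, "c", k, "ck",
                    routing = data.frame(metabolite = "hexa",
                                         producer = "c", consumer = "ck",
                                         uptake_by_producer = FALSE))
  expect_error(merge_models(bad), "absent in species")
})

test_that("CO is unusable by the blocked elongator in the community", {
  cm <- make_toy_community()
  # the elongator's CO transport is pinned to zero
  fv <- flux_variability(
    apply_constraints(cm, build_constraints(cm, toy_scenario())),
    reactions = c("TR_co_ck", "CODH_ck"))
  expect_equal(fv$min, c(0, 0), tolerance = 1e-9)
  expect_equal(fv$max, c(0, 0), tolerance = 1e-9)
})

test_that("block and unblock are inverse; blocking twice is a no-op", {
  cm <- make_toy_community()
  before <- get_bounds(cm, "TR_succ_ck")
  b1 <- block_cross_feed(cm, "succ", "ck")
  expect_equal(get_bounds(b1, "TR_succ_ck")$ub, 0)
  b2 <- block_cross_feed(b1, "succ", "ck")
  expect_equal(get_bounds(b2, "TR_succ_ck"), get_bounds(b1, "TR_succ_ck"))
  b3 <- unblock_cross_feed(b2, "succ", "ck")
  expect_equal(get_bounds(b3, "TR_succ_ck"), before)
  expect_error(block_cross_feed(cm, "nosuchmet", "ck"), "no transport")
})

test_that("merge order does not change the feasible exchange set", {
  a <- make_toy_acetogen()
  k <- make_toy_elongator()
  routing <- data.frame(metabolite = c("h2", "ac", "etoh"),
                        producer = c("ck", "c", "c"),
                        consumer = c("c", "ck", "ck"),
                        uptake_by_producer = c(FALSE, TRUE, FALSE),
                        stringsAsFactors = FALSE)
  blocked <- data.frame(species = "ck", metabolite = "co",
                        stringsAsFactors = FALSE)
  m1 <- merge_models(merge_spec(a, "c", k, "ck", routing = routing,
                                blocked_uptakes = blocked))
  m2 <- merge_models(merge_spec(k, "ck", a, "c", routing = routing,
                                blocked_uptakes = blocked))
  eval_order <- function(m) {
    m <- set_bounds(m, "EX_co_e", -4.8, -4.8)
    for (r in c("EX_ac_e", "EX_etoh_e", "EX_succ_e", "EX_h2_e")) {
      m <- set_bounds(m, r, 0, 1000)
    }
    c(solve_fba(m, objective = "EX_hexa_e", sense = "max")$objective_value,
      solve_fba(m, objective = "EX_buty_e", sense = "max")$objective_value)
  }
  expect_equal(eval_order(m1), eval_order(m2), tolerance = 1e-8)
})

test_that("MCFA reduction pathway enables alcohols and is idempotent", {
  a <- make_toy_acetogen()
  a2 <- add_mcfa_reduction_pathway(a, "c")
  expect_gt(nrow(a2$reactions), nrow(a$reactions))
  expect_identical(nrow(add_mcfa_reduction_pathway(a2, "c")$reactions),
                   nrow(a2$reactions))
  # all added conversions are elementally balanced (C6 acid -> C6 alcohol)
  audit <- check_mass_balance(a2)
  expect_true(all(audit$balanced))
  # butyrate feed allows butanol production
  a3 <- set_bounds(a2, "EX_buty_e", -1, -1)
  a3 <- set_bounds(a3, "EX_co_e", -10, 0)
  sol <- solve_fba(a3, objective = "EX_btoh_e", sense = "max")
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective_value, 0.99)
  # missing cofactor is reported by name
  bad <- a
  bad$metabolites <- bad$metabolites[bad$metabolites$id != "h2o_c", ]
  expect_error(add_mcfa_reduction_pathway(bad, "c"), "h2o_c")
})
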