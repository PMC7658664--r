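# Shared fixtures: all built in code, no files.

# minimal linear network: S_e -> S_c -> P_c -> P_e, 5 reactions
tiny_model <- function() {
  metabolic_model(
    id = "tiny",
    compartments = c(c = "cytosol", e = "extracellular"),
    metabolites = data.frame(
      id = c("s_e", "s_c", "p_c", "p_e"),
      name = c("s", "s", "p", "p"),
      compartment = c("e", "c", "c", "e"),
      formula = c("C1", "C1", "C1", "C1"),
      charge = 0L, stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_s_e", "TR_s", "CONV", "TR_p", "EX_p_e"),
      name = c("s exchange", "s uptake", "convert", "p export",
               "p exchange"),
      lb = c(-10, 0, 0, 0, 0), ub = c(0, 10, 10, 10, 10),
      genes = c("", "", "g1", "", ""),
      is_exchange = c(TRUE, FALSE, FALSE, FALSE, TRUE),
      is_biomass = FALSE, stringsAsFactors = FALSE),
    stoich = list(EX_s_e = c(s_e = -1), TR_s = c(s_e = -1, s_c = 1),
                  CONV = c(s_c = -1, p_c = 1), TR_p = c(p_c = -1, p_e = 1),
                  EX_p_e = c(p_e = -1)))
}

# abstract strain-design network: source s feeds three ATP routes,
#   R1: s -> 2 atp           (efficient, geneful)
#   R2: s -> 1 atp + 1 etoh  (couples target to growth)
#   R3: s -> 1 atp           (silent alternative)
# growth burns 3 atp. With the source fixed, max growth uses R1 only; the
# optimal face after knocking R1 is degenerate between R2 and R3.
design_fixture <- function(with_r3 = TRUE) {
  rid <- c("EX_src_e", "TR_src", "R1", "R2", if (with_r3) "R3",
           "GROWTH", "TR_et", "EX_et_e")
  rxn <- data.frame(
    id = rid, name = rid,
    lb = c(-10, 0, 0, 0, if (with_r3) 0, 0, 0, 0),
    ub = c(-10, 1000, 1000, 1000, if (with_r3) 1000, 1000, 1000, 1000),
    genes = c("", "", "g1", "g2", if (with_r3) "g3", "", "", ""),
    is_exchange = rid %in% c("EX_src_e", "EX_et_e"),
    is_biomass = rid == "GROWTH", stringsAsFactors = FALSE)
  st <- list(
    EX_src_e = c(src_e = -1),
    TR_src = c(src_e = -1, src_c = 1),
    R1 = c(src_c = -1, atp_c = 2),
    R2 = c(src_c = -1, atp_c = 1, et_c = 1),
    GROWTH = c(atp_c = -3),
    TR_et = c(et_c = -1, et_e = 1),
    EX_et_e = c(et_e = -1))
  if (with_r3) st$R3 <- c(src_c = -1, atp_c = 1)
  metabolic_model(
    id = "design_fixture",
    compartments = c(c = "cytosol", e = "extracellular"),
    metabolites = data.frame(
      id = c("src_e", "src_c", "atp_c", "et_c", "et_e"),
      name = c("src", "src", "atp", "et", "et"),
      compartment = c("e", "c", "c", "c", "e"),
      formula = NA_character_, charge = NA_integer_,
      stringsAsFactors = FALSE),
    reactions = rxn, stoich = st[rid],
    objective = list(reaction = "GROWTH", direction = "max"))
}

# acetogen under the ethanol-forcing demo condition: fixed CO feed,
# chemostat-like biomass cap and maintenance floor, saturating acetate export
demo_acetogen <- function() {
  a <- make_toy_acetogen(toy_network_spec("acetogen",
                                          include_formate_branch = TRUE))
  a <- set_bounds(a, "EX_co_e", -10, -10)
  a <- set_bounds(a, "EX_h2_e", 0, 0)
  for (r in c("EX_ac_e", "EX_etoh_e", "EX_succ_e", "EX_form_e")) {
    a <- set_bounds(a, r, 0, 1000)
  }
  a <- set_bounds(a, "BIOMASS", 0, 0.1)
  a <- set_bounds(a, "ATPM", 0.5, 1000)
  set_bounds(a, "TR_ac", 0, 1.5)
}

# standard chemostat scenario on the toy community
toy_scenario <- function(phi_ck = 0.685, feeds = c(co = 4.8, h2 = 2.4),
                         xt = 0.4, hrt = 48) {
  chemostat_scenario(
    feeds = feeds, hrt = hrt, community_biomass = xt,
    abundance = species_abundance(c(ck = phi_ck, c = 1 - phi_ck)),
    atpm_specific = c(c = 0.45, ck = 0.45),
    cross_feeds = c(succ = "ck"))
}

# brute-force bi-level oracle: exhaustively enumerate knockout subsets and
# re-solve the two-stage LPs; independent of the branch-and-bound search
brute_force_designs <- function(model, candidates, target, objective,
                                max_k, value = "guaranteed") {
  best <- -Inf
  best_sets <- list()
  for (k in 0:max_k) {
    sets <- if (k == 0) list(character(0)) else
      utils::combn(candidates, k, simplify = FALSE)
    for (s in sets) {
      ev <- cofba:::evaluate_design(model, s, target, objective)
      if (is.null(ev)) next
      v <- ev[[value]]
      if (v > best + 1e-9) {
        best <- v; best_sets <- list(sort(s))
      } else if (abs(v - best) <= 1e-9) {
        best_sets[[length(best_sets) + 1]] <- sort(s)
      }
    }
  }
  list(value = best, sets = best_sets)
}

expect_models_equal <- function(m1, m2) {
  expect_equal(sort(m1$metabolites$id), sort(m2$metabolites$id))
  expect_equal(sort(m1$reactions$id), sort(m2$reactions$id))
  o <- match(m2$reactions$id, m1$reactions$id)
  expect_equal(m1$reactions$lb[o], m2$reactions$lb, tolerance = 1e-9)
  expect_equal(m1$reactions$ub[o], m2$reactions$ub, tolerance = 1e-9)
  expect_equal(m1$reactions$genes[o], m2$reactions$genes)
  expect_equal(m1$reactions$is_biomass[o], m2$reactions$is_biomass)
  for (rid in m1$reactions$id) {
    s1 <- m1$stoich[[rid]]; s2 <- m2$stoich[[rid]]
    expect_equal(sort(names(s1)), sort(names(s2)), info = rid)
    expect_equal(s1[sort(names(s1))], s2[sort(names(s1))],
                 tolerance = 1e-9, info = rid)
  }
}
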