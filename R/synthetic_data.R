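## Toy single-species networks emulating a syngas-fermenting acetogen and a
## chain-elongating clostridium. Every internal reaction is elementally
## balanced (C/H/O audit enforced at generation time); reducing equivalents
## are lumped into intracellular H2, and ATP/ADP/phosphate close an explicit
## energy cycle, so electron- and energy-limited behaviour emerges from the
## stoichiometry rather than from ad-hoc bounds.

TOY_FORMULAS <- c(
  co = "CO", co2 = "CO2", h2 = "H2", h2o = "H2O", form = "CH2O2",
  ac = "C2H4O2", etoh = "C2H6O", acal = "C2H4O", accoa = "C2H4O2",
  pyr = "C3H4O3", succ = "C4H6O4", croc = "C4H6O2", buty = "C4H8O2",
  hexa = "C6H12O2", btal = "C4H8O", hxal = "C6H12O", btoh = "C4H10O",
  hxoh = "C6H14O",
  atp = "C10H16N5O13P3", adp = "C10H15N5O10P2", pi = "H3O4P")

#' Specification for a toy network generator
#'
#' @param species_role \code{"acetogen"} or \code{"chain_elongator"}.
#' @param include_succinate_route include the succinate overflow (acetogen) /
#'   succinate-to-crotonyl (elongator) pathway.
#' @param include_mcfa_reduction (acetogen only) also add the medium-chain
#'   fatty-acid reduction pathway at generation time.
#' @param include_formate_branch (acetogen only) add a reversible formate
#'   dehydrogenase with formate export: an electron overflow valve that makes
#'   the growth-optimal face degenerate, which is what strain-design
#'   algorithms exploit (default \code{FALSE}, keeping the default acetogen
#'   at 20 reactions).
#' @param biomass_yield_coeffs named numeric: precursor demand per unit of
#'   biomass flux. Defaults: acetogen \code{c(accoa = 0.5, atp = 2)};
#'   elongator \code{c(pyr = 1, ac = 1, atp = 2)}.
#' @param atpm_specific non-growth ATP maintenance, mmol gDW-1 h-1
#'   (default 0.45); recorded on the model and consumed by scenario builders.
#' @param etoh_uptake_vmax (elongator only) saturation cap on the ethanol
#'   uptake transport, mmol l-1 h-1 (default 0.25). This kinetic cap is what
#'   makes the elongator's energy metabolism depend on alternative carbon
#'   routes (e.g. succinate) when its maintenance demand is high.
#' @param seed integer seed driving the synthetic gene-association labels.
#' @return object of class \code{toy_network_spec}.
#' @export
toy_network_spec <- function(species_role = c("acetogen", "chain_elongator"),
                             include_succinate_route = TRUE,
                             include_mcfa_reduction = FALSE,
                             include_formate_branch = FALSE,
                             biomass_yield_coeffs = NULL,
                             atpm_specific = 0.45,
                             etoh_uptake_vmax = 0.25,
                             seed = 1L) {
  species_role <- match.arg(species_role)
  if (is.null(biomass_yield_coeffs)) {
    biomass_yield_coeffs <- if (species_role == "acetogen") {
      c(accoa = 0.5, atp = 2)
    } else c(pyr = 1, ac = 1, atp = 2)
  }
  structure(list(species_role = species_role,
                 include_succinate_route = include_succinate_route,
                 include_mcfa_reduction = include_mcfa_reduction,
                 include_formate_branch = include_formate_branch,
                 biomass_yield_coeffs = biomass_yield_coeffs,
                 atpm_specific = atpm_specific,
                 etoh_uptake_vmax = etoh_uptake_vmax,
                 seed = as.integer(seed)),
            class = "toy_network_spec")
}

## shared skeleton: compartments, metabolite helper, exchange+transport pairs
new_toy_model <- function(id) {
  m <- structure(list(
    id = id,
    compartments = c(c = "cytosol", e = "extracellular"),
    metabolites = data.frame(id = character(0), name = character(0),
                             compartment = character(0),
                             formula = character(0), charge = integer(0),
                             stringsAsFactors = FALSE),
    reactions = data.frame(id = character(0), name = character(0),
                           lb = numeric(0), ub = numeric(0),
                           genes = character(0), is_exchange = logical(0),
                           is_biomass = logical(0), stringsAsFactors = FALSE),
    stoich = list(),
    objective = list(reaction = NA_character_, direction = "max")),
    class = "metabolic_model")
  m
}

toy_met <- function(m, base, comp) {
  id <- paste0(base, "_", comp)
  add_met(m, id, comp, formula = unname(TOY_FORMULAS[base]), name = base)
}

toy_exchange <- function(m, base, lb = -1000, ub = 1000) {
  m <- toy_met(m, base, "e")
  add_rxn(m, paste0("EX_", base, "_e"),
          stats::setNames(-1, paste0(base, "_e")), lb = lb, ub = ub,
          is_exchange = TRUE)
}

## synthetic gene-association labels so knockout-candidate filters have
## something realistic to chew on (1-2 genes, occasionally isoenzymes)
assign_genes <- function(model, prefix, internal_ids, seed) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  withr_seed({
    gi <- 0L
    for (rid in internal_ids) {
      n <- sample(1:2, 1)
      genes <- paste0(prefix, sprintf("%02d", gi + seq_len(n)))
      gi <- gi + n
      op <- if (n == 2 && stats::runif(1) < 0.5) " or " else " and "
      model$reactions$genes[model$reactions$id == rid] <-
        paste(genes, collapse = op)
    }
  })
  model
}

#' Generate the toy acetogen model
#'
#' A lumped Wood-Ljungdahl acetogen: CO and H2 uptake, CO dehydrogenase
#' providing reducing equivalents (lumped as intracellular H2), an acetyl-CoA
#' synthesis reaction fixing 2 CO2 with 4 H2, acetate kinase as the sole
#' ATP-yielding step, acetate reduction to ethanol, an optional succinate
#' overflow (2 acetyl-CoA -> succinate, excreted), a biomass drain and an ATP
#' maintenance reaction. All internal reactions are C/H/O balanced; maximal
#' acetate yield on CO alone is 1/4 mmol per mmol CO (electron-capped) and
#' maximal ethanol yield is 1/6.
#'
#' @param spec a \code{\link{toy_network_spec}} with role \code{"acetogen"}.
#' @return a validated \code{metabolic_model} (at most 20 reactions).
#' @export
make_toy_acetogen <- function(spec = toy_network_spec("acetogen")) {
  stopifnot(inherits(spec, "toy_network_spec"),
            spec$species_role == "acetogen")
  m <- new_toy_model("toy_acetogen")
  for (b in c("co", "h2", "co2", "h2o", "ac", "etoh", "accoa", "atp", "adp",
              "pi")) {
    m <- toy_met(m, b, "c")
  }
  m <- toy_exchange(m, "co"); m <- toy_exchange(m, "h2")
  m <- toy_exchange(m, "co2"); m <- toy_exchange(m, "h2o")
  m <- toy_exchange(m, "ac"); m <- toy_exchange(m, "etoh")
  m <- add_rxn(m, "TR_co", c(co_e = -1, co_c = 1), lb = 0)
  m <- add_rxn(m, "TR_h2", c(h2_e = -1, h2_c = 1), lb = 0)
  m <- add_rxn(m, "TR_co2", c(co2_c = -1, co2_e = 1))
  m <- add_rxn(m, "TR_h2o", c(h2o_c = -1, h2o_e = 1))
  m <- add_rxn(m, "TR_ac", c(ac_c = -1, ac_e = 1))
  m <- add_rxn(m, "TR_etoh", c(etoh_c = -1, etoh_e = 1), lb = 0)
  m <- add_rxn(m, "CODH", c(co_c = -1, h2o_c = -1, co2_c = 1, h2_c = 1),
               lb = 0, name = "CO dehydrogenase (lumped)")
  m <- add_rxn(m, "WLP", c(co2_c = -2, h2_c = -4, accoa_c = 1, h2o_c = 2),
               lb = 0, name = "acetyl-CoA synthesis (lumped WLP)")
  m <- add_rxn(m, "ACK", c(accoa_c = -1, adp_c = -1, pi_c = -1, ac_c = 1,
                           atp_c = 1, h2o_c = 1), lb = 0,
               name = "acetate kinase (lumped SLP)")
  m <- add_rxn(m, "AOR", c(ac_c = -1, h2_c = -2, etoh_c = 1, h2o_c = 1),
               lb = 0, name = "acetate reduction to ethanol (lumped AOR+ADH)")
  if (spec$include_succinate_route) {
    m <- toy_exchange(m, "succ")
    m <- add_rxn(m, "SUCOVF", c(accoa_c = -2, succ_e = 1, h2_c = 1), lb = 0,
                 name = "succinate overflow (excreting)")
  }
  if (spec$include_formate_branch) {
    m <- toy_met(m, "form", "c")
    m <- toy_exchange(m, "form")
    m <- add_rxn(m, "FDH", c(co2_c = -1, h2_c = -1, form_c = 1),
                 name = "formate dehydrogenase")
    m <- add_rxn(m, "TR_form", c(form_c = -1, form_e = 1), lb = 0)
  }
  by <- spec$biomass_yield_coeffs
  m <- add_rxn(m, "BIOMASS",
               c(accoa_c = -unname(by[["accoa"]]),
                 atp_c = -unname(by[["atp"]]), h2o_c = -unname(by[["atp"]]),
                 adp_c = unname(by[["atp"]]), pi_c = unname(by[["atp"]])),
               lb = 0, name = "biomass synthesis", is_biomass = TRUE)
  m <- add_rxn(m, "ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
               lb = 0, name = "ATP maintenance")
  m$objective <- list(reaction = "BIOMASS", direction = "max")
  internal <- c("CODH", "WLP", "ACK", "AOR",
                if (spec$include_succinate_route) "SUCOVF",
                if (spec$include_formate_branch) "FDH")
  m <- assign_genes(m, "gA", internal, spec$seed)
  attr(m, "atpm_specific") <- spec$atpm_specific
  if (spec$include_mcfa_reduction) m <- add_mcfa_reduction_pathway(m, "c")
  validate_model(m)
  audit <- check_mass_balance(m)
  if (!all(audit$balanced)) {
    stop("generator bug: imbalanced reactions ",
         paste(audit$reaction[!audit$balanced], collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Generate the toy chain-elongator model
#'
#' A lumped reverse-beta-oxidation chain elongator: it oxidises ethanol to
#' acetyl-CoA (releasing reducing equivalents), activates acetate at ATP
#' cost, condenses acetyl-CoA to crotonyl-level C4 which is reduced to
#' butyrate in the single ATP-conserving step (lumping the substrate-level
#' phosphorylation and ion-gradient energy conservation of chain elongation),
#' elongates butyrate to hexanoate, fixes CO2 into pyruvate for biomass
#' (making CO2 essential for growth), and optionally converts succinate to
#' crotonyl-level C4 without ATP expense. A CO dehydrogenase plus CO
#' transport is present but is intended to be blocked at the community level
#' (the organism is CO-sensitive in vivo). Ethanol uptake saturates at
#' \code{etoh_uptake_vmax}. Growth requires ethanol, acetate and CO2
#' simultaneously; by design neither ethanol-only nor acetate-only feeds
#' support growth.
#'
#' @param spec a \code{\link{toy_network_spec}} with role
#'   \code{"chain_elongator"}.
#' @return a validated \code{metabolic_model}.
#' @export
make_toy_elongator <- function(spec = toy_network_spec("chain_elongator")) {
  stopifnot(inherits(spec, "toy_network_spec"),
            spec$species_role == "chain_elongator")
  m <- new_toy_model("toy_elongator")
  for (b in c("co", "co2", "h2", "h2o", "ac", "etoh", "accoa", "croc",
              "buty", "hexa", "pyr", "atp", "adp", "pi")) {
    m <- toy_met(m, b, "c")
  }
  m <- toy_exchange(m, "co"); m <- toy_exchange(m, "h2")
  m <- toy_exchange(m, "co2"); m <- toy_exchange(m, "h2o")
  m <- toy_exchange(m, "ac"); m <- toy_exchange(m, "etoh")
  m <- toy_exchange(m, "buty"); m <- toy_exchange(m, "hexa")
  m <- add_rxn(m, "TR_etoh", c(etoh_e = -1, etoh_c = 1), lb = 0,
               ub = spec$etoh_uptake_vmax,
               name = "ethanol uptake (saturating)")
  m <- add_rxn(m, "TR_ac", c(ac_e = -1, ac_c = 1), lb = 0)
  m <- add_rxn(m, "TR_co2", c(co2_e = -1, co2_c = 1))
  m <- add_rxn(m, "TR_h2", c(h2_c = -1, h2_e = 1), lb = 0,
               name = "hydrogen release")
  m <- add_rxn(m, "TR_h2o", c(h2o_c = -1, h2o_e = 1))
  m <- add_rxn(m, "TR_co", c(co_e = -1, co_c = 1), lb = 0)
  m <- add_rxn(m, "TR_buty", c(buty_c = -1, buty_e = 1), lb = 0)
  m <- add_rxn(m, "TR_hexa", c(hexa_c = -1, hexa_e = 1), lb = 0)
  m <- add_rxn(m, "ETOHDH",
               c(etoh_c = -1, h2o_c = -1, accoa_c = 1, h2_c = 2), lb = 0,
               name = "ethanol oxidation to acetyl-CoA")
  m <- add_rxn(m, "ACTIV", c(ac_c = -1, atp_c = -1, h2o_c = -1, accoa_c = 1,
                             adp_c = 1, pi_c = 1), lb = 0,
               name = "acetate activation")
  m <- add_rxn(m, "RBOX1", c(accoa_c = -2, h2_c = -1, croc_c = 1,
                             h2o_c = 2), lb = 0,
               name = "acetyl-CoA condensation to crotonyl level")
  m <- add_rxn(m, "RBOX2", c(croc_c = -1, h2_c = -1, adp_c = -1, pi_c = -1,
                             buty_c = 1, atp_c = 1, h2o_c = 1), lb = 0,
               name = "butyrate formation (energy-conserving)")
  m <- add_rxn(m, "RBOX3", c(buty_c = -1, accoa_c = -1, h2_c = -2,
                             hexa_c = 1, h2o_c = 2), lb = 0,
               name = "elongation to hexanoate")
  m <- add_rxn(m, "CODH", c(co_c = -1, h2o_c = -1, co2_c = 1, h2_c = 1),
               lb = 0, name = "CO dehydrogenase (blocked in community)")
  m <- add_rxn(m, "PYRS", c(accoa_c = -1, co2_c = -1, h2_c = -1, pyr_c = 1,
                            h2o_c = 1), lb = 0, name = "pyruvate synthase")
  if (spec$include_succinate_route) {
    m <- toy_exchange(m, "succ")
    m <- toy_met(m, "succ", "c")
    m <- add_rxn(m, "TR_succ", c(succ_e = -1, succ_c = 1), lb = 0)
    m <- add_rxn(m, "SUCCROC", c(succ_c = -1, h2_c = -2, croc_c = 1,
                                 h2o_c = 2), lb = 0,
                 name = "succinate to crotonyl level")
  }
  by <- spec$biomass_yield_coeffs
  m <- add_rxn(m, "BIOMASS",
               c(pyr_c = -unname(by[["pyr"]]), ac_c = -unname(by[["ac"]]),
                 atp_c = -unname(by[["atp"]]), h2o_c = -unname(by[["atp"]]),
                 adp_c = unname(by[["atp"]]), pi_c = unname(by[["atp"]])),
               lb = 0, name = "biomass synthesis", is_biomass = TRUE)
  m <- add_rxn(m, "ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
               lb = 0, name = "ATP maintenance")
  m$objective <- list(reaction = "BIOMASS", direction = "max")
  internal <- c("ETOHDH", "ACTIV", "RBOX1", "RBOX2", "RBOX3", "CODH", "PYRS",
                if (spec$include_succinate_route) "SUCCROC")
  m <- assign_genes(m, "gK", internal, spec$seed)
  attr(m, "atpm_specific") <- spec$atpm_specific
  validate_model(m)
  audit <- check_mass_balance(m)
  if (!all(audit$balanced)) {
    stop("generator bug: imbalanced reactions ",
         paste(audit$reaction[!audit$balanced], collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Build the default toy community model
#'
#' Convenience wrapper: generates the toy acetogen and elongator, merges them
#' with tags \code{"c"}/\code{"ck"}, wires the standard cross-feeding routes
#' (H2 from elongator to acetogen, acetate from acetogen to elongator with a
#' dedicated acetogen uptake route, ethanol and succinate toward the
#' elongator) and blocks CO uptake by the elongator.
#'
#' @param include_succinate_route passed to both generators.
#' @param seed generator seed.
#' @param etoh_uptake_vmax elongator ethanol uptake cap.
#' @return merged community \code{metabolic_model}.
#' @export
make_toy_community <- function(include_succinate_route = TRUE, seed = 1L,
                               etoh_uptake_vmax = 0.25) {
  a <- make_toy_acetogen(toy_network_spec(
    "acetogen", include_succinate_route = include_succinate_route,
    seed = seed))
  k <- make_toy_elongator(toy_network_spec(
    "chain_elongator", include_succinate_route = include_succinate_route,
    seed = seed + 1L, etoh_uptake_vmax = etoh_uptake_vmax))
  spec <- merge_spec(
    species_a = a, tag_a = "c", species_b = k, tag_b = "ck",
    routing = data.frame(
      metabolite = c("h2", "ac", "etoh"),
      producer = c("ck", "c", "c"),
      consumer = c("c", "ck", "ck"),
      uptake_by_producer = c(FALSE, TRUE, FALSE),
      stringsAsFactors = FALSE),
    blocked_uptakes = data.frame(species = "ck", metabolite = "co",
                                 stringsAsFactors = FALSE))
  merge_models(spec)
}

#' Scenario grid specification
#'
#' @param co_feed CO feed rate (mmol l-1 h-1).
#' @param h2_feeds vector of H2 feed rates.
#' @param acetate_feeds vector of acetate feed rates.
#' @param succinate_feeds vector of succinate feed rates.
#' @param biomass_ratios list of two-element named vectors
#'   \code{c(ck = , c = )} summing to 1.
#' @param hrt hydraulic retention time (h).
#' @param working_volume litres.
#' @param community_biomass X_T, gDW l-1.
#' @param noise_sd multiplicative lognormal noise sd on synthetic
#'   "measured" product rates (0 = noiseless).
#' @param seed integer seed.
#' @return object of class \code{scenario_grid_spec}.
#' @export
scenario_grid_spec <- function(co_feed = 4.8, h2_feeds = c(0, 2.4, 5.3),
                               acetate_feeds = 0, succinate_feeds = 0,
                               biomass_ratios = list(c(ck = 0.685,
                                                       c = 0.315)),
                               hrt = 48, working_volume = 1,
                               community_biomass = 0.4,
                               noise_sd = 0.05, seed = 1L) {
  for (r in biomass_ratios) {
    if (abs(sum(r) - 1) > 1e-9) stop("ratios must sum to 1", call. = FALSE)
  }
  if (any(c(co_feed, h2_feeds, acetate_feeds, succinate_feeds) < 0)) {
    stop("feeds must be >= 0", call. = FALSE)
  }
  structure(list(co_feed = co_feed, h2_feeds = h2_feeds,
                 acetate_feeds = acetate_feeds,
                 succinate_feeds = succinate_feeds,
                 biomass_ratios = biomass_ratios, hrt = hrt,
                 working_volume = working_volume,
                 community_biomass = community_biomass,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scenario_grid_spec")
}

## canonical community solve used to synthesise "measurements": maximise
## hexanoate export, break ties parsimoniously (minimal total absolute flux)
canonical_solve <- function(model, constraints) {
  solve_fba(model, constraints, objective = "EX_hexa_e", sense = "max",
            parsimonious = TRUE)
}

#' Generate chemostat scenarios over a feed/ratio grid
#'
#' For every grid point the toy community is constrained with the feeds,
#' biomass and maintenance terms, solved canonically (maximal hexanoate
#' export with a parsimonious tie-break), and the resulting product exchange
#' fluxes become the scenario's synthetic "measured" products, optionally
#' perturbed by multiplicative lognormal noise. Infeasible grid points are
#' still emitted, flagged via \code{attr(scenario, "infeasible")}.
#'
#' @param grid a \code{\link{scenario_grid_spec}}.
#' @param abundance default \code{\link{species_abundance}} used when the
#'   grid's \code{biomass_ratios} entry is NULL; otherwise each ratio becomes
#'   its own abundance.
#' @param model optionally a pre-built community model (defaults to
#'   \code{\link{make_toy_community}()}).
#' @param products metabolite base names reported as measured products.
#' @return list of \code{\link{chemostat_scenario}} objects.
#' @export
make_scenarios <- function(grid, abundance = NULL, model = NULL,
                           products = c("ac", "etoh", "buty", "hexa")) {
  stopifnot(inherits(grid, "scenario_grid_spec"))
  if (is.null(model)) model <- make_toy_community(seed = grid$seed)
  atpm <- c(c = attr_or(model, "atpm_specific_c", 0.45),
            ck = attr_or(model, "atpm_specific_ck", 0.45))
  set.seed(grid$seed)
  out <- list()
  for (ratio in grid$biomass_ratios) {
    ab <- if (is.null(ratio)) abundance else species_abundance(ratio)
    for (h2 in grid$h2_feeds) for (acf in grid$acetate_feeds)
      for (sf in grid$succinate_feeds) {
        feeds <- c(co = grid$co_feed, h2 = h2, ac = acf, succ = sf)
        feeds <- feeds[feeds > 0 | names(feeds) == "co"]
        sc <- chemostat_scenario(
          feeds = feeds, measured_products = numeric(0), hrt = grid$hrt,
          working_volume = grid$working_volume,
          community_biomass = grid$community_biomass, abundance = ab,
          atpm_specific = atpm,
          cross_feeds = c(succ = "ck"))
        cs <- build_constraints(model, sc)
        sol <- canonical_solve(model, cs)
        if (sol$status != "optimal") {
          attr(sc, "infeasible") <- TRUE
          out[[length(out) + 1]] <- sc
          next
        }
        meas <- vapply(products, function(p) {
          v <- sol$fluxes[[paste0("EX_", p, "_e")]]
          if (is.null(v) || v < 1e-9) 0 else v
        }, numeric(1))
        meas <- meas[meas > 0]
        if (grid$noise_sd > 0) {
          meas <- meas * stats::rlnorm(length(meas), -grid$noise_sd^2 / 2,
                                       grid$noise_sd)
        }
        sc$measured_products <- meas
        attr(sc, "generating_fluxes") <- sol$fluxes
        out[[length(out) + 1]] <- sc
      }
  }
  out
}

attr_or <- function(x, name, default) {
  v <- attr(x, name, exact = TRUE)
  if (is.null(v)) default else v
}

#' Write pipeline-ready fixtures to a directory
#'
#' Emits the two toy single-species SBML models, a merge specification
#' (JSON) and a scenario table (TSV) so the complete pipeline can be driven
#' from files.
#'
#' @param dir output directory (created if missing).
#' @param seed generator seed.
#' @return invisibly the vector of written paths.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- make_toy_acetogen(toy_network_spec("acetogen", seed = seed))
  k <- make_toy_elongator(toy_network_spec("chain_elongator",
                                           seed = seed + 1L))
  pa <- file.path(dir, "toy_acetogen.xml")
  pk <- file.path(dir, "toy_elongator.xml")
  write_model(a, pa, "sbml")
  write_model(k, pk, "sbml")
  spec <- list(
    species_a = "toy_acetogen.xml", tag_a = "c",
    species_b = "toy_elongator.xml", tag_b = "ck",
    routing = data.frame(metabolite = c("h2", "ac", "etoh"),
                         producer = c("ck", "c", "c"),
                         consumer = c("c", "ck", "ck"),
                         uptake_by_producer = c(FALSE, TRUE, FALSE)),
    blocked_uptakes = data.frame(species = "ck", metabolite = "co"))
  ps <- file.path(dir, "merge_spec.json")
  jsonlite::write_json(spec, ps, auto_unbox = TRUE, digits = NA)
  grid <- scenario_grid_spec(seed = seed)
  scen <- make_scenarios(grid)
  rows <- do.call(rbind, lapply(seq_along(scen), function(i) {
    sc <- scen[[i]]
    data.frame(
      scenario = i,
      feeds = paste(sprintf("%s=%g", names(sc$feeds), sc$feeds),
                    collapse = ";"),
      products = paste(sprintf("%s=%g", names(sc$measured_products),
                               sc$measured_products), collapse = ";"),
      hrt = sc$hrt, working_volume = sc$working_volume,
      community_biomass = sc$community_biomass,
      phi_ck = sc$abundance$fractions[["ck"]],
      phi_c = sc$abundance$fractions[["c"]],
      infeasible = isTRUE(attr(sc, "infeasible")),
      stringsAsFactors = FALSE)
  }))
  pt <- file.path(dir, "scenarios.tsv")
  utils::write.table(rows, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pa, pk, ps, pt))
}
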