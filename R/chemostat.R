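#' Chemostat scenario
#'
#' Bundles the measurements and operating parameters of one chemostat
#' steady state: substrate feed rates, measured product formation rates, the
#' hydraulic retention time (which fixes the dilution rate and hence the
#' common growth rate), working volume, total community biomass and the
#' species biomass fractions.
#'
#' @param feeds named numeric vector of substrate feed rates
#'   (mmol l-1 h-1, >= 0); names are extracellular metabolite base names
#'   (e.g. \code{co}, \code{h2}, \code{ac}, \code{succ}).
#' @param measured_products named numeric vector of measured product
#'   formation rates (mmol l-1 h-1).
#' @param hrt hydraulic retention time, hours (> 0).
#' @param working_volume reactor working volume, litres (> 0).
#' @param community_biomass total community biomass X_T, gDW l-1 (> 0).
#' @param abundance a \code{\link{species_abundance}}.
#' @param atpm_specific named numeric vector: non-growth ATP maintenance per
#'   species tag, mmol gDW-1 h-1.
#' @param cross_feeds named character vector: metabolite base name ->
#'   consumer species tag, for cross-fed intermediates whose transport must
#'   be forced from the extracellular compartment into the consumer.
#' @return object of class \code{chemostat_scenario}.
#' @export
chemostat_scenario <- function(feeds, measured_products = numeric(0),
                               hrt, working_volume = 1,
                               community_biomass, abundance,
                               atpm_specific = numeric(0),
                               cross_feeds = character(0)) {
  stopifnot(hrt > 0, working_volume > 0, community_biomass > 0)
  if (any(feeds < 0)) stop("feeds must be >= 0", call. = FALSE)
  if (any(measured_products < 0)) {
    stop("measured product rates must be >= 0", call. = FALSE)
  }
  structure(list(feeds = feeds, measured_products = measured_products,
                 hrt = hrt, working_volume = working_volume,
                 community_biomass = community_biomass,
                 abundance = abundance, atpm_specific = atpm_specific,
                 cross_feeds = cross_feeds),
            class = "chemostat_scenario")
}

#' Dilution rate from hydraulic retention time
#'
#' In a chemostat at steady state the dilution rate D = 1/HRT equals the
#' specific growth rate of every washed-out organism.
#'
#' @param hrt hydraulic retention time, hours (> 0).
#' @return dilution rate, 1/h.
#' @export
dilution_rate <- function(hrt) {
  if (any(hrt <= 0)) stop("hrt must be > 0", call. = FALSE)
  1 / hrt
}

#' Convert steady-state concentrations to volumetric rates
#'
#' At steady state a product accumulating to concentration c (mM) in a
#' chemostat with hydraulic retention time HRT is produced at c / HRT
#' mmol l-1 h-1 (washout balance). The inverse relation recovers the
#' concentration as rate * HRT.
#'
#' @param concentrations named numeric vector, mM (>= 0).
#' @param hrt hydraulic retention time, hours (> 0).
#' @return named numeric vector of rates, mmol l-1 h-1.
#' @export
concentrations_to_rates <- function(concentrations, hrt) {
  if (any(hrt <= 0)) stop("hrt must be > 0", call. = FALSE)
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  concentrations / hrt
}

#' Build flux constraints from a chemostat scenario
#'
#' Translates a \code{\link{chemostat_scenario}} into bounds on the community
#' model, all in environmental-flux units (mmol l-1 h-1):
#' \itemize{
#'   \item each substrate feed fixes its exchange reaction to uptake at the
#'     feed rate (\code{lb = ub = -feed}; with \code{fix_feeds = FALSE} the
#'     feed is an upper limit on uptake: \code{lb = -feed, ub = 0});
#'   \item each measured product must be formed at a rate of at least
#'     \code{product_floor} times the measurement (exchange lower bound);
#'   \item the biomass reaction of species i is fixed (both bounds) to
#'     \code{mu * X_T * phi_i}, with \code{mu = 1/HRT}, so all species grow
#'     at the common dilution rate;
#'   \item the ATP-maintenance reaction of species i must carry at least
#'     \code{atpm_specific_i * X_T * phi_i};
#'   \item transports of cross-fed metabolites are forced to run from the
#'     extracellular compartment into the consumer species.
#' }
#'
#' @param model community \code{metabolic_model}.
#' @param scenario a \code{\link{chemostat_scenario}}.
#' @param product_floor fraction of the measured product rate that must be
#'   attained (default 0.8).
#' @param fix_feeds fix substrate uptake exactly at the feed rate (default
#'   \code{TRUE}); set \code{FALSE} for a maximum-uptake sensitivity mode.
#' @param open_exchanges base names of extracellular metabolites that may be
#'   drawn freely from the medium even when not fed (default water and CO2).
#'   Every other non-fed exchange reaction is closed in the uptake direction,
#'   so nothing enters the system that is not in the feed.
#' @return object of class \code{constraint_set}: list with \code{bounds}
#'   (data.frame \code{reaction}, \code{lb}, \code{ub}), \code{growth_rate},
#'   and \code{notes} describing every applied rule.
#' @export
build_constraints <- function(model, scenario, product_floor = 0.8,
                              fix_feeds = TRUE,
                              open_exchanges = c("h2o", "co2")) {
  if (product_floor < 0 || product_floor > 1) {
    stop("product_floor must be in [0, 1]", call. = FALSE)
  }
  mu <- dilution_rate(scenario$hrt)
  xt <- scenario$community_biomass
  phi <- scenario$abundance$fractions
  comp_of <- stats::setNames(model$metabolites$compartment,
                             model$metabolites$id)
  ex_rxn_for <- function(met) {
    mid <- paste0(met, "_e")
    hits <- model$reactions$id[model$reactions$is_exchange &
      vapply(model$stoich[model$reactions$id], function(s) {
        length(s) == 1 && names(s) == mid
      }, logical(1))]
    if (!length(hits)) {
      stop("no exchange reaction for metabolite '", met, "'", call. = FALSE)
    }
    hits[1]
  }
  bounds <- list(); notes <- character(0)
  add_bound <- function(rid, lb, ub, why) {
    bounds[[length(bounds) + 1]] <<- data.frame(reaction = rid, lb = lb,
                                                ub = ub,
                                                stringsAsFactors = FALSE)
    notes <<- c(notes, why)
  }

  prods <- names(scenario$measured_products)
  for (met in names(scenario$feeds)) {
    rid <- ex_rxn_for(met)
    f <- scenario$feeds[[met]]
    if (met %in% prods) {
      ## fed and measured: constrain the net exchange balance
      net <- product_floor * scenario$measured_products[[met]] - f
      add_bound(rid, net, 1000,
                sprintf("net exchange of fed+measured %s >= %.4g", met, net))
    } else if (fix_feeds) {
      add_bound(rid, -f, -f, sprintf("feed %s fixed at %.4g", met, f))
    } else {
      add_bound(rid, -f, 0, sprintf("feed %s limited to %.4g", met, f))
    }
  }
  for (met in setdiff(prods, names(scenario$feeds))) {
    rid <- ex_rxn_for(met)
    floor_rate <- product_floor * scenario$measured_products[[met]]
    add_bound(rid, floor_rate, 1000,
              sprintf("product %s >= %.0f%% of measured %.4g", met,
                      100 * product_floor,
                      scenario$measured_products[[met]]))
  }

  ## medium closure: nothing not fed (and not declared freely available)
  ## may be taken up from the environment
  touched <- vapply(bounds, function(b) b$reaction, character(1))
  open_ids <- vapply(open_exchanges, function(met) {
    tryCatch(ex_rxn_for(met), error = function(e) NA_character_)
  }, character(1))
  for (rid in model$reactions$id[model$reactions$is_exchange]) {
    if (rid %in% touched || rid %in% open_ids) next
    i <- rxn_row(model, rid)
    if (model$reactions$lb[i] < 0) {
      add_bound(rid, 0, model$reactions$ub[i],
                sprintf("medium closure: no uptake through %s", rid))
    }
  }

  ## species biomass reactions: identify by flag + internal compartment
  bm_ids <- model$reactions$id[model$reactions$is_biomass]
  for (rid in bm_ids) {
    comps <- setdiff(unique(comp_of[names(model$stoich[[rid]])]), "e")
    tag <- comps[1]
    if (!tag %in% names(phi)) next
    v <- mu * xt * phi[[tag]]
    add_bound(rid, v, v,
              sprintf("biomass[%s] = mu * X_T * phi = %.6g", tag, v))
  }
  for (tag in names(scenario$atpm_specific)) {
    rid <- paste0("ATPM_", tag)
    if (!rid %in% model$reactions$id) {
      stop("no ATP maintenance reaction '", rid, "' in model", call. = FALSE)
    }
    v <- scenario$atpm_specific[[tag]] * xt * phi[[tag]]
    add_bound(rid, v, 1000,
              sprintf("ATPM[%s] >= %.6g (specific %.3g scaled by X_T*phi)",
                      tag, v, scenario$atpm_specific[[tag]]))
  }

  ## force cross-fed transports toward the consumer
  for (met in names(scenario$cross_feeds)) {
    tag <- scenario$cross_feeds[[met]]
    e_id <- paste0(met, "_e"); in_id <- paste0(met, "_", tag)
    for (rid in model$reactions$id) {
      s <- model$stoich[[rid]]
      if (!(e_id %in% names(s) && in_id %in% names(s))) next
      i <- rxn_row(model, rid)
      if (s[[e_id]] < 0 && s[[in_id]] > 0) {        # e -> consumer
        add_bound(rid, max(0, model$reactions$lb[i]), model$reactions$ub[i],
                  sprintf("cross-feed %s -> %s forced forward", met, tag))
      } else if (s[[e_id]] > 0 && s[[in_id]] < 0) { # consumer -> e: block
        add_bound(rid, 0, 0,
                  sprintf("cross-feed %s: %s -> e blocked", met, tag))
      }
    }
  }

  structure(list(bounds = do.call(rbind, bounds), growth_rate = mu,
                 notes = notes),
            class = "constraint_set")
}

#' Apply a constraint set to a model
#'
#' @param model a \code{metabolic_model}.
#' @param constraints a \code{constraint_set} (or NULL for no-op).
#' @return the model with the overridden bounds.
#' @export
apply_constraints <- function(model, constraints) {
  if (is.null(constraints)) return(model)
  b <- constraints$bounds
  for (i in seq_len(nrow(b))) {
    model <- set_bounds(model, b$reaction[i], b$lb[i], b$ub[i])
  }
  model
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set> growth rate", format(x$growth_rate, digits = 4),
      "1/h,", nrow(x$bounds), "bounds\n")
  for (n in x$notes) cat("  -", n, "\n")
  invisible(x)
}
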