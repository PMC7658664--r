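#' Merge specification for a two-species community model
#'
#' Describes how two single-species models are combined: the compartment tag
#' each species receives, how extracellular metabolite names are unified, and
#' the explicit cross-feeding wiring (routing rules and blocked uptakes).
#'
#' @param species_a,species_b single-species \code{metabolic_model}s.
#' @param tag_a,tag_b distinct compartment tags (e.g. \code{"c"},
#'   \code{"ck"}).
#' @param namespace_map optional data.frame \code{species} (\code{"a"} or
#'   \code{"b"}), \code{from}, \code{to}: renames extracellular metabolite
#'   ids of one species onto the unified namespace. No fuzzy matching is
#'   attempted: identical ids are assumed to be the same compound (and must
#'   not carry conflicting formulas).
#' @param routing data.frame \code{metabolite} (extracellular base name),
#'   \code{producer}, \code{consumer} (tags), \code{uptake_by_producer}
#'   (logical): each rule replaces the species' transports of that metabolite
#'   by separate irreversible reactions so production into the medium, uptake
#'   by the consumer, and (optionally) uptake by the producer are distinct
#'   reported fluxes.
#' @param blocked_uptakes data.frame \code{species} (tag),
#'   \code{metabolite} (base name): uptake of the metabolite by that species
#'   is blocked (zero bounds in the uptake direction).
#' @param added_reactions optional list of extra reactions (each a list with
#'   \code{id}, \code{stoich}, optional \code{lb}, \code{ub}, \code{name}).
#' @return object of class \code{merge_spec}.
#' @export
merge_spec <- function(species_a, tag_a, species_b, tag_b,
                       namespace_map = NULL, routing = NULL,
                       blocked_uptakes = NULL, added_reactions = NULL) {
  if (identical(tag_a, tag_b)) stop("tags must be distinct", call. = FALSE)
  validate_model(species_a); validate_model(species_b)
  structure(list(species_a = species_a, tag_a = tag_a,
                 species_b = species_b, tag_b = tag_b,
                 namespace_map = namespace_map, routing = routing,
                 blocked_uptakes = blocked_uptakes,
                 added_reactions = added_reactions),
            class = "merge_spec")
}

## retag one species model: internal compartment -> tag, internal metabolite
## ids suffixed with the tag, non-exchange reaction ids suffixed with the tag
retag_species <- function(model, tag, which_species, namespace_map) {
  internal <- setdiff(names(model$compartments), "e")
  if (length(internal) != 1) {
    stop("expected exactly one internal compartment in '", model$id, "'",
         call. = FALSE)
  }
  old <- internal
  met <- model$metabolites
  remap <- stats::setNames(met$id, met$id)
  for (i in seq_len(nrow(met))) {
    if (met$compartment[i] == old) {
      base <- sub(paste0("_", old, "$"), "", met$id[i])
      remap[[met$id[i]]] <- paste0(base, "_", tag)
    }
  }
  if (!is.null(namespace_map)) {
    nm <- namespace_map[namespace_map$species == which_species, , drop = FALSE]
    for (i in seq_len(nrow(nm))) {
      if (!nm$from[i] %in% names(remap)) {
        stop("namespace map entry for absent metabolite: ", nm$from[i],
             call. = FALSE)
      }
      remap[[nm$from[i]]] <- nm$to[i]
    }
  }
  met$id <- unname(remap[met$id])
  met$compartment[met$compartment == old] <- tag
  comps <- model$compartments
  names(comps)[names(comps) == old] <- tag
  comps[[tag]] <- paste0("cytosol_", tag)
  rxn <- model$reactions
  new_rid <- ifelse(rxn$is_exchange | endsWith(rxn$id, paste0("_", tag)),
                    rxn$id, paste0(rxn$id, "_", tag))
  stoich <- lapply(model$stoich, function(s) {
    stats::setNames(unname(s), unname(remap[names(s)]))
  })
  names(stoich) <- new_rid[match(names(model$stoich), rxn$id)]
  rxn$id <- new_rid
  model$metabolites <- met
  model$compartments <- comps
  model$reactions <- rxn
  model$stoich <- stoich
  model
}

## find transports of extracellular metabolite e_id into/out of species tag
transports_of <- function(model, e_id, tag) {
  hits <- character(0)
  suffix <- paste0("_", tag)
  for (rid in model$reactions$id[!model$reactions$is_exchange]) {
    s <- model$stoich[[rid]]
    if (e_id %in% names(s) &&
        any(endsWith(setdiff(names(s), e_id), suffix))) {
      hits <- c(hits, rid)
    }
  }
  hits
}

#' Merge two single-species models into a community model
#'
#' Produces a three-compartment community model (two internal compartments
#' plus the shared extracellular compartment \code{"e"}): internal metabolite
#' and reaction ids are suffixed with the species tag, shared extracellular
#' metabolites are deduplicated (colliding ids must agree on their formula),
#' duplicate exchange reactions are collapsed onto the lexicographically
#' first id (logged as an alias), each species gets an extracellular biomass
#' metabolite with a transport and an exchange reaction, routing rules are
#' realised as separate irreversible transports, and blocked uptakes get
#' zero bounds. The merge log (aliases, added and dropped reactions) is
#' attached as \code{attr(model, "merge_log")}.
#'
#' @param spec a \code{\link{merge_spec}}.
#' @return a validated community \code{metabolic_model}.
#' @export
merge_models <- function(spec) {
  stopifnot(inherits(spec, "merge_spec"))
  a <- retag_species(spec$species_a, spec$tag_a, "a", spec$namespace_map)
  b <- retag_species(spec$species_b, spec$tag_b, "b", spec$namespace_map)
  log <- list(aliases = character(0), added = character(0),
              dropped = character(0))

  ## collision audit on the shared extracellular namespace
  ea <- a$metabolites[a$metabolites$compartment == "e", ]
  eb <- b$metabolites[b$metabolites$compartment == "e", ]
  common <- intersect(ea$id, eb$id)
  fa <- stats::setNames(ea$formula, ea$id)[common]
  fb <- stats::setNames(eb$formula, eb$id)[common]
  clash <- common[!is.na(fa) & !is.na(fb) & fa != fb]
  if (length(clash)) {
    stop("extracellular namespace collision (conflicting formulas), ",
         "extend the namespace map: ", paste(clash, collapse = ", "),
         call. = FALSE)
  }

  compartments <- c(a$compartments[spec$tag_a], b$compartments[spec$tag_b],
                    c(e = "extracellular"))
  mets <- rbind(a$metabolites, b$metabolites)
  mets <- mets[!duplicated(mets$id), , drop = FALSE]

  ## collapse duplicate exchange reactions (same extracellular metabolite);
  ## the lexicographically first id survives, widened to the union of bounds
  rxns <- rbind(a$reactions, b$reactions)
  stl <- c(a$stoich[a$reactions$id], b$stoich[b$reactions$id])
  ex_rows <- which(rxns$is_exchange)
  ex_met <- vapply(ex_rows, function(r) names(stl[[r]])[1], character(1))
  drop_rows <- integer(0)
  for (mid in unique(ex_met[duplicated(ex_met)])) {
    rows <- ex_rows[ex_met == mid]
    keep_row <- rows[order(rxns$id[rows])][1]
    other_rows <- setdiff(rows, keep_row)
    rxns$lb[keep_row] <- min(rxns$lb[rows])
    rxns$ub[keep_row] <- max(rxns$ub[rows])
    log$aliases <- c(log$aliases,
                     stats::setNames(rep(rxns$id[keep_row],
                                         length(other_rows)),
                                     rxns$id[other_rows]))
    drop_rows <- c(drop_rows, other_rows)
  }
  if (length(drop_rows)) {
    log$dropped <- unique(rxns$id[drop_rows])
    rxns <- rxns[-drop_rows, , drop = FALSE]
    stl <- stl[-drop_rows]
  }
  if (anyDuplicated(rxns$id)) {
    stop("merge error: colliding reaction ids after tagging: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "),
         call. = FALSE)
  }
  stoich <- stats::setNames(stl, rxns$id)

  model <- structure(list(id = paste0(spec$species_a$id, "__",
                                      spec$species_b$id),
                          compartments = compartments,
                          metabolites = mets,
                          reactions = rxns,
                          stoich = stoich[rxns$id],
                          objective = list(reaction = NA_character_,
                                           direction = "max")),
                     class = "metabolic_model")

  ## biomass metabolite + transport + exchange per species
  for (tag in c(spec$tag_a, spec$tag_b)) {
    bm_ids <- model$reactions$id[model$reactions$is_biomass &
                                   endsWith(model$reactions$id,
                                            paste0("_", tag))]
    if (length(bm_ids) != 1) {
      stop("species '", tag, "' must have exactly one biomass reaction",
           call. = FALSE)
    }
    bmet <- paste0("BIOMASS_", tag)
    bmet_e <- paste0("BIOMASS_", tag, "_e")
    model <- add_met(model, bmet, tag, name = paste("biomass", tag))
    model <- add_met(model, bmet_e, "e", name = paste("biomass", tag))
    s <- model$stoich[[bm_ids]]
    s[bmet] <- 1
    model$stoich[[bm_ids]] <- s
    tr <- paste0("TR_BIOMASS_", tag)
    ex <- paste0("EX_BIOMASS_", tag, "_e")
    model <- add_rxn(model, tr, stats::setNames(c(-1, 1), c(bmet, bmet_e)),
                     lb = 0, name = paste("biomass export", tag))
    model <- add_rxn(model, ex, stats::setNames(-1, bmet_e), lb = 0,
                     is_exchange = TRUE, name = paste("biomass sink", tag))
    log$added <- c(log$added, tr, ex)
  }

  ## routing rules: split shared-metabolite transports into distinct
  ## irreversible production / uptake reactions
  if (!is.null(spec$routing)) {
    for (i in seq_len(nrow(spec$routing))) {
      rr <- spec$routing[i, ]
      e_id <- paste0(rr$metabolite, "_e")
      for (tag in c(rr$producer, rr$consumer)) {
        if (!paste0(rr$metabolite, "_", tag) %in% model$metabolites$id) {
          stop("routing rule for '", rr$metabolite,
               "': metabolite absent in species '", tag, "'", call. = FALSE)
        }
      }
      caps <- list()
      for (tag in unique(c(rr$producer, rr$consumer))) {
        for (rid in transports_of(model, e_id, tag)) {
          s <- model$stoich[[rid]]
          r <- model$reactions[rxn_row(model, rid), ]
          if (s[[e_id]] < 0) {          # forward = uptake
            caps[[paste0("in_", tag)]] <-
              min(caps[[paste0("in_", tag)]] %||% Inf, r$ub)
            if (r$lb < 0) caps[[paste0("out_", tag)]] <-
                min(caps[[paste0("out_", tag)]] %||% Inf, -r$lb)
          } else {                      # forward = production
            caps[[paste0("out_", tag)]] <-
              min(caps[[paste0("out_", tag)]] %||% Inf, r$ub)
            if (r$lb < 0) caps[[paste0("in_", tag)]] <-
                min(caps[[paste0("in_", tag)]] %||% Inf, -r$lb)
          }
          model <- drop_rxn(model, rid)
          log$dropped <- c(log$dropped, rid)
        }
      }
      mk <- function(id, stoich, cap) {
        model <<- add_rxn(model, id, stoich, lb = 0,
                          ub = min(cap %||% Inf, 1000))
        log$added <<- c(log$added, id)
      }
      p <- rr$producer; q <- rr$consumer
      mk(paste0("TR_", rr$metabolite, "_out_", p),
         stats::setNames(c(-1, 1), c(paste0(rr$metabolite, "_", p), e_id)),
         caps[[paste0("out_", p)]])
      mk(paste0("TR_", rr$metabolite, "_in_", q),
         stats::setNames(c(-1, 1), c(e_id, paste0(rr$metabolite, "_", q))),
         caps[[paste0("in_", q)]])
      if (isTRUE(rr$uptake_by_producer)) {
        mk(paste0("TR_", rr$metabolite, "_in_", p),
           stats::setNames(c(-1, 1), c(e_id, paste0(rr$metabolite, "_", p))),
           caps[[paste0("in_", p)]])
      }
    }
  }

  ## blocked uptakes
  if (!is.null(spec$blocked_uptakes)) {
    for (i in seq_len(nrow(spec$blocked_uptakes))) {
      bu <- spec$blocked_uptakes[i, ]
      model <- block_cross_feed(model, bu$metabolite, bu$species)
    }
  }

  if (!is.null(spec$added_reactions)) {
    for (ar in spec$added_reactions) {
      model <- add_rxn(model, ar$id, unlist(ar$stoich),
                       lb = ar$lb %||% -1000, ub = ar$ub %||% 1000,
                       name = ar$name %||% ar$id)
      log$added <- c(log$added, ar$id)
    }
  }

  ## propagate maintenance attributes from the single-species models
  for (pair in list(list(spec$species_a, spec$tag_a),
                    list(spec$species_b, spec$tag_b))) {
    v <- attr(pair[[1]], "atpm_specific", exact = TRUE)
    if (!is.null(v)) attr(model, paste0("atpm_specific_", pair[[2]])) <- v
  }
  attr(model, "merge_log") <- log
  attr(model, "tags") <- c(spec$tag_a, spec$tag_b)
  validate_model(model)
  model
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Block uptake of an extracellular metabolite by one species
#'
#' Sets the bounds of every transport of the metabolite into the consumer
#' species to zero in the uptake direction. Original bounds are remembered
#' so \code{\link{unblock_cross_feed}} can restore them. Blocking an already
#' blocked route is a no-op.
#'
#' @param model community \code{metabolic_model}.
#' @param metabolite extracellular metabolite base name (e.g. \code{"co"}).
#' @param consumer species tag whose uptake is blocked.
#' @return the modified model.
#' @export
block_cross_feed <- function(model, metabolite, consumer) {
  e_id <- paste0(metabolite, "_e")
  trs <- transports_of(model, e_id, consumer)
  if (!length(trs)) {
    stop("no transport of '", metabolite, "' into species '", consumer, "'",
         call. = FALSE)
  }
  saved <- attr(model, "blocked_bounds") %||% list()
  for (rid in trs) {
    s <- model$stoich[[rid]]
    i <- rxn_row(model, rid)
    key <- paste0(metabolite, ":", consumer, ":", rid)
    if (is.null(saved[[key]])) {
      saved[[key]] <- c(model$reactions$lb[i], model$reactions$ub[i])
    }
    if (s[[e_id]] < 0) {               # forward flux = uptake
      model$reactions$ub[i] <- min(model$reactions$ub[i], 0)
      model$reactions$lb[i] <- min(model$reactions$lb[i], 0)
    } else {                           # reverse flux = uptake
      model$reactions$lb[i] <- max(model$reactions$lb[i], 0)
      model$reactions$ub[i] <- max(model$reactions$ub[i], 0)
    }
  }
  attr(model, "blocked_bounds") <- saved
  model
}

#' Restore bounds changed by \code{\link{block_cross_feed}}
#'
#' @inheritParams block_cross_feed
#' @return the modified model.
#' @export
unblock_cross_feed <- function(model, metabolite, consumer) {
  saved <- attr(model, "blocked_bounds") %||% list()
  prefix <- paste0(metabolite, ":", consumer, ":")
  keys <- grep(prefix, names(saved), fixed = TRUE, value = TRUE)
  if (!length(keys)) return(model)
  for (key in keys) {
    rid <- sub(prefix, "", key, fixed = TRUE)
    model <- set_bounds(model, rid, saved[[key]][1], saved[[key]][2])
    saved[[key]] <- NULL
  }
  attr(model, "blocked_bounds") <- saved
  model
}

#' Add the medium-chain fatty-acid reduction pathway to a species
#'
#' Adds, inside the tagged species compartment, uptake transports for
#' butyrate and hexanoate, acid-to-aldehyde reductions consuming one
#' reducing equivalent each (with water release), aldehyde-to-alcohol
#' reductions, alcohol export transports and alcohol exchange reactions.
#' All added reactions are carbon balanced (C4 acid to C4 alcohol, C6 acid
#' to C6 alcohol). Adding the pathway twice is a no-op.
#'
#' @param model a \code{metabolic_model} (single-species or community).
#' @param species_tag compartment tag receiving the pathway.
#' @param reducing_equiv base name of the intracellular reducing-equivalent
#'   metabolite (default \code{"h2"}, the lumped redox carrier of the toy
#'   models; real models would use reduced ferredoxin).
#' @return the modified model.
#' @export
add_mcfa_reduction_pathway <- function(model, species_tag,
                                       reducing_equiv = "h2") {
  t <- species_tag
  if (paste0("BTAOR_", t) %in% model$reactions$id) return(model)
  for (b in c("buty", "hexa")) {
    if (!paste0(b, "_e") %in% model$metabolites$id) {
      model <- toy_met(model, b, "e")
      model <- add_rxn(model, paste0("EX_", b, "_e"),
                       stats::setNames(-1, paste0(b, "_e")),
                       is_exchange = TRUE)
    }
  }
  red <- paste0(reducing_equiv, "_", t)
  h2o <- paste0("h2o_", t)
  missing <- setdiff(c(red, h2o), model$metabolites$id)
  if (length(missing)) {
    stop("cannot add MCFA reduction pathway: cofactor metabolite(s) missing ",
         "in species '", t, "': ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (b in c("buty", "hexa", "btal", "hxal", "btoh", "hxoh")) {
    model <- toy_met(model, b, t)
  }
  for (b in c("btoh", "hxoh")) {
    if (!paste0(b, "_e") %in% model$metabolites$id) {
      model <- toy_met(model, b, "e")
    }
    if (!paste0("EX_", b, "_e") %in% model$reactions$id) {
      model <- add_rxn(model, paste0("EX_", b, "_e"),
                       stats::setNames(-1, paste0(b, "_e")),
                       is_exchange = TRUE)
    }
  }
  mk <- function(id, stoich, name, genes = "") {
    add_rxn(model, id, stoich, lb = 0, name = name, genes = genes)
  }
  model <- mk(paste0("TR_buty_upt_", t),
              stats::setNames(c(-1, 1), c("buty_e", paste0("buty_", t))),
              "butyrate uptake")
  model <- mk(paste0("TR_hexa_upt_", t),
              stats::setNames(c(-1, 1), c("hexa_e", paste0("hexa_", t))),
              "hexanoate uptake")
  model <- mk(paste0("BTAOR_", t),
              stats::setNames(c(-1, -1, 1, 1),
                              c(paste0("buty_", t), red,
                                paste0("btal_", t), h2o)),
              "butyrate to butyraldehyde", "gM01")
  model <- mk(paste0("BTADH_", t),
              stats::setNames(c(-1, -1, 1),
                              c(paste0("btal_", t), red,
                                paste0("btoh_", t))),
              "butyraldehyde to butanol", "gM02")
  model <- mk(paste0("HXAOR_", t),
              stats::setNames(c(-1, -1, 1, 1),
                              c(paste0("hexa_", t), red,
                                paste0("hxal_", t), h2o)),
              "hexanoate to caproaldehyde", "gM01")
  model <- mk(paste0("HXADH_", t),
              stats::setNames(c(-1, -1, 1),
                              c(paste0("hxal_", t), red,
                                paste0("hxoh_", t))),
              "caproaldehyde to hexanol", "gM02")
  model <- mk(paste0("TR_btoh_", t),
              stats::setNames(c(-1, 1), c(paste0("btoh_", t), "btoh_e")),
              "butanol export")
  model <- mk(paste0("TR_hxoh_", t),
              stats::setNames(c(-1, 1), c(paste0("hxoh_", t), "hxoh_e")),
              "hexanol export")
  validate_model(model)
  model
}

#' Audit extracellular connectivity
#'
#' Every extracellular metabolite should be linked to at least one species
#' compartment by a transport reaction (biomass metabolites are linked by
#' their export reactions).
#'
#' @param model community \code{metabolic_model}.
#' @return character vector of unreachable extracellular metabolite ids
#'   (empty when the audit passes).
#' @export
audit_connectivity <- function(model) {
  e_mets <- model$metabolites$id[model$metabolites$compartment == "e"]
  reached <- character(0)
  for (rid in model$reactions$id[!model$reactions$is_exchange]) {
    s <- model$stoich[[rid]]
    here <- intersect(names(s), e_mets)
    if (length(here) && length(setdiff(names(s), e_mets))) {
      reached <- c(reached, here)
    }
  }
  setdiff(e_mets, reached)
}
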