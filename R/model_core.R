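#' Construct a constraint-based metabolic model
#'
#' The central data structure of the package: a stoichiometric network with
#' compartments, flux bounds, gene associations, and designated biomass and
#' exchange reactions. Closely mirrors the constraint-based models used by the
#' COBRA family of tools.
#'
#' @param id model identifier.
#' @param compartments named character vector, names are compartment ids,
#'   values are display names.
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, and optionally \code{formula} and \code{charge}.
#' @param reactions data.frame with columns \code{id}, \code{name},
#'   \code{lb}, \code{ub}, \code{genes} (boolean gene-association string,
#'   \code{""} for none), \code{is_exchange}, \code{is_biomass}.
#' @param stoich named list; one entry per reaction id holding a named numeric
#'   vector of stoichiometric coefficients (negative = consumed).
#' @param objective list with \code{reaction} (id or \code{NA}) and
#'   \code{direction} (\code{"max"} or \code{"min"}).
#'
#' @return An object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions, stoich,
                            objective = list(reaction = NA_character_,
                                             direction = "max")) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  nm <- nrow(metabolites); nr <- nrow(reactions)
  if (is.null(metabolites$formula)) {
    metabolites$formula <- rep(NA_character_, nm)
  }
  if (is.null(metabolites$charge)) metabolites$charge <- rep(NA_integer_, nm)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$genes)) reactions$genes <- rep("", nr)
  if (is.null(reactions$is_exchange)) {
    reactions$is_exchange <- rep(FALSE, nr)
  }
  if (is.null(reactions$is_biomass)) reactions$is_biomass <- rep(FALSE, nr)
  reactions$lb[is.na(reactions$lb)] <- -1000
  reactions$ub[is.na(reactions$ub)] <- 1000
  m <- structure(list(id = id, compartments = compartments,
                      metabolites = metabolites, reactions = reactions,
                      stoich = stoich[reactions$id], objective = objective),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique ids, declared compartments,
#' stoichiometry referring only to declared metabolites, \code{lb <= ub},
#' exchange reactions touching exactly one extracellular metabolite, and at
#' most one biomass reaction per internal compartment.
#'
#' @param model a \code{metabolic_model}.
#' @param extracellular id of the extracellular compartment (default
#'   \code{"e"}).
#' @return invisibly \code{TRUE}; stops with a message listing all violations
#'   otherwise.
#' @export
validate_model <- function(model, extracellular = "e") {
  errs <- character(0)
  met <- model$metabolites; rxn <- model$reactions
  if (anyDuplicated(met$id)) {
    errs <- c(errs, paste("duplicate metabolite ids:",
                          paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rxn$id)) {
    errs <- c(errs, paste("duplicate reaction ids:",
                          paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  }
  badc <- setdiff(unique(met$compartment), names(model$compartments))
  if (length(badc)) {
    errs <- c(errs, paste("metabolites reference undeclared compartments:",
                          paste(badc, collapse = ", ")))
  }
  if (any(rxn$lb > rxn$ub)) {
    errs <- c(errs, paste("lb > ub for:",
                          paste(rxn$id[rxn$lb > rxn$ub], collapse = ", ")))
  }
  missing_st <- setdiff(rxn$id, names(model$stoich))
  if (length(missing_st)) {
    errs <- c(errs, paste("reactions without stoichiometry:",
                          paste(missing_st, collapse = ", ")))
  }
  for (rid in intersect(rxn$id, names(model$stoich))) {
    s <- model$stoich[[rid]]
    unknown <- setdiff(names(s), met$id)
    if (length(unknown)) {
      errs <- c(errs, paste0("reaction ", rid, " references undeclared metabolites: ",
                             paste(unknown, collapse = ", ")))
    }
    if (!length(s) && !rxn$is_exchange[rxn$id == rid]) {
      errs <- c(errs, paste0("reaction ", rid, " has empty stoichiometry"))
    }
  }
  comp_of <- stats::setNames(met$compartment, met$id)
  for (rid in rxn$id[rxn$is_exchange]) {
    s <- model$stoich[[rid]]
    if (length(s) != 1 || !identical(unname(comp_of[names(s)]), extracellular)) {
      errs <- c(errs, paste0("exchange reaction ", rid,
                             " must touch exactly one metabolite in '",
                             extracellular, "'"))
    }
  }
  bm <- rxn$id[rxn$is_biomass]
  if (length(bm)) {
    bc <- vapply(bm, function(rid) {
      cc <- setdiff(unique(comp_of[names(model$stoich[[rid]])]), extracellular)
      if (length(cc)) cc[1] else extracellular
    }, character(1))
    dup <- names(table(bc))[table(bc) > 1]
    if (length(dup)) {
      errs <- c(errs, paste("more than one biomass reaction in compartment:",
                            paste(dup, collapse = ", ")))
    }
  }
  if (length(errs)) stop("invalid model '", model$id, "':\n  ",
                         paste(errs, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, "\n")
  cat("  compartments:", paste(names(x$compartments), collapse = ", "), "\n")
  cat("  metabolites: ", nrow(x$metabolites), "\n")
  cat("  reactions:   ", nrow(x$reactions),
      sprintf("(%d exchange, %d biomass)", sum(x$reactions$is_exchange),
              sum(x$reactions$is_biomass)), "\n")
  if (!is.na(x$objective$reaction)) {
    cat("  objective:   ", x$objective$direction, x$objective$reaction, "\n")
  }
  invisible(x)
}

#' Classify reaction reversibility from Gibbs free energy
#'
#' A reaction is treated as reversible when its standard-condition Gibbs
#' energy change lies within \[-30, 30\] kJ/mol (boundaries included);
#' strongly exergonic reactions (below -30) run forward only and strongly
#' endergonic ones (above +30) backward only.
#'
#' @param delta_g numeric vector, kJ/mol. Must be finite.
#' @return data.frame with columns \code{delta_g} and \code{verdict}
#'   (\code{"reversible"}, \code{"forward_only"}, \code{"backward_only"}).
#' @export
classify_reversibility <- function(delta_g) {
  if (!is.numeric(delta_g) || any(!is.finite(delta_g))) {
    stop("delta_g must be finite numeric", call. = FALSE)
  }
  verdict <- ifelse(delta_g < -30, "forward_only",
                    ifelse(delta_g > 30, "backward_only", "reversible"))
  data.frame(delta_g = delta_g, verdict = verdict, stringsAsFactors = FALSE)
}

#' Stoichiometric matrix of a model
#'
#' @param model a \code{metabolic_model}.
#' @return sparse \code{Matrix} (metabolites x reactions) with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- model$reactions$id
  if (!length(mids) || !length(rids)) {
    return(Matrix::Matrix(0, length(mids), length(rids), sparse = TRUE,
                          dimnames = list(mids, rids)))
  }
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rids)) {
    s <- model$stoich[[rids[k]]]
    if (!length(s)) next
    i <- c(i, match(names(s), mids))
    j <- c(j, rep(k, length(s)))
    x <- c(x, unname(s))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

## Parse a chemical formula ("C2H4O2", "Fe8S8H2") into a named element count.
parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f))[[1]]
  el <- sub("[0-9.]*$", "", parts)
  ct <- sub("^[A-Za-z]+", "", parts)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  tapply(ct, el, sum)
}

#' Check elemental balance of internal reactions
#'
#' For every non-exchange, non-biomass reaction whose metabolites all carry
#' formulas, sums element counts weighted by stoichiometric coefficients. Used
#' as a structural audit of generated toy networks and as a test oracle.
#'
#' @param model a \code{metabolic_model}.
#' @param elements elements to audit.
#' @return data.frame with one row per audited reaction and one column per
#'   element holding the net imbalance (0 = balanced), plus a \code{balanced}
#'   logical column.
#' @export
check_mass_balance <- function(model, elements = c("C", "H", "O")) {
  met <- model$metabolites
  fmap <- stats::setNames(met$formula, met$id)
  rxn <- model$reactions
  audit <- rxn$id[!rxn$is_exchange & !rxn$is_biomass]
  rows <- lapply(audit, function(rid) {
    s <- model$stoich[[rid]]
    fs <- fmap[names(s)]
    if (any(is.na(fs) | !nzchar(fs))) return(NULL)
    tot <- stats::setNames(numeric(length(elements)), elements)
    for (k in seq_along(s)) {
      cnt <- parse_formula(fs[k])
      for (e in intersect(names(cnt), elements)) {
        tot[e] <- tot[e] + s[k] * cnt[[e]]
      }
    }
    c(list(reaction = rid), as.list(tot))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(reaction = character(0))
    out$balanced <- logical(0)
    return(out)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$balanced <- apply(abs(as.matrix(out[, elements, drop = FALSE])), 1,
                        max) < 1e-9
  out
}

## ---- convenience accessors used throughout the package ----

rxn_row <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (any(is.na(i))) stop("unknown reaction id(s): ",
                          paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Set flux bounds of a reaction
#' @param model a \code{metabolic_model}.
#' @param id reaction id.
#' @param lb,ub new bounds (either may be NULL to leave unchanged).
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- rxn_row(model, id)
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  model
}

#' Get flux bounds of reactions
#' @param model a \code{metabolic_model}.
#' @param id reaction ids (default all).
#' @return data.frame with \code{id}, \code{lb}, \code{ub}.
#' @export
get_bounds <- function(model, id = model$reactions$id) {
  i <- rxn_row(model, id)
  data.frame(id = model$reactions$id[i], lb = model$reactions$lb[i],
             ub = model$reactions$ub[i], stringsAsFactors = FALSE)
}

## Add a reaction (internal helper for builders/generators).
add_rxn <- function(model, id, stoich, lb = -1000, ub = 1000, name = id,
                    genes = "", is_exchange = FALSE, is_biomass = FALSE) {
  if (id %in% model$reactions$id) {
    stop("reaction id already present: ", id, call. = FALSE)
  }
  model$reactions <- rbind(model$reactions,
                           data.frame(id = id, name = name, lb = lb, ub = ub,
                                      genes = genes, is_exchange = is_exchange,
                                      is_biomass = is_biomass,
                                      stringsAsFactors = FALSE))
  model$stoich[[id]] <- stoich
  model
}

add_met <- function(model, id, compartment, formula = NA_character_,
                    name = id, charge = NA_integer_) {
  if (id %in% model$metabolites$id) return(model)
  model$metabolites <- rbind(model$metabolites,
                             data.frame(id = id, name = name,
                                        compartment = compartment,
                                        formula = formula, charge = charge,
                                        stringsAsFactors = FALSE))
  model
}

drop_rxn <- function(model, ids) {
  keep <- !(model$reactions$id %in% ids)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$stoich <- model$stoich[model$reactions$id]
  model
}
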