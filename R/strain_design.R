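#' Knockout candidate filter
#'
#' Mirrors the usual strain-design preselection: exclude reactions that are
#' essential, associated to essential genes, extracellular (exchanges and
#' transports touching the extracellular compartment), or carrying no gene
#' association.
#'
#' @param exclude_essential_reactions,exclude_essential_gene_reactions,exclude_extracellular,exclude_geneless
#'   logical switches, all \code{TRUE} by default.
#' @return object of class \code{knockout_filter}.
#' @export
knockout_filter <- function(exclude_essential_reactions = TRUE,
                            exclude_essential_gene_reactions = TRUE,
                            exclude_extracellular = TRUE,
                            exclude_geneless = TRUE) {
  structure(list(exclude_essential_reactions = exclude_essential_reactions,
                 exclude_essential_gene_reactions =
                   exclude_essential_gene_reactions,
                 exclude_extracellular = exclude_extracellular,
                 exclude_geneless = exclude_geneless),
            class = "knockout_filter")
}

fba_max <- function(model, objective) {
  S <- as.matrix(stoichiometric_matrix(model))
  cc <- as.numeric(colnames(S) == objective)
  lp_solve(cc, S, rep(0, nrow(S)), model$reactions$lb, model$reactions$ub,
           sense = "max")
}

knock <- function(model, ids) {
  for (id in ids) model <- set_bounds(model, id, 0, 0)
  model
}

#' Find essential reactions
#'
#' A reaction is essential when deleting it (zero bounds) makes the required
#' growth unattainable: the LP becomes infeasible (fixed-biomass scenario
#' constraints) or the maximal growth drops below \code{grow_tol}.
#'
#' @param model a \code{metabolic_model}.
#' @param constraints optional \code{constraint_set}.
#' @param objective growth reaction id (defaults to the model objective).
#' @param grow_tol minimal growth regarded as viable.
#' @return character vector of essential reaction ids.
#' @export
find_essential_reactions <- function(model, constraints = NULL,
                                     objective = model$objective$reaction,
                                     grow_tol = 1e-6) {
  model <- apply_constraints(model, constraints)
  base <- fba_max(model, objective)
  if (base$status != "optimal") {
    stop("baseline is infeasible; cannot screen essentiality", call. = FALSE)
  }
  ess <- character(0)
  for (rid in setdiff(model$reactions$id, objective)) {
    i <- rxn_row(model, rid)
    if (model$reactions$lb[i] == 0 && model$reactions$ub[i] == 0) next
    sol <- fba_max(knock(model, rid), objective)
    if (sol$status != "optimal" || sol$objective < grow_tol) {
      ess <- c(ess, rid)
    }
  }
  ess
}

## evaluate a boolean gene-association string with a set of deleted genes
eval_gpr <- function(genes, deleted) {
  if (!nzchar(genes)) return(TRUE)
  expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", genes,
                                      ignore.case = TRUE),
               ignore.case = TRUE)
  ids <- unique(regmatches(genes,
                           gregexpr("[A-Za-z][A-Za-z0-9_.-]*", genes))[[1]])
  ids <- setdiff(ids, c("and", "or", "AND", "OR"))
  env <- new.env(parent = baseenv())
  for (g in ids) assign(g, !(g %in% deleted), envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

all_genes <- function(model) {
  ids <- unlist(lapply(model$reactions$genes, function(g) {
    regmatches(g, gregexpr("[A-Za-z][A-Za-z0-9_.-]*", g))[[1]]
  }))
  setdiff(unique(ids), c("and", "or", "AND", "OR"))
}

#' Find essential genes
#'
#' A gene is essential when deleting it — propagated through each reaction's
#' boolean gene association, so isoenzymes (OR) survive single deletions —
#' removes enough reactions to abolish growth.
#'
#' @inheritParams find_essential_reactions
#' @return character vector of essential gene ids.
#' @export
find_essential_genes <- function(model, constraints = NULL,
                                 objective = model$objective$reaction,
                                 grow_tol = 1e-6) {
  model <- apply_constraints(model, constraints)
  ess <- character(0)
  for (g in all_genes(model)) {
    dead <- model$reactions$id[!vapply(model$reactions$genes, eval_gpr,
                                       logical(1), deleted = g)]
    if (!length(dead)) next
    sol <- fba_max(knock(model, dead), objective)
    if (sol$status != "optimal" || sol$objective < grow_tol) ess <- c(ess, g)
  }
  ess
}

#' Build the knockout candidate set
#'
#' @inheritParams find_essential_reactions
#' @param filter a \code{\link{knockout_filter}}.
#' @param species_tag restrict candidates to reactions of one species
#'   compartment (NULL = no restriction).
#' @return character vector of candidate reaction ids.
#' @export
knockout_candidates <- function(model, constraints = NULL,
                                filter = knockout_filter(),
                                objective = model$objective$reaction,
                                species_tag = NULL) {
  mdl <- apply_constraints(model, constraints)
  rxn <- mdl$reactions
  cand <- setdiff(rxn$id, objective)
  comp_of <- stats::setNames(mdl$metabolites$compartment,
                             mdl$metabolites$id)
  ## extracellular = exchange, or a translocation moving the same compound
  ## (same base name) across the membrane; chemical conversions that deposit
  ## a product in the medium stay knockable
  base_of <- function(ids) sub("_[A-Za-z0-9]+$", "", ids)
  extracellular <- vapply(cand, function(r) {
    s <- names(mdl$stoich[[r]])
    in_e <- comp_of[s] == "e"
    if (!any(in_e)) return(FALSE)
    if (all(in_e)) return(TRUE)
    any(base_of(s[in_e]) %in% base_of(s[!in_e]))
  }, logical(1))
  if (filter$exclude_extracellular) cand <- cand[!extracellular]
  if (filter$exclude_geneless) {
    cand <- cand[nzchar(rxn$genes[match(cand, rxn$id)])]
  }
  if (!is.null(species_tag)) {
    suffix <- paste0("_", species_tag)
    cand <- cand[vapply(cand, function(r) {
      all(endsWith(setdiff(names(mdl$stoich[[r]]),
                           mdl$metabolites$id[comp_of == "e"]), suffix)) ||
        all(comp_of[names(mdl$stoich[[r]])] == species_tag)
    }, logical(1))]
  }
  if (filter$exclude_essential_reactions) {
    cand <- setdiff(cand, find_essential_reactions(model, constraints,
                                                   objective))
  }
  if (filter$exclude_essential_gene_reactions) {
    eg <- find_essential_genes(model, constraints, objective)
    if (length(eg)) {
      uses_eg <- vapply(cand, function(r) {
        g <- rxn$genes[match(r, rxn$id)]
        any(eg %in% regmatches(g, gregexpr("[A-Za-z][A-Za-z0-9_.-]*",
                                           g))[[1]])
      }, logical(1))
      cand <- cand[!uses_eg]
    }
  }
  cand
}

## inner bi-level evaluation of one knockout set:
## growth is maximised first; the target is then maximised (optimistic) and
## minimised (guaranteed) over the growth-optimal face.
evaluate_design <- function(model, knocked, target, objective,
                            grow_tol = 1e-6) {
  mdl <- knock(model, knocked)
  g <- fba_max(mdl, objective)
  if (g$status != "optimal" || g$objective < grow_tol) return(NULL)
  S <- as.matrix(stoichiometric_matrix(mdl))
  lb <- mdl$reactions$lb; ub <- mdl$reactions$ub
  i <- match(objective, colnames(S))
  lb[i] <- ub[i] <- g$objective
  cc <- as.numeric(colnames(S) == target)
  hi <- lp_solve(cc, S, rep(0, nrow(S)), lb, ub, sense = "max")
  lo <- lp_solve(cc, S, rep(0, nrow(S)), lb, ub, sense = "min")
  if (hi$status != "optimal" || lo$status != "optimal") return(NULL)
  ## duality audit on the inner growth LP
  dual_gap <- abs((sum(g$reduced_costs * g$x)) - g$objective)
  list(growth = g$objective, optimistic = hi$objective,
       guaranteed = lo$objective, dual_gap = dual_gap)
}

## optimistic pruning bound: max target with this partial knockout set,
## ignoring growth optimality (valid upper bound for all supersets)
design_bound <- function(model, knocked, target) {
  sol <- fba_max(knock(model, knocked), target)
  if (sol$status != "optimal") -Inf else sol$objective
}

run_knockout_search <- function(model, constraints, target, max_knockouts,
                                filter, objective, species_tag,
                                value_kind = c("optimistic", "guaranteed"),
                                grow_tol = 1e-6) {
  value_kind <- match.arg(value_kind)
  mdl <- apply_constraints(model, constraints)
  if (!target %in% mdl$reactions$id) {
    stop("unknown target reaction: ", target, call. = FALSE)
  }
  cand <- knockout_candidates(model, constraints, filter, objective,
                              species_tag)
  wt <- evaluate_design(mdl, character(0), target, objective, grow_tol)
  if (is.null(wt)) stop("wild type cannot grow under these constraints",
                        call. = FALSE)
  wt_value <- wt[[value_kind]]
  best <- list(value = wt_value, sets = list(character(0)), evals = list(wt))
  if (max_knockouts == 0 || !length(cand)) {
    return(list(best = best, wild_type = wt, candidates = cand,
                explored = 0L))
  }
  explored <- 0L
  ## depth-first search over candidate subsets with optimistic LP pruning
  recurse <- function(start, knocked) {
    for (ci in start:length(cand)) {
      ks <- c(knocked, cand[ci])
      bound <- design_bound(mdl, ks, target)
      explored <<- explored + 1L
      if (bound < best$value - 1e-9) next   # no superset can beat incumbent
      ev <- evaluate_design(mdl, ks, target, objective, grow_tol)
      if (!is.null(ev)) {
        v <- ev[[value_kind]]
        if (v > best$value + 1e-9) {
          best <<- list(value = v, sets = list(ks), evals = list(ev))
        } else if (abs(v - best$value) <= 1e-9) {
          best$sets[[length(best$sets) + 1]] <<- ks
          best$evals[[length(best$evals) + 1]] <<- ev
        }
      }
      if (length(ks) < max_knockouts && ci < length(cand)) {
        recurse(ci + 1L, ks)
      }
    }
  }
  recurse(1L, character(0))
  list(best = best, wild_type = wt, candidates = cand, explored = explored)
}

finish_designs <- function(search, target, algorithm, wt_value) {
  best <- search$best
  ## tie-break: fewest knockouts, then lexicographic ids
  ord <- order(vapply(best$sets, length, integer(1)),
               vapply(best$sets, function(s) paste(sort(s), collapse = ","),
                      character(1)))
  sets <- best$sets[ord]; evals <- best$evals[ord]
  keep <- !duplicated(vapply(sets, function(s) {
    paste(sort(s), collapse = ",")
  }, character(1)))
  sets <- sets[keep]; evals <- evals[keep]
  out <- lapply(seq_along(sets), function(i) {
    structure(list(knocked_reactions = sort(sets[[i]]),
                   guaranteed_target_flux = evals[[i]]$guaranteed,
                   optimistic_target_flux = evals[[i]]$optimistic,
                   wild_type_flux = wt_value,
                   growth = evals[[i]]$growth,
                   dual_gap = evals[[i]]$dual_gap,
                   algorithm = algorithm, target = target),
              class = "design_result")
  })
  attr(out, "explored") <- search$explored
  attr(out, "candidates") <- search$candidates
  out
}

#' OptKnock-style knockout design
#'
#' Searches knockout sets (up to \code{max_knockouts} reactions from the
#' filtered candidate set) maximising the target flux attainable while the
#' cell grows optimally: the inner level maximises growth, the outer level
#' picks the growth-optimal solution with the highest target flux. The
#' bi-level program is solved exactly by implicit branch-and-bound over
#' candidate subsets with an LP-based optimistic pruning bound; for every
#' returned design the inner LP's primal/dual agreement is reported as
#' \code{dual_gap}.
#'
#' @param model a \code{metabolic_model}.
#' @param constraints optional \code{constraint_set}.
#' @param target target exchange reaction id.
#' @param max_knockouts maximal knockout set size (default 1).
#' @param filter a \code{\link{knockout_filter}}.
#' @param objective inner (growth) objective reaction.
#' @param species_tag restrict candidates to one species (community models).
#' @return list of \code{design_result} objects (best designs, ties broken
#'   by fewest knockouts then lexicographic ids). The wild type is included
#'   when no knockout improves on it.
#' @export
optknock <- function(model, constraints = NULL, target, max_knockouts = 1,
                     filter = knockout_filter(),
                     objective = model$objective$reaction,
                     species_tag = NULL) {
  search <- run_knockout_search(model, constraints, target, max_knockouts,
                                filter, objective, species_tag, "optimistic")
  finish_designs(search, target, "optknock", search$wild_type$optimistic)
}

#' RobustKnock-style knockout design
#'
#' As \code{\link{optknock}}, but the outer level maximises the
#' \emph{minimum} target flux over all growth-optimal solutions (max-min),
#' guaranteeing a production floor even under adversarial alternative
#' optima. \code{guaranteed_target_flux} of each design equals that inner
#' minimum; \code{guaranteed <= optimistic} always holds.
#'
#' @inheritParams optknock
#' @return list of \code{design_result} objects.
#' @export
robustknock <- function(model, constraints = NULL, target,
                        max_knockouts = 1, filter = knockout_filter(),
                        objective = model$objective$reaction,
                        species_tag = NULL) {
  search <- run_knockout_search(model, constraints, target, max_knockouts,
                                filter, objective, species_tag, "guaranteed")
  finish_designs(search, target, "robustknock", search$wild_type$guaranteed)
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result>", x$algorithm, "target", x$target, "\n")
  cat("  knockouts: ", if (length(x$knocked_reactions)) {
    paste(x$knocked_reactions, collapse = ", ")
  } else "(none)", "\n")
  cat(sprintf("  guaranteed %.6g / optimistic %.6g (wild type %.6g)\n",
              x$guaranteed_target_flux, x$optimistic_target_flux,
              x$wild_type_flux))
  invisible(x)
}

#' Evaluate a mutant under scenario constraints
#'
#' Deletes the given reactions, samples the mutant flux space and compares
#' per-reaction means against a wild-type sample drawn with the same seed.
#' An infeasible mutant is reported as a result (status
#' \code{"infeasible"}), not as an error.
#'
#' @inheritParams solve_fba
#' @param knocked character vector of reaction ids to delete.
#' @param n_samples,seed sampling parameters (see
#'   \code{\link{sample_fluxes}}).
#' @param report_reactions reactions to report fold-changes for (default:
#'   exchange reactions).
#' @return list with \code{status}, \code{mutant} and \code{wild_type}
#'   \code{flux_sample}s, and \code{comparison} (data.frame reaction,
#'   wild-type mean/sd, mutant mean/sd, percent change).
#' @export
evaluate_mutant <- function(model, constraints = NULL, knocked,
                            n_samples = 1000, seed = 0,
                            report_reactions = NULL) {
  if (length(knocked)) rxn_row(model, knocked)   # errors on unknown ids
  mdl <- apply_constraints(model, constraints)
  mut <- knock(mdl, knocked)
  probe <- if (length(knocked)) knocked[1] else mut$reactions$id[1]
  feas <- tryCatch(flux_variability(mut, reactions = probe),
                   cofba_infeasible = function(e) NULL)
  if (is.null(feas)) {
    return(list(status = "infeasible", knocked = knocked,
                mutant = NULL, wild_type = NULL, comparison = NULL))
  }
  wt_s <- sample_fluxes(mdl, n = n_samples, seed = seed)
  mu_s <- sample_fluxes(mut, n = n_samples, seed = seed)
  if (is.null(report_reactions)) {
    report_reactions <- mdl$reactions$id[mdl$reactions$is_exchange]
  }
  cmp <- data.frame(
    reaction = report_reactions,
    wt_mean = wt_s$mean[report_reactions],
    wt_sd = wt_s$sd[report_reactions],
    mut_mean = mu_s$mean[report_reactions],
    mut_sd = mu_s$sd[report_reactions],
    row.names = NULL, stringsAsFactors = FALSE)
  cmp$pct_change <- ifelse(abs(cmp$wt_mean) > 1e-9,
                           100 * (cmp$mut_mean - cmp$wt_mean) /
                             abs(cmp$wt_mean), NA_real_)
  list(status = "optimal", knocked = knocked, mutant = mu_s,
       wild_type = wt_s, comparison = cmp)
}
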