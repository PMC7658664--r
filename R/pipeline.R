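#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param n_samples flux-sampling iterations per scenario.
#' @param thin sampler thinning.
#' @param grid a \code{\link{scenario_grid_spec}} (defaults to the standard
#'   validation grid).
#' @param knockout_target target exchange for strain design.
#' @param max_knockouts knockout budget.
#' @param product_floor measured-product floor fraction.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed = 1L, n_samples = 1000, thin = 10,
                       grid = NULL, knockout_target = "EX_etoh_e",
                       max_knockouts = 2, product_floor = 0.8) {
  stopifnot(n_samples >= 1)
  if (is.null(grid)) grid <- scenario_grid_spec(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_samples = n_samples, thin = thin, grid = grid,
                 knockout_target = knockout_target,
                 max_knockouts = max_knockouts,
                 product_floor = product_floor),
            class = "run_config")
}

#' Run the complete analysis pipeline
#'
#' Stages: generate the toy models, merge them into the community model,
#' build per-scenario chemostat constraints, solve/FVA/sample each scenario,
#' run the knockout design on the acetogen, and compute electron yields.
#' Per-scenario tables are written as TSV, a machine-readable summary as
#' JSON (free of timestamps, so identical configurations produce identical
#' summaries), and a log with versions, seeds and timings. A failing stage
#' is recorded and dependent stages are skipped; infeasible scenarios are
#' diagnosed, not fatal.
#'
#' @param config a \code{\link{run_config}}.
#' @return the summary list, invisibly; side effect: files under
#'   \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  t0 <- Sys.time()
  logline <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), ..., "\n", file = logf,
        append = TRUE)
  }
  cat("cofba pipeline log\nR", R.version.string, "\nseed", config$seed,
      "\n", file = logf)
  summary <- list(seed = config$seed, stages = list(), scenarios = list())
  fail <- NULL
  stage <- function(name, fun) {
    if (!is.null(fail)) {
      summary$stages[[name]] <<- "skipped"
      return(NULL)
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      logline("stage", name, "FAILED:", conditionMessage(res))
      summary$stages[[name]] <<- paste("failed:", conditionMessage(res))
      fail <<- name
      NULL
    } else {
      logline("stage", name, "ok")
      summary$stages[[name]] <<- "ok"
      res
    }
  }

  community <- stage("build", function() {
    make_toy_community(seed = config$seed)
  })
  scenarios <- stage("scenarios", function() {
    make_scenarios(config$grid, model = community)
  })

  if (!is.null(scenarios)) {
    for (i in seq_along(scenarios)) {
      sc <- scenarios[[i]]
      tag <- sprintf("scenario_%02d", i)
      entry <- list(feeds = as.list(sc$feeds),
                    phi = as.list(sc$abundance$fractions))
      if (isTRUE(attr(sc, "infeasible"))) {
        diag <- diagnose_infeasibility(
          community, build_constraints(community, sc, config$product_floor))
        entry$status <- "infeasible"
        entry$total_slack <- attr(diag, "total_slack")
        utils::write.table(diag[diag$slack > 0, ],
                           file.path(config$out_dir,
                                     paste0(tag, "_diagnosis.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      } else {
        cs <- build_constraints(community, sc, config$product_floor)
        smp <- sample_fluxes(community, cs, n = config$n_samples,
                             seed = config$seed + i, thin = config$thin)
        tab <- data.frame(reaction = names(smp$mean), mean = smp$mean,
                          sd = smp$sd, lb = smp$fva$min, ub = smp$fva$max,
                          row.names = NULL)
        utils::write.table(tab, file.path(config$out_dir,
                                          paste0(tag, "_fluxes.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        hexa <- unname(smp$mean["EX_hexa_e"])
        entry$status <- "ok"
        entry$mean_hexanoate <- hexa
        entry$electron_yield_hexa <- electron_yield(
          sc$feeds[sc$feeds > 0], "hexa", max(hexa, 0))
        entry$carbon_yield_hexa <- carbon_normalized_yield(
          max(hexa, 0), sc$feeds[names(sc$feeds) %in%
                                   names(carbon_ledger()$carbons_per_mol)])
      }
      summary$scenarios[[tag]] <- entry
      logline(tag, entry$status)
    }
  }

  designs <- stage("knockout", function() {
    ## ethanol-forcing demo condition: fixed CO feed, chemostat-like biomass
    ## and maintenance, saturating acetate export; the electron-overflow
    ## valves (formate, succinate) are then the knockout levers
    acetogen <- make_toy_acetogen(toy_network_spec(
      "acetogen", include_formate_branch = TRUE, seed = config$seed))
    acetogen <- set_bounds(acetogen, "EX_co_e", -10, -10)
    acetogen <- set_bounds(acetogen, "EX_h2_e", 0, 0)
    for (r in c("EX_ac_e", "EX_etoh_e", "EX_succ_e", "EX_form_e")) {
      acetogen <- set_bounds(acetogen, r, 0, 1000)
    }
    acetogen <- set_bounds(acetogen, "BIOMASS", 0, 0.1)
    acetogen <- set_bounds(acetogen, "ATPM", 0.5, 1000)
    acetogen <- set_bounds(acetogen, "TR_ac", 0, 1.5)
    robustknock(acetogen, target = config$knockout_target,
                max_knockouts = config$max_knockouts)
  })
  if (!is.null(designs)) {
    dtab <- do.call(rbind, lapply(designs, function(d) {
      data.frame(knockouts = paste(d$knocked_reactions, collapse = ","),
                 guaranteed = d$guaranteed_target_flux,
                 optimistic = d$optimistic_target_flux,
                 wild_type = d$wild_type_flux, stringsAsFactors = FALSE)
    }))
    utils::write.table(dtab, file.path(config$out_dir, "designs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$designs <- lapply(designs, function(d) {
      list(knockouts = d$knocked_reactions,
           optimistic = d$optimistic_target_flux,
           guaranteed = d$guaranteed_target_flux,
           wild_type = d$wild_type_flux)
    })
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  logline("total", format(difftime(Sys.time(), t0, units = "secs")))
  invisible(summary)
}
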