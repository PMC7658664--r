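#' Flux balance analysis on a (community) model
#'
#' Solves the steady-state LP \code{S v = 0}, \code{lb <= v <= ub},
#' optimising the flux of one reaction. With \code{parsimonious = TRUE} a
#' second LP fixes the objective at its optimum and minimises the total
#' absolute flux, giving a deterministic representative solution.
#'
#' @param model a \code{metabolic_model}.
#' @param constraints optional \code{constraint_set} applied before solving.
#' @param objective reaction id (defaults to the model objective).
#' @param sense \code{"max"} or \code{"min"}.
#' @param parsimonious apply the minimal-total-flux tie-break.
#' @return object of class \code{flux_solution}: list with \code{fluxes}
#'   (named vector), \code{objective_value}, \code{status}, \code{duals}.
#'   At an optimum the steady-state residual is asserted to be below 1e-6.
#' @export
solve_fba <- function(model, constraints = NULL,
                      objective = model$objective$reaction,
                      sense = model$objective$direction,
                      parsimonious = FALSE) {
  model <- apply_constraints(model, constraints)
  if (is.na(objective) || !objective %in% model$reactions$id) {
    stop("objective reaction not found: ", objective, call. = FALSE)
  }
  S <- as.matrix(stoichiometric_matrix(model))
  n <- ncol(S)
  cc <- as.numeric(colnames(S) == objective)
  res <- lp_solve(cc, S, rep(0, nrow(S)), model$reactions$lb,
                  model$reactions$ub, sense = sense)
  if (res$status != "optimal") {
    return(structure(list(fluxes = NULL, objective_value = NA_real_,
                          status = res$status, duals = NULL),
                     class = "flux_solution"))
  }
  x <- res$x
  if (parsimonious) {
    ## min sum |v| subject to the objective staying at its optimum:
    ## variables [v, p, q] with v = p - q, p,q >= 0
    lb <- model$reactions$lb; ub <- model$reactions$ub
    i <- which(colnames(S) == objective)
    lb[i] <- ub[i] <- res$objective
    A2 <- rbind(cbind(S, matrix(0, nrow(S), 2 * n)),
                cbind(diag(n), -diag(n), diag(n)))
    c2 <- c(rep(0, n), rep(1, 2 * n))
    r2 <- lp_solve(c2, A2, rep(0, nrow(S) + n),
                   c(lb, rep(0, 2 * n)),
                   c(ub, rep(1e4, 2 * n)), sense = "min")
    if (r2$status == "optimal") x <- r2$x[seq_len(n)]
  }
  resid <- max(abs(S %*% x))
  if (resid > 1e-6) {
    stop("steady-state residual above tolerance: ", format(resid),
         call. = FALSE)
  }
  structure(list(fluxes = stats::setNames(x, colnames(S)),
                 objective_value = res$objective, status = "optimal",
                 duals = stats::setNames(res$duals, rownames(S))),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution>", x$status)
  if (x$status == "optimal") cat(", objective", format(x$objective_value))
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the constraints and,
#' optionally, to the model objective staying within a fraction of its
#' optimum.
#'
#' @inheritParams solve_fba
#' @param fraction_of_optimum if non-NULL and the model has an objective,
#'   require objective >= fraction * optimum before scanning.
#' @param reactions reaction ids to scan (default all).
#' @return data.frame \code{reaction}, \code{min}, \code{max}; vertex
#'   solutions encountered during the scan are attached as
#'   \code{attr(, "vertices")} (reactions x solutions matrix) for sampler
#'   warm-up. Infeasible constraint sets raise a condition of class
#'   \code{cofba_infeasible}.
#' @export
flux_variability <- function(model, constraints = NULL,
                             fraction_of_optimum = NULL,
                             reactions = NULL) {
  model <- apply_constraints(model, constraints)
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- model$reactions$lb; ub <- model$reactions$ub
  rids <- colnames(S)
  if (!is.null(fraction_of_optimum) && !is.na(model$objective$reaction)) {
    i <- match(model$objective$reaction, rids)
    cc <- as.numeric(seq_along(rids) == i)
    base <- lp_solve(cc, S, rep(0, nrow(S)), lb, ub,
                     sense = model$objective$direction)
    if (base$status != "optimal") {
      stop(structure(class = c("cofba_infeasible", "error", "condition"),
                     list(message = paste("FVA baseline:", base$status),
                          call = NULL)))
    }
    if (model$objective$direction == "max") {
      lb[i] <- max(lb[i], fraction_of_optimum * base$objective)
    } else {
      ub[i] <- min(ub[i], fraction_of_optimum * base$objective)
    }
  }
  scan <- if (is.null(reactions)) rids else reactions
  res <- matrix(NA_real_, length(scan), 2,
                dimnames = list(scan, c("min", "max")))
  verts <- list()
  for (r in scan) {
    cc <- as.numeric(rids == r)
    for (s in c("min", "max")) {
      sol <- lp_solve(cc, S, rep(0, nrow(S)), lb, ub, sense = s)
      if (sol$status != "optimal") {
        stop(structure(class = c("cofba_infeasible", "error", "condition"),
                       list(message = paste("FVA:", sol$status, "for", r),
                            call = NULL)))
      }
      res[r, s] <- sol$objective
      verts[[length(verts) + 1]] <- sol$x
    }
  }
  out <- data.frame(reaction = scan, min = res[, "min"], max = res[, "max"],
                    row.names = NULL, stringsAsFactors = FALSE)
  V <- do.call(cbind, verts)
  rownames(V) <- rids
  attr(out, "vertices") <- V
  out
}

#' Sample the steady-state flux space
#'
#' Artificial-centering hit-and-run sampling of the flux polytope
#' \code{\{v : S v = 0, lb <= v <= ub\}}. Warm-up points are the vertex
#' solutions of a preparatory flux variability analysis; chord directions are
#' differences between randomly chosen stored points and the running center,
#' which keeps every iterate in the steady-state null space. Results are
#' reproducible for a fixed seed.
#'
#' @inheritParams solve_fba
#' @param n number of retained samples (default 15000).
#' @param seed integer seed (required).
#' @param thin hit-and-run steps between retained samples. The default of 10
#'   keeps the default run inside a interactive-scale time budget; increase
#'   for better mixing on larger networks.
#' @return object of class \code{flux_sample}: list with \code{mean},
#'   \code{sd} (named per reaction), \code{n_samples}, \code{seed},
#'   \code{fva} (the warm-up FVA table), and \code{samples} (n x reactions
#'   matrix).
#' @export
sample_fluxes <- function(model, constraints = NULL, n = 15000, seed,
                          thin = 10) {
  stopifnot(n > 0)
  if (missing(seed)) stop("seed is required for sampling", call. = FALSE)
  model <- apply_constraints(model, constraints)
  fva <- flux_variability(model)
  V <- attr(fva, "vertices")
  rids <- rownames(V)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  if (any(!is.finite(fva$min)) || any(!is.finite(fva$max))) {
    stop("unbounded directions remain; tighten bounds before sampling",
         call. = FALSE)
  }
  set.seed(seed)
  nv <- ncol(V)
  center <- rowMeans(V)
  x <- center
  ## orthonormal basis of the stoichiometric row space: used to re-project
  ## iterates onto {S v = 0} and stop numerical drift from accumulating
  S <- as.matrix(stoichiometric_matrix(model))
  qs <- qr(t(S))
  Q <- qr.Q(qs)[, seq_len(qs$rank), drop = FALSE]
  samples <- matrix(NA_real_, n, length(rids),
                    dimnames = list(NULL, rids))
  stored_sum <- rowSums(V); stored_n <- nv
  eps <- 1e-12
  for (k in seq_len(n)) {
    for (s in seq_len(thin)) {
      repeat {
        pick <- sample.int(stored_n, 1)
        p <- if (pick <= nv) V[, pick] else samples[pick - nv, ]
        d <- p - center
        nd <- sqrt(sum(d * d))
        if (nd > eps) break
      }
      d <- d / nd
      act <- abs(d) > 1e-11
      ## 1e-9 slack: coordinates pinned at a bound up to LP tolerance carry
      ## tiny noise components in chord directions and must not freeze the
      ## walk (bound violations stay below the 1e-6 sample invariant)
      up <- ub[act] - x[act] + 1e-9
      lo <- lb[act] - x[act] - 1e-9
      tpos <- suppressWarnings(min(pmax(up / d[act], lo / d[act])))
      tneg <- suppressWarnings(max(pmin(up / d[act], lo / d[act])))
      if (!is.finite(tpos) || !is.finite(tneg) || tpos < tneg) next
      t <- stats::runif(1, tneg, tpos)
      x <- x + t * d
    }
    x <- x - as.numeric(Q %*% crossprod(Q, x))
    viol <- pmax(x - ub, lb - x)
    if (any(viol > 1e-6)) {
      ## projection pushed clearly past a bound (rare): shrink toward the
      ## center (itself in the null space) just enough to restore the box
      w <- which(viol > 1e-6)
      lam <- min(1, abs((ifelse(x[w] > ub[w], ub[w], lb[w]) - center[w]) /
                          (x[w] - center[w])))
      x <- center + 0.999999 * lam * (x - center)
    }
    samples[k, ] <- x
    stored_sum <- stored_sum + x
    stored_n <- stored_n + 1L
    center <- stored_sum / stored_n
  }
  structure(list(mean = colMeans(samples),
                 sd = apply(samples, 2, stats::sd),
                 n_samples = n, seed = seed, fva = fva, samples = samples),
            class = "flux_sample")
}

#' @export
print.flux_sample <- function(x, ...) {
  cat("<flux_sample>", x$n_samples, "samples, seed", x$seed, "\n")
  invisible(x)
}

#' Diagnose an infeasible constraint set
#'
#' Solves an elastic-relaxation LP: every reaction bound may be violated by a
#' non-negative slack, and the total slack is minimised. The nonzero slacks
#' identify the (minimal total) set of constraints that must be relaxed to
#' restore feasibility — typically maintenance or biomass requirements in
#' over-constrained chemostat scenarios. Called on a feasible set it returns
#' an all-zero report.
#'
#' @inheritParams solve_fba
#' @return data.frame \code{reaction}, \code{lb}, \code{ub}, \code{flux},
#'   \code{slack} with \code{attr(, "total_slack")} and
#'   \code{attr(, "feasible")}.
#' @export
diagnose_infeasibility <- function(model, constraints = NULL) {
  model <- apply_constraints(model, constraints)
  S <- as.matrix(stoichiometric_matrix(model))
  n <- ncol(S); m <- nrow(S)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  box <- max(1e4, 10 * max(abs(c(lb, ub))))
  ## variables [v, w, sp, sm]: S v = 0; v - w - sp + sm = 0; w in [lb,ub]
  A <- rbind(cbind(S, matrix(0, m, 3 * n)),
             cbind(diag(n), -diag(n), -diag(n), diag(n)))
  cc <- c(rep(0, 2 * n), rep(1, 2 * n))
  res <- lp_solve(cc, A, rep(0, m + n),
                  c(rep(-box, n), lb, rep(0, 2 * n)),
                  c(rep(box, n), ub, rep(box, 2 * n)), sense = "min")
  if (res$status != "optimal") {
    stop("elastic relaxation LP failed: ", res$status, call. = FALSE)
  }
  v <- res$x[seq_len(n)]
  slack <- res$x[n + n + seq_len(n)] + res$x[3 * n + seq_len(n)]
  slack[slack < 1e-9] <- 0
  out <- data.frame(reaction = colnames(S), lb = lb, ub = ub, flux = v,
                    slack = slack, stringsAsFactors = FALSE)
  attr(out, "total_slack") <- sum(slack)
  attr(out, "feasible") <- sum(slack) < 1e-7
  out
}
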