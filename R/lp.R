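#' Solve a bounded-variable linear program
#'
#' Solves \code{optimize c'x subject to A x = b, lb <= x <= ub} with a two-phase
#' primal simplex method specialised for bounded variables. This is the LP
#' engine behind all flux balance computations in the package; it is written in
#' plain R because the problems it faces (toy metabolic networks with at most a
#' few hundred reactions) are tiny by LP standards, and no LP backend is
#' assumed to be installed.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix (dense or \pkg{Matrix} sparse), m x n. Equality
#'   constraints only; inequalities must be rewritten with slack variables or
#'   variable bounds by the caller.
#' @param rhs right-hand side, length m.
#' @param lb,ub variable bounds, length n. May contain \code{-Inf}/\code{Inf}.
#' @param sense \code{"max"} or \code{"min"}.
#' @param tol feasibility/optimality tolerance.
#'
#' @return A list with elements \code{status} (\code{"optimal"},
#'   \code{"infeasible"} or \code{"unbounded"}), \code{x} (primal solution),
#'   \code{objective}, \code{duals} (row duals y with \code{A' y + d = c}),
#'   and \code{reduced_costs} (d). At an optimum the dual objective
#'   \code{b'y + sum(d_j x_j)} equals the primal objective (strong duality);
#'   this identity is used by the strain-design duality audit.
#' @export
lp_solve <- function(obj, A, rhs, lb, ub, sense = c("max", "min"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, duals = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n)))
  }
  cost <- if (sense == "max") -as.numeric(obj) else as.numeric(obj)

  ## Replace infinite bounds by a large finite box: all flux problems in this
  ## package are intrinsically bounded by exchange limits, so this is safe.
  big <- max(1e4, 100 * max(1, abs(rhs), abs(lb[is.finite(lb)]),
                            abs(ub[is.finite(ub)])))
  lbf <- ifelse(is.finite(lb), lb, -big)
  ubf <- ifelse(is.finite(ub), ub, big)

  res <- simplex_bounded(cost, A, as.numeric(rhs), lbf, ubf, tol)

  if (res$status == "optimal") {
    ## A solution pinned at an artificial box bound means the true LP is
    ## unbounded in that direction (only possible if the user bound was Inf).
    at_fake <- (!is.finite(lb) & res$x < -big + 1e-6) |
      (!is.finite(ub) & res$x > big - 1e-6)
    if (any(at_fake)) res$status <- "unbounded"
  }
  obj_val <- if (res$status == "optimal") sum(obj * res$x) else NA_real_
  duals <- res$y
  redc <- res$d
  if (sense == "max" && res$status == "optimal") {
    duals <- -duals
    redc <- -redc
  }
  list(status = res$status, x = res$x, objective = obj_val,
       duals = duals, reduced_costs = redc)
}

## Two-phase bounded-variable primal simplex (minimisation).
## Returns list(status, x, y, d). Internal.
simplex_bounded <- function(cost, A, b, lb, ub, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)

  ## Initial nonbasic point: every structural variable at the bound nearer 0.
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_upper <- abs(lb) > abs(ub)          # logical per structural variable

  r <- b - as.numeric(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))         # artificial columns
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  xe <- c(x, abs(r))
  at_up_e <- c(at_upper, rep(FALSE, m))
  basis <- (n + 1):(n + m)

  run_phase <- function(cvec, basis, xe, at_up_e, lbe, ube, allow) {
    iter <- 0L
    max_iter <- 20000L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex: iteration limit reached")
      bland <- iter > 4000L
      B <- Aext[, basis, drop = FALSE]
      fac <- tryCatch(lu_factor(B), error = function(e) NULL)
      if (is.null(fac)) stop("simplex: singular basis")
      xB <- fac$solve(b - as.numeric(Aext[, -basis, drop = FALSE] %*%
                                       xe[-basis]))
      xe[basis] <- xB
      y <- fac$tsolve(cvec[basis])
      d <- cvec - as.numeric(crossprod(Aext, y))
      d[basis] <- 0

      cand <- setdiff(which(allow), basis)
      viol <- numeric(0)
      if (length(cand)) {
        dn <- d[cand]
        up <- at_up_e[cand]
        can_inc <- !up & (dn < -tol) & (ube[cand] > lbe[cand] + tol)
        can_dec <- up & (dn > tol) & (ube[cand] > lbe[cand] + tol)
        sel <- can_inc | can_dec
        cand <- cand[sel]
        viol <- abs(dn[sel])
      }
      if (!length(cand)) {
        return(list(basis = basis, xe = xe, at_up_e = at_up_e, y = y, d = d,
                    obj = sum(cvec * xe)))
      }
      e <- if (bland) min(cand) else cand[which.max(viol)]
      dir <- if (at_up_e[e]) -1 else 1     # entering variable moves by dir * t

      w <- fac$solve(Aext[, e])            # B^{-1} A_e
      ## Basic variable change: xB_new = xB - t * dir * w.
      tmax <- ube[e] - lbe[e]              # bound flip limit
      leave <- 0L; leave_to_upper <- FALSE
      for (k in seq_len(m)) {
        wk <- dir * w[k]
        if (wk > tol) {                    # basic var decreases toward lb
          tk <- max(0, (xe[basis[k]] - lbe[basis[k]]) / wk)
          if (tk < tmax - 1e-12 ||
              (tk < tmax + 1e-12 && leave > 0L && bland &&
               basis[k] < basis[leave])) {
            tmax <- min(tmax, tk); leave <- k; leave_to_upper <- FALSE
          }
        } else if (wk < -tol) {            # basic var increases toward ub
          if (is.finite(ube[basis[k]])) {
            tk <- max(0, (ube[basis[k]] - xe[basis[k]]) / (-wk))
            if (tk < tmax - 1e-12 ||
                (tk < tmax + 1e-12 && leave > 0L && bland &&
                 basis[k] < basis[leave])) {
              tmax <- min(tmax, tk); leave <- k; leave_to_upper <- TRUE
            }
          }
        }
      }
      if (!is.finite(tmax)) return(list(unbounded = TRUE))
      tmax <- max(tmax, 0)
      xe[e] <- xe[e] + dir * tmax
      xe[basis] <- xe[basis] - tmax * dir * w
      if (leave == 0L) {                   # bound flip, basis unchanged
        at_up_e[e] <- !at_up_e[e]
      } else {
        lv <- basis[leave]
        at_up_e[lv] <- leave_to_upper
        xe[lv] <- if (leave_to_upper) ube[lv] else lbe[lv]
        basis[leave] <- e
      }
    }
  }

  ## Phase 1: minimise the sum of artificials.
  c1 <- c(rep(0, n), rep(1, m))
  allow1 <- rep(TRUE, n + m)
  p1 <- run_phase(c1, basis, xe, at_up_e, lbe, ube, allow1)
  if (isTRUE(p1$unbounded)) stop("simplex: phase 1 unbounded (internal error)")
  if (p1$obj > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                y = rep(NA_real_, m), d = rep(NA_real_, n)))
  }

  ## Phase 2: pin artificials to zero, optimise the true cost.
  ube2 <- c(ub, rep(0, m))
  lbe2 <- c(lb, rep(0, m))
  xe2 <- p1$xe
  xe2[(n + 1):(n + m)] <- 0
  c2 <- c(cost, rep(0, m))
  allow2 <- c(rep(TRUE, n), rep(FALSE, m))
  p2 <- run_phase(c2, p1$basis, xe2, p1$at_up_e, lbe2, ube2, allow2)
  if (isTRUE(p2$unbounded)) {
    return(list(status = "unbounded", x = rep(NA_real_, n),
                y = rep(NA_real_, m), d = rep(NA_real_, n)))
  }
  list(status = "optimal", x = p2$xe[seq_len(n)], y = p2$y,
       d = p2$d[seq_len(n)])
}

## Small dense LU helper: returns solve / transpose-solve closures.
lu_factor <- function(B) {
  qrB <- qr(B, LAPACK = TRUE)
  if (qrB$rank < ncol(B) && !is.null(qrB$rank)) {
    ## LAPACK qr does not expose rank reliably; singularity surfaces in solve.
  }
  tB <- t(B)
  qrT <- qr(tB, LAPACK = TRUE)
  list(
    solve = function(v) qr.coef(qrB, v),
    tsolve = function(v) qr.coef(qrT, v)
  )
}

#' Enumerate the vertices of a flux polytope (oracle)
#'
#' Exhaustively enumerates basic feasible solutions of
#' \code{\{x : A x = b, lb <= x <= ub\}} by trying every choice of
#' \code{n - rank(A)} variables pinned at a lower or upper bound and solving
#' for the rest. Exponential in n; intended purely as an independent test
#' oracle for \code{\link{lp_solve}} on networks with at most ~12 reactions.
#'
#' @inheritParams lp_solve
#' @return matrix with one vertex per row (possibly with duplicates removed).
#' @export
enumerate_vertices <- function(A, rhs, lb, ub, tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  qa <- qr(A)
  r <- qa$rank
  keep_rows <- sort(qa$pivot[seq_len(r)])
  ## Use a row-reduced full-rank system equivalent on the affine hull.
  qt <- qr(t(A))
  rows <- sort(qt$pivot[seq_len(qt$rank)])
  Ar <- A[rows, , drop = FALSE]
  br <- rhs[rows]
  r <- nrow(Ar)
  free_count <- n - r
  stopifnot(free_count >= 0)
  verts <- list()
  combos <- utils::combn(n, free_count)
  for (ci in seq_len(ncol(combos))) {
    nb <- combos[, ci]
    bas <- setdiff(seq_len(n), nb)
    Bm <- Ar[, bas, drop = FALSE]
    if (abs(det(Bm)) < 1e-12) next
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(nb))))
    if (!length(nb)) grid <- matrix(FALSE, 1, 0)
    for (gi in seq_len(nrow(grid))) {
      xv <- numeric(n)
      xv[nb] <- ifelse(grid[gi, ], ub[nb], lb[nb])
      if (any(!is.finite(xv[nb]))) next
      xv[bas] <- solve(Bm, br - Ar[, nb, drop = FALSE] %*% xv[nb])
      if (all(xv >= lb - tol) && all(xv <= ub + tol) &&
          max(abs(A %*% xv - rhs)) < tol) {
        verts[[length(verts) + 1L]] <- xv
      }
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 6)), , drop = FALSE]
}
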