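#' Solve a bounded linear program
#'
#' Solves max/min `obj' x` subject to `Aeq x = beq`, `Aineq x <= bineq` and
#' `lb <= x <= ub` with a two-phase bounded-variable revised simplex using
#' Bland's rule (finite, no cycling). Flux balance problems are small but
#' highly degenerate, so robustness against cycling matters more than pivot
#' heuristics here.
#'
#' @param obj numeric objective coefficients.
#' @param Aeq,beq equality constraints (matrix may be a `Matrix` sparse class).
#' @param lb,ub finite variable bounds (flux bounds in constraint-based models
#'   are conventionally capped at +-1000).
#' @param Aineq,bineq optional extra inequality constraints `Aineq x <= bineq`.
#' @param maximize logical; maximize instead of minimize.
#'
#' @return list with `x` (solution), `objval`, and `status` (`"optimal"` or
#'   `"infeasible"`).
#' @keywords internal
solve_lp <- function(obj, Aeq, beq, lb, ub,
                     Aineq = NULL, bineq = NULL, maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite variable bounds")
  if (any(lb > ub + 1e-9))
    return(list(x = NULL, objval = NA_real_, status = "infeasible"))

  A <- as.matrix(Aeq)
  b <- as.numeric(beq)
  cc <- if (maximize) -obj else obj
  l <- lb; u <- ub
  if (!is.null(Aineq)) {             # slack variables for inequality rows
    Aineq <- as.matrix(Aineq)
    ns <- nrow(Aineq)
    A <- rbind(cbind(A, matrix(0, nrow(A), ns)),
               cbind(Aineq, diag(ns)))
    b <- c(b, as.numeric(bineq))
    cc <- c(cc, numeric(ns))
    slack_cap <- max(1, sum(abs(bineq)) + sum(abs(Aineq) %*% pmax(abs(lb), abs(ub))))
    l <- c(l, numeric(ns)); u <- c(u, rep(slack_cap, ns))
  }
  res <- simplex_bounded(cc, A, b, l, u)
  if (res$status != "optimal")
    return(list(x = NULL, objval = NA_real_, status = res$status))
  x <- res$x[seq_len(n)]
  list(x = x, objval = sum(obj * x), status = "optimal")
}

# Two-phase bounded-variable revised simplex, Bland's rule throughout.
# min cc'x  s.t.  A x = b,  l <= x <= u  (l, u finite for structural
# variables; artificials get an infinite upper bound internally).
simplex_bounded <- function(cc, A, b, l, u, tol = 1e-9, maxiter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  # phase 1: artificial basis carrying the residual of x at lower bounds
  r <- b - as.numeric(A %*% l)
  sg <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sg, m))
  lf <- c(l, numeric(m))
  uf <- c(u, rep(Inf, m))
  cart <- c(numeric(n), rep(1, m))
  state <- list(
    basis = n + seq_len(m),                  # basic variable indices
    at_upper = rep(FALSE, n + m),            # nonbasic-at-upper flags
    x = c(l, abs(r)))
  st <- simplex_core(cart, Afull, b, lf, uf, state, tol, maxiter)
  if (st$status != "optimal") return(st)
  if (sum(cart * st$x) > 1e-7)
    return(list(status = "infeasible"))
  # phase 2: pin artificials to zero, optimize the true objective
  uf[n + seq_len(m)] <- 0
  st$x[n + seq_len(m)] <- 0
  st <- simplex_core(c(cc, numeric(m)), Afull, b, lf, uf, st, tol, maxiter)
  if (st$status != "optimal") return(st)
  list(status = "optimal", x = st$x[seq_len(n)], objval = sum(cc * st$x[seq_len(n)]))
}

simplex_core <- function(cc, A, b, l, u, state, tol, maxiter) {
  m <- nrow(A); n <- ncol(A)
  basis <- state$basis
  at_upper <- state$at_upper
  x <- state$x
  in_basis <- logical(n); in_basis[basis] <- TRUE
  Binv <- NULL
  since_refac <- 0L
  degen <- 0L          # consecutive degenerate pivots; triggers Bland's rule
  for (it in seq_len(maxiter)) {
    if (is.null(Binv) || since_refac >= 40L) {
      Binv <- tryCatch(solve(A[, basis, drop = FALSE]), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular"))
      since_refac <- 0L
    }
    nb <- which(!in_basis)
    x[basis] <- as.numeric(Binv %*% (b - A[, nb, drop = FALSE] %*% x[nb]))
    y <- as.numeric(crossprod(Binv, cc[basis]))
    d <- cc[nb] - as.numeric(crossprod(A[, nb, drop = FALSE], y))
    improving <- (d < -tol & !at_upper[nb]) | (d > tol & at_upper[nb])
    if (!any(improving)) {
      return(list(status = "optimal", basis = basis, at_upper = at_upper, x = x))
    }
    cand <- nb[improving]
    j <- if (degen > 30L) min(cand) else cand[which.max(abs(d[improving]))]
    dir <- if (at_upper[j]) -1 else 1                # entering moves off its bound
    w <- as.numeric(Binv %*% A[, j]) * dir           # x_B changes by -w * t
    # ratio test: how far can the entering variable move
    step_k <- rep(Inf, m)                            # per-basic blocking step
    dec <- w > tol                                   # basic decreases to its lb
    inc <- w < -tol & is.finite(u[basis])            # basic increases to its ub
    step_k[dec] <- (x[basis[dec]] - l[basis[dec]]) / w[dec]
    step_k[inc] <- (u[basis[inc]] - x[basis[inc]]) / (-w[inc])
    to_upper_k <- inc
    tflip <- u[j] - l[j]                             # bound-to-bound flip
    tmax <- min(tflip, step_k)
    if (!is.finite(tmax)) return(list(status = "unbounded"))
    tmax <- max(tmax, 0)
    degen <- if (tmax <= tol) degen + 1L else 0L
    leave <- 0L; leave_to_upper <- FALSE
    if (min(step_k) <= tflip + tol) {
      blockers <- which(step_k <= tmax + tol)        # Bland: smallest-index leaver
      leave <- blockers[which.min(basis[blockers])]
      leave_to_upper <- to_upper_k[leave]
      tmax <- max(min(tmax, step_k[leave]), 0)
    }
    # apply step
    x[basis] <- x[basis] - w * tmax
    x[j] <- x[j] + dir * tmax
    if (leave == 0L) {                               # bound flip, basis unchanged
      at_upper[j] <- !at_upper[j]
    } else {
      bi <- basis[leave]
      x[bi] <- if (leave_to_upper) u[bi] else l[bi]
      at_upper[bi] <- leave_to_upper
      in_basis[bi] <- FALSE
      basis[leave] <- j
      in_basis[j] <- TRUE
      at_upper[j] <- FALSE
      # product-form update of the basis inverse
      dj <- w * dir                                  # Binv %*% A[, j]
      piv <- dj[leave]
      if (abs(piv) < 1e-10) { Binv <- NULL }         # force refactorization
      else {
        row_l <- Binv[leave, ] / piv
        Binv <- Binv - outer(dj, row_l)
        Binv[leave, ] <- row_l
        since_refac <- since_refac + 1L
      }
    }
  }
  list(status = "maxiter")
}
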