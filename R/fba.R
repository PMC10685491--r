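#' Flux balance analysis
#'
#' Solves the LP max/min v_obj subject to S v = 0 and the model's flux bounds.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#'
#' @return a `flux_solution`: list with `fluxes` (named vector), `objective`
#'   (list of reaction/sense/value), and `status` (`"optimal"`/`"infeasible"`).
#'   On infeasibility `fluxes` is `NULL`.
#' @export
fba <- function(model, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  j <- match(objective, model$rxns$id)
  if (is.na(j)) stop("objective reaction not in model: ", objective)
  n <- nrow(model$rxns)
  obj <- numeric(n); obj[j] <- 1
  sol <- solve_lp(obj, Aeq = dense_S(model), beq = rep(0, nrow(model$S)),
                  lb = model$rxns$lb, ub = model$rxns$ub,
                  maximize = (sense == "max"))
  flux_solution(model, sol$x, list(list(reaction = objective, sense = sense,
                                        value = sol$objval)), sol$status)
}

flux_solution <- function(model, x, objectives, status) {
  fl <- NULL
  if (!is.null(x)) fl <- stats::setNames(x, model$rxns$id)
  structure(list(fluxes = fl, objectives = objectives, status = status),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status, "\n")
  for (o in x$objectives)
    cat(sprintf("  %s %s = %.6g\n", o$sense, o$reaction, o$value))
  invisible(x)
}

#' Parsimonious flux balance analysis
#'
#' Optimizes the objective reaction, fixes it at its optimum, then minimizes
#' the total absolute flux sum. The reported objective value equals the plain
#' FBA optimum; the flux vector is the minimal-total-flux representative of
#' the optimal face. Flux splitting uses auxiliary variables s_i >= |v_i|.
#'
#' @inheritParams fba
#' @return a `flux_solution`; `total_flux` holds the minimized sum of |v|.
#' @export
pfba <- function(model, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  first <- fba(model, objective, sense)
  if (first$status != "optimal") return(first)
  opt <- first$objectives[[1]]$value

  model2 <- fix_objective(model, objective, sense, opt)
  n <- nrow(model2$rxns)
  # variables [v; s], minimize sum(s), s_i >= |v_i|
  obj <- c(numeric(n), rep(1, n))
  Aeq <- cbind(dense_S(model2), matrix(0, nrow(model2$S), n))
  big <- pmax(abs(model2$rxns$lb), abs(model2$rxns$ub))
  lb <- c(model2$rxns$lb, numeric(n))
  ub <- c(model2$rxns$ub, big)
  Ain <- rbind(cbind(diag(n), -diag(n)),     #  v - s <= 0
               cbind(-diag(n), -diag(n)))    # -v - s <= 0
  sol <- solve_lp(obj, Aeq, rep(0, nrow(model2$S)), lb, ub,
                  Aineq = Ain, bineq = rep(0, 2 * n), maximize = FALSE)
  if (sol$status != "optimal")
    return(flux_solution(model, NULL,
                         list(list(reaction = objective, sense = sense, value = NA_real_)),
                         "infeasible"))
  out <- flux_solution(model, sol$x[seq_len(n)],
                       list(list(reaction = objective, sense = sense, value = opt)),
                       "optimal")
  out$total_flux <- sol$objval
  out
}

# Fix a single-reaction objective at its optimum with a small feasibility
# slack eps = 1e-6 * max(1, |opt|) on the optimizing side.
fix_objective <- function(model, rxn, sense, opt) {
  eps <- 1e-6 * max(1, abs(opt))
  i <- match(rxn, model$rxns$id)
  if (sense == "max") {
    model$rxns$lb[i] <- opt - eps
    model$rxns$ub[i] <- max(model$rxns$ub[i], opt)
  } else {
    model$rxns$ub[i] <- opt + eps
    model$rxns$lb[i] <- min(model$rxns$lb[i], opt)
  }
  model
}

#' Lexicographic flux balance analysis
#'
#' Optimizes an ordered list of single-reaction objectives: objective k+1 is
#' solved with objectives 1..k fixed at their optima (within a relative
#' fixing tolerance of 1e-6). The order mirrors staged process objectives,
#' e.g. maximize growth, then minimize sulfate uptake, then maximize product
#' synthesis.
#'
#' @param model a `metabolic_model`.
#' @param objectives list of `list(reaction=, sense=)` entries (or a character
#'   vector of reaction ids, all maximized).
#'
#' @return a `flux_solution` whose `objectives` carry the per-level optima in
#'   order; the flux vector is the solution of the last level.
#' @export
lexicographic_fba <- function(model, objectives) {
  if (is.character(objectives))
    objectives <- lapply(objectives, function(r) list(reaction = r, sense = "max"))
  stopifnot(length(objectives) >= 1)
  levels <- list()
  sol <- NULL
  for (k in seq_along(objectives)) {
    ob <- objectives[[k]]
    sense <- match.arg(ob$sense, c("max", "min"))
    sol <- fba(model, ob$reaction, sense)
    if (sol$status != "optimal")
      stop("lexicographic FBA infeasible at level ", k, " (", ob$reaction, ")")
    opt <- sol$objectives[[1]]$value
    levels[[k]] <- list(reaction = ob$reaction, sense = sense, value = opt)
    if (k < length(objectives))
      model <- fix_objective(model, ob$reaction, sense, opt)
  }
  flux_solution(model, sol$fluxes, levels, "optimal")
}

#' Minimal medium from parsimonious growth
#'
#' Runs biomass pFBA and returns the exchange reactions with uptake above the
#' solver noise floor (1e-6 mmol gDW^-1 h^-1). These define the minimal
#' medium; [apply_minimal_medium()] then closes every other exchange except
#' water and protons.
#'
#' @param model a `metabolic_model` with a designated biomass reaction.
#' @param zero_tol uptake magnitude below which an exchange is not counted.
#' @return named numeric vector: exchange reaction id -> uptake magnitude
#'   (mmol gDW^-1 h^-1).
#' @export
minimal_medium <- function(model, zero_tol = 1e-6) {
  if (is.null(model$biomass_id)) stop("model has no biomass reaction")
  sol <- pfba(model, model$biomass_id, "max")
  if (sol$status != "optimal") stop("biomass pFBA infeasible; cannot derive medium")
  if (sol$objectives[[1]]$value <= zero_tol)
    stop("no growth possible; cannot derive a minimal medium")
  ex <- exchanges(model)
  up <- -sol$fluxes[ex]
  up <- up[up > zero_tol]
  up
}

#' Restrict a model to a minimal medium
#'
#' Closes the uptake side (`lb = 0`) of every exchange reaction not in
#' `medium`, keeping water and proton exchange open. Secretion bounds are
#' untouched.
#'
#' @param model a `metabolic_model`.
#' @param medium named vector from [minimal_medium()] (names are exchange ids;
#'   values are maximal uptake magnitudes, applied as `lb = -value` only when
#'   `cap_uptake = TRUE`).
#' @param keep_open exchange ids always left open (water, protons).
#' @param cap_uptake if `TRUE`, also cap the uptake of medium components at
#'   the supplied values; default leaves them at the model bounds.
#' @return the modified model.
#' @export
apply_minimal_medium <- function(model, medium,
                                 keep_open = c("EX_h2o_e", "EX_h_e"),
                                 cap_uptake = FALSE) {
  ex <- exchanges(model)
  close <- setdiff(ex, c(names(medium), keep_open))
  if (length(close)) model <- set_bounds(model, close, lb = 0)
  if (cap_uptake)
    model <- set_bounds(model, names(medium), lb = -as.numeric(medium))
  model
}
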