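#' Compare nutrient uptake under growth versus plasmid synthesis
#'
#' Runs two parsimonious FBAs on a plasmid-augmented model restricted to its
#' minimal medium — one maximizing biomass, one maximizing plasmid synthesis —
#' and records the uptake of every minimal-medium component under each
#' objective. Nutrients that growth needs but plasmid synthesis does not are
#' the candidate decoupling agents: withdrawing them halts growth while
#' leaving production feasible.
#'
#' @param model plasmid-augmented `metabolic_model` (see
#'   [add_plasmid_pathway()]).
#' @param medium optional minimal medium (from [minimal_medium()]); computed
#'   if missing. The model is restricted to it either way.
#' @return a `decoupling_report` data.frame: one row per medium component
#'   with `uptake_biomass`, `uptake_pdna` (mmol gDW^-1 h^-1, magnitudes),
#'   `essential` and `decoupler` logical flags (`NA` until
#'   [classify_decouplers()] fills them).
#' @export
uptake_comparison <- function(model, medium = NULL) {
  sink_id <- attr(model, "pdna_sink_id")
  if (is.null(sink_id)) stop("model has no plasmid pathway")
  if (is.null(medium)) medium <- minimal_medium(model)
  m <- apply_minimal_medium(model, medium)
  bio <- pfba(m, m$biomass_id, "max")
  pdna <- pfba(m, sink_id, "max")
  if (pdna$status != "optimal" || pdna$objectives[[1]]$value <= 1e-9)
    stop("plasmid synthesis infeasible on the minimal medium")
  structure(data.frame(
    exchange = names(medium),
    uptake_biomass = unname(pmax(-bio$fluxes[names(medium)], 0)),
    uptake_pdna = unname(pmax(-pdna$fluxes[names(medium)], 0)),
    essential = NA, decoupler = NA,
    row.names = NULL), class = c("decoupling_report", "data.frame"))
}

#' Plasmid production envelope under a nutrient uptake cap
#'
#' Caps the uptake of one minimal-medium component at a fraction of its rate
#' during optimal growth, then computes the maximal and minimal plasmid
#' synthesis flux at equidistant growth levels between zero and the capped
#' growth optimum. Output is normalized: growth as percent of the *uncapped*
#' optimum, plasmid flux as percent of the zero-growth synthesis capacity of
#' the unrestricted medium, so envelopes for different nutrients and caps are
#' directly comparable.
#'
#' @param model plasmid-augmented `metabolic_model`.
#' @param nutrient exchange reaction id of the capped component.
#' @param fraction cap as a fraction (0, 1] of the biomass-optimal uptake.
#' @param medium minimal medium (computed if missing).
#' @param n_growth number of growth levels (the envelope boundary is
#'   piecewise linear; 20 points resolve it amply).
#' @return data.frame with `growth_pct`, `pdna_min_pct`, `pdna_max_pct`
#'   (empty, with a warning, if the cap makes the model infeasible);
#'   attribute `fraction`.
#' @export
production_envelope <- function(model, nutrient, fraction, medium = NULL,
                                n_growth = 20) {
  stopifnot(fraction > 0, fraction <= 1)
  sink_id <- attr(model, "pdna_sink_id")
  if (is.null(sink_id)) stop("model has no plasmid pathway")
  if (is.null(medium)) medium <- minimal_medium(model)
  if (!nutrient %in% names(medium)) stop("nutrient not in minimal medium: ", nutrient)
  m <- apply_minimal_medium(model, medium)

  mu_max0 <- fba(m, m$biomass_id, "max")$objectives[[1]]$value
  pdna_cap0 <- fba(m, sink_id, "max")$objectives[[1]]$value

  mc <- set_bounds(m, nutrient, lb = -fraction * medium[[nutrient]])
  sol_mu <- fba(mc, mc$biomass_id, "max")
  if (sol_mu$status != "optimal") {
    warning("infeasible at all growth values for ", nutrient,
            " at fraction ", fraction, call. = FALSE)
    out <- data.frame(growth_pct = numeric(0), pdna_min_pct = numeric(0),
                      pdna_max_pct = numeric(0))
    attr(out, "fraction") <- fraction
    return(out)
  }
  mu_cap <- sol_mu$objectives[[1]]$value
  mus <- seq(0, mu_cap, length.out = n_growth)
  res <- vapply(mus, function(mu) {
    mm <- set_bounds(mc, mc$biomass_id, lb = mu, ub = mu)
    hi <- fba(mm, sink_id, "max")
    lo <- fba(mm, sink_id, "min")
    c(if (hi$status == "optimal") hi$objectives[[1]]$value else NA_real_,
      if (lo$status == "optimal") lo$objectives[[1]]$value else NA_real_)
  }, numeric(2))
  out <- data.frame(growth_pct = 100 * mus / mu_max0,
                    pdna_max_pct = 100 * res[1, ] / pdna_cap0,
                    pdna_min_pct = 100 * res[2, ] / pdna_cap0)
  attr(out, "fraction") <- fraction
  out
}

#' Classify decoupling medium components
#'
#' A medium component decouples production from growth when restricting its
#' uptake raises the maximal plasmid synthesis attainable at maximal (capped)
#' growth: the component is essential for biomass formation but not for the
#' product. The test evaluates the envelope top point at caps of 100, 75, 50,
#' 25, and 5 percent of the biomass-optimal uptake and flags components whose
#' plasmid optimum at maximal growth increases (relative tolerance 1e-6) as
#' the cap tightens.
#'
#' @param model plasmid-augmented `metabolic_model`.
#' @param medium minimal medium (computed if missing).
#' @param fractions cap levels, descending.
#' @return a `decoupling_report` (see [uptake_comparison()]) with
#'   `essential` and `decoupler` filled in.
#' @export
classify_decouplers <- function(model, medium = NULL,
                                fractions = c(1, 0.75, 0.5, 0.25, 0.05)) {
  sink_id <- attr(model, "pdna_sink_id")
  if (is.null(medium)) medium <- minimal_medium(model)
  rep <- uptake_comparison(model, medium)
  m <- apply_minimal_medium(model, medium)

  top_point <- function(nutrient, fraction) {
    mc <- set_bounds(m, nutrient, lb = -fraction * medium[[nutrient]])
    sol_mu <- fba(mc, mc$biomass_id, "max")
    if (sol_mu$status != "optimal") return(c(NA_real_, NA_real_))
    mu <- sol_mu$objectives[[1]]$value
    mm <- set_bounds(mc, mc$biomass_id, lb = mu, ub = mu)
    hi <- fba(mm, sink_id, "max")
    c(mu, if (hi$status == "optimal") hi$objectives[[1]]$value else NA_real_)
  }

  ess <- dec <- logical(nrow(rep))
  for (i in seq_len(nrow(rep))) {
    nut <- rep$exchange[i]
    blocked <- fba(set_bounds(m, nut, lb = 0), m$biomass_id, "max")
    ess[i] <- blocked$status != "optimal" ||
      blocked$objectives[[1]]$value < 1e-6
    tops <- vapply(fractions, function(f) top_point(nut, f)[2], 0)
    incr <- diff(tops)          # successive tightening of the cap
    dec[i] <- any(!is.na(incr) & incr > 1e-6 * pmax(1, abs(tops[-length(tops)])))
  }
  rep$essential <- ess
  rep$decoupler <- dec
  rep
}
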