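#' Screen secreted products for sulfate-limitation benefit
#'
#' For every candidate product the staged objectives (maximize growth,
#' minimize sulfate uptake, maximize product synthesis) are solved twice on
#' the minimal medium: once with sulfate available and once with its uptake
#' blocked. Blocking sulfate forces zero growth, so the blocked rate `q*` is
#' the zero-growth synthesis capacity; products whose `q*` exceeds the
#' growth-coupled rate `q_mu` benefit from a sulfate-limited process design.
#' Products whose biosynthesis requires sulfur atoms necessarily have
#' `q* = 0`.
#'
#' @param model plasmid-augmented (or plain) `metabolic_model`.
#' @param products character vector of exchange/sink reaction ids to screen.
#'   Defaults to every exchange reaction that is not a minimal-medium
#'   component, water, or proton exchange; a curated list can be supplied
#'   instead.
#' @param medium minimal medium (computed if missing).
#' @param tol relative improvement tolerance (LP noise floor).
#' @return data.frame with `product`, `q_mu`, `q_star` (mmol gDW^-1 h^-1),
#'   and logical `improved`.
#' @export
screen_products <- function(model, products = NULL, medium = NULL,
                            tol = 1e-6) {
  if (is.null(medium)) medium <- minimal_medium(model)
  m <- apply_minimal_medium(model, medium)
  if (is.null(products))
    products <- setdiff(exchanges(m), c(names(medium), "EX_h2o_e", "EX_h_e"))
  miss <- setdiff(products, m$rxns$id)
  if (length(miss)) stop("unknown product reaction(s): ",
                         paste(miss, collapse = ", "))
  m_blocked <- set_bounds(m, "EX_so4_e", lb = 0)

  rate <- function(mod, prod) {
    sol <- tryCatch(
      lexicographic_fba(mod, list(
        list(reaction = mod$biomass_id, sense = "max"),
        list(reaction = "EX_so4_e", sense = "max"),   # least uptake
        list(reaction = prod, sense = "max"))),
      error = function(e) NULL)
    if (is.null(sol)) 0 else max(unname(sol$fluxes[prod]), 0)
  }

  q_mu <- vapply(products, function(p) rate(m, p), 0)
  q_star <- vapply(products, function(p) rate(m_blocked, p), 0)
  data.frame(product = products,
             q_mu = unname(q_mu), q_star = unname(q_star),
             improved = unname(q_star > q_mu * (1 + tol) + 1e-9),
             row.names = NULL)
}
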