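# Fixtures and closed-form oracles, built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

minisulf_base <- function() cached("base", function() make_minisulf())

minisulf_pdna <- function() cached("pdna", function()
  make_minisulf(plasmid = plasmid_spec()))

minisulf_medium <- function() cached("medium", function()
  minimal_medium(minisulf_pdna()))

# default linear fed-batch trajectory (3.8 g/L sulfate, kappa = 2)
default_traj <- function() cached("traj", function()
  simulate_fedbatch(minisulf_pdna(), process_config(), n_out = 61))

# Exact solution of the linear-feed fed-batch on MiniSulf. With the glucose
# uptake fixed by the feed, biomass follows the linear ODE
#   d(XV)/dt = (r F - (g_m + a_glc q_mu) XV) / g_x  =  c1 - c2 XV,
# so XV(t) = A + (XV0 - A) exp(-c2 t) with A = c1/c2; sulfate is consumed
# proportionally to biomass gain; plasmid accumulates at q_mu XV during
# growth and kappa q_mu XV(t_s) during starvation.
closed_form_linear <- function(cfg = process_config(),
                               spec = minisulf_spec(),
                               plasmid = plasmid_spec()) {
  tru <- minisulf_truth(spec, plasmid)
  rF <- cfg$feed$r_lin * cfg$feed$c_glc_feed / 180.156 * 1000   # mmol glc/h
  q_mu_mmol <- cfg$q_pdna_mu / plasmid$molecular_weight
  c1 <- rF / spec$g_x
  c2 <- (spec$g_m + tru$a_glc * q_mu_mmol) / spec$g_x
  A <- c1 / c2
  xv0 <- cfg$c_biomass0 * cfg$v0
  XV <- function(t) A + (xv0 - A) * exp(-c2 * t)
  iXV <- function(t) A * t + (xv0 - A) * (1 - exp(-c2 * t)) / c2
  t_end <- (cfg$v_max - cfg$v0) / cfg$feed$r_lin
  ns0 <- cfg$c_so4_0 * cfg$v0 / 96.06 * 1000                    # mmol
  xv_s <- xv0 + ns0 / spec$s_x
  t_switch <- if (xv_s >= A || XV(t_end) <= xv_s) NA_real_
              else log((A - xv0) / (A - xv_s)) / c2
  np <- function(t) {          # plasmid amount, mg
    if (is.na(t_switch) || t <= t_switch) cfg$q_pdna_mu * iXV(t)
    else cfg$q_pdna_mu * iXV(t_switch) +
      cfg$kappa * cfg$q_pdna_mu * XV(t_switch) * (t - t_switch)
  }
  # plasmid amount at process end as a function of the switching time
  np_end_at <- function(ts, kappa)
    cfg$q_pdna_mu * (iXV(ts) + kappa * XV(ts) * (t_end - ts))
  dose_for_ts <- function(ts)   # initial sulfate dose that switches at ts
    spec$s_x * (XV(ts) - xv0) * 96.06 / 1000 / cfg$v0
  list(XV = XV, iXV = iXV, np = np, np_end_at = np_end_at,
       dose_for_ts = dose_for_ts, t_end = t_end, t_switch = t_switch,
       xv0 = xv0, ns0 = ns0, spec = spec, cfg = cfg)
}

# elemental balance of one reaction for selected elements
reaction_element_balance <- function(model, rxn, elements = c("C", "N", "P", "S")) {
  st <- reaction_stoich(model, rxn)
  bal <- stats::setNames(numeric(length(elements)), elements)
  for (met in names(st)) {
    f <- model$mets$formula[model$mets$id == met]
    counts <- pdnaflux:::parse_formula(f)
    for (e in elements)
      if (e %in% names(counts)) bal[e] <- bal[e] + st[[met]] * counts[[e]]
  }
  bal
}
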