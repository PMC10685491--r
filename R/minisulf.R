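#' Specification of the MiniSulf test network
#'
#' MiniSulf is a deliberately small sulfate-dependent metabolic network whose
#' optima are hand-checkable. It lumps energy metabolism into glucose
#' equivalents: biomass requires glucose, sulfate, ammonium, phosphate,
#' potassium, and oxygen; maintenance is a fixed glucose-oxidation drain; the
#' deoxyribonucleotide precursors of plasmid synthesis derive from glucose,
#' ammonium, phosphate, and respiratory oxygen (no sulfur), so sulfate and
#' potassium are
#' decoupling nutrients by construction. An acetate overflow route disposes
#' of excess carbon when growth stops.
#'
#' The default coefficients mimic an E. coli fed-batch: a biomass/glucose
#' yield of 0.303 g/g (18.32 mmol glucose per gDW), 0.62 mmol sulfate per gDW
#' (the effective sulfate yield of a process in which 3.8 g/L sulfate in a
#' 0.5 L starting volume is exhausted about two thirds into the feed phase),
#' a maintenance drain of 0.3 mmol glucose per gDW and hour (the glucose
#' equivalent of the canonical 6.86 mmol ATP NGAM at ~23 mol ATP per mol
#' glucose), and a glucose uptake cap of 10 mmol per gDW and hour.
#'
#' @param g_x,s_x,n_x,p_x,k_x,o_x biomass requirements per gDW: glucose,
#'   sulfate, ammonium, phosphate, potassium, oxygen (mmol/gDW).
#' @param g_m maintenance glucose drain (mmol gDW^-1 h^-1, reaction `NGAM`).
#' @param glc_cap maximal glucose uptake (mmol gDW^-1 h^-1).
#' @param atp_per_glc lumped ATP yield per glucose for ATP regeneration.
#' @return object of class `minisulf_spec`.
#' @export
minisulf_spec <- function(g_x = 18.32, s_x = 0.62, n_x = 8.6, p_x = 0.9,
                          k_x = 0.15, o_x = 10, g_m = 0.3, glc_cap = 10,
                          atp_per_glc = 23) {
  vals <- c(g_x = g_x, s_x = s_x, n_x = n_x, p_x = p_x, k_x = k_x, o_x = o_x,
            glc_cap = glc_cap, atp_per_glc = atp_per_glc)
  if (any(vals <= 0)) stop("all MiniSulf coefficients must be positive")
  if (g_m < 0) stop("maintenance drain must be >= 0")
  if (g_m >= glc_cap) stop("maintenance drain must be below the glucose uptake cap")
  structure(as.list(c(as.list(vals), g_m = g_m)), class = "minisulf_spec")
}

#' Build the MiniSulf model
#'
#' Constructs the network of [minisulf_spec()] as a `metabolic_model`,
#' optionally augmented with a plasmid synthesis pathway and written to SBML.
#'
#' Ground truths (see [minisulf_truth()]): maximal growth
#' `(glc_cap - g_m)/g_x`; minimal medium glucose, O2, NH4+, phosphate,
#' sulfate, K+; decouplers sulfate and K+; zero-growth plasmid synthesis
#' capacity `(glc_cap - g_m)/a_glc` where `a_glc` is the lumped glucose cost
#' per plasmid.
#'
#' @param spec a [minisulf_spec()].
#' @param plasmid `NULL`, or a [plasmid_spec()] to add via
#'   [add_plasmid_pathway()].
#' @param sbml_path optional path; if given the model is also written as SBML.
#' @return a `metabolic_model`.
#' @export
make_minisulf <- function(spec = minisulf_spec(), plasmid = NULL,
                          sbml_path = NULL) {
  stopifnot(inherits(spec, "minisulf_spec"))
  mets <- rbind(
    data.frame(id = "glc_e",  formula = "C6H12O6",       charge = 0,  compartment = "e"),
    data.frame(id = "o2_e",   formula = "O2",            charge = 0,  compartment = "e"),
    data.frame(id = "nh4_e",  formula = "H4N",           charge = 1,  compartment = "e"),
    data.frame(id = "pi_e",   formula = "HO4P",          charge = -2, compartment = "e"),
    data.frame(id = "so4_e",  formula = "O4S",           charge = -2, compartment = "e"),
    data.frame(id = "k_e",    formula = "K",             charge = 1,  compartment = "e"),
    data.frame(id = "ac_e",   formula = "C2H3O2",        charge = -1, compartment = "e"),
    data.frame(id = "co2_e",  formula = "CO2",           charge = 0,  compartment = "e"),
    data.frame(id = "h2o_e",  formula = "H2O",           charge = 0,  compartment = "e"),
    data.frame(id = "h_e",    formula = "H",             charge = 1,  compartment = "e"),
    data.frame(id = "h2s_e",  formula = "H2S",           charge = 0,  compartment = "e"),
    data.frame(id = "datp_c", formula = "C10H12N5O12P3", charge = -4, compartment = "c"),
    data.frame(id = "dttp_c", formula = "C10H13N2O14P3", charge = -4, compartment = "c"),
    data.frame(id = "dgtp_c", formula = "C10H12N5O13P3", charge = -4, compartment = "c"),
    data.frame(id = "dctp_c", formula = "C9H12N3O13P3",  charge = -4, compartment = "c"),
    data.frame(id = "atp_c",  formula = "C10H12N5O13P3", charge = -4, compartment = "c"),
    data.frame(id = "adp_c",  formula = "C10H12N5O10P2", charge = -3, compartment = "c"),
    data.frame(id = "pi_c",   formula = "HO4P",          charge = -2, compartment = "c"),
    data.frame(id = "ppi_c",  formula = "HO7P2",         charge = -3, compartment = "c"),
    data.frame(id = "h2o_c",  formula = "H2O",           charge = 0,  compartment = "c"),
    data.frame(id = "h_c",    formula = "H",             charge = 1,  compartment = "c"))

  m <- metabolic_model("minisulf", mets,
                       rxns = data.frame(id = character(), lb = numeric(), ub = numeric()),
                       S = Matrix::Matrix(0, nrow(mets), 0, sparse = TRUE))

  ex <- function(m, met, lb, ub)
    add_reaction(m, paste0("EX_", met), stats::setNames(-1, met), lb = lb, ub = ub)
  m <- ex(m, "glc_e", -spec$glc_cap, 1000)
  m <- ex(m, "o2_e", -1000, 1000)
  m <- ex(m, "nh4_e", -1000, 1000)
  m <- ex(m, "pi_e", -1000, 1000)
  m <- ex(m, "so4_e", -1000, 1000)
  m <- ex(m, "k_e", -1000, 1000)
  m <- ex(m, "ac_e", 0, 1000)
  m <- ex(m, "co2_e", 0, 1000)
  m <- ex(m, "h2o_e", -1000, 1000)
  m <- ex(m, "h_e", -1000, 1000)
  m <- ex(m, "h2s_e", 0, 1000)

  m <- add_reaction(m, "GROWTH",
                    c(glc_e = -spec$g_x, so4_e = -spec$s_x, nh4_e = -spec$n_x,
                      pi_e = -spec$p_x, k_e = -spec$k_x, o2_e = -spec$o_x),
                    lb = 0, ub = 1000)
  # maintenance as complete glucose oxidation, fixed lower bound
  m <- add_reaction(m, "NGAM",
                    c(glc_e = -1, o2_e = -6, co2_e = 6, h2o_e = 6),
                    lb = spec$g_m, ub = 1000)
  # acetate overflow: carbon disposal when growth halts
  m <- add_reaction(m, "OVERFLOW",
                    c(glc_e = -1, o2_e = -2, ac_e = 2, co2_e = 2, h2o_e = 2, h_e = 2),
                    lb = 0, ub = 1000)
  # lumped dNTP synthesis from glucose/ammonium/phosphate with respiratory
  # oxygen demand (C, N, P, S balanced; H/O lumped like the biomass reaction)
  m <- add_reaction(m, "DATPS",
                    c(glc_e = -10 / 6, nh4_e = -5, pi_e = -3, o2_e = -2, datp_c = 1))
  m <- add_reaction(m, "DTTPS",
                    c(glc_e = -10 / 6, nh4_e = -2, pi_e = -3, o2_e = -2, dttp_c = 1))
  m <- add_reaction(m, "DGTPS",
                    c(glc_e = -10 / 6, nh4_e = -5, pi_e = -3, o2_e = -2, dgtp_c = 1))
  m <- add_reaction(m, "DCTPS",
                    c(glc_e = -9 / 6, nh4_e = -3, pi_e = -3, o2_e = -2, dctp_c = 1))
  # ADP rephosphorylation at the lumped ATP yield per glucose
  m <- add_reaction(m, "ATPREGEN",
                    c(glc_e = -1 / spec$atp_per_glc, adp_c = -1, pi_c = -1,
                      atp_c = 1, co2_e = 6 / spec$atp_per_glc))
  # pyrophosphatase and inorganic transport shuttles
  m <- add_reaction(m, "PPA", c(ppi_c = -1, h2o_c = -1, pi_c = 2, h_c = 1))
  m <- add_reaction(m, "PIT", c(pi_c = -1, pi_e = 1), lb = -1000, ub = 1000)
  m <- add_reaction(m, "H2OT", c(h2o_c = -1, h2o_e = 1), lb = -1000, ub = 1000)
  m <- add_reaction(m, "HT", c(h_c = -1, h_e = 1), lb = -1000, ub = 1000)
  # sulfate reduction to a secreted sulfur product (blocked without sulfate)
  m <- add_reaction(m, "SULFRED",
                    c(so4_e = -1, glc_e = -0.5, h2s_e = 1, co2_e = 3))

  m$biomass_id <- "GROWTH"
  m$ngam_id <- "NGAM"
  validate_model(m)
  if (!is.null(plasmid)) m <- add_plasmid_pathway(m, plasmid)
  if (!is.null(sbml_path)) write_sbml(m, sbml_path)
  m
}

#' Closed-form ground truths of MiniSulf
#'
#' Documented constants of the fixture, used as independent oracles: maximal
#' growth rate, lumped glucose cost per plasmid, zero-growth plasmid
#' synthesis capacity, the minimal medium, and the decoupler set.
#'
#' @param spec a [minisulf_spec()].
#' @param plasmid a [plasmid_spec()] (for the glucose cost per plasmid).
#' @return list with `mu_max` (h^-1), `a_glc` (mmol glucose per mmol
#'   plasmid), `pdna_capacity` (mmol gDW^-1 h^-1 at zero growth),
#'   `minimal_medium` (exchange ids), `decouplers` (exchange ids).
#' @export
minisulf_truth <- function(spec = minisulf_spec(), plasmid = plasmid_spec()) {
  glc_per_dntp <- c(datp = 10 / 6, dttp = 10 / 6, dgtp = 10 / 6, dctp = 9 / 6)
  a_glc <- sum(glc_per_dntp * plasmid$counts[names(glc_per_dntp)]) +
    plasmid$atp_per_dntp * 2 * plasmid$length_bp / spec$atp_per_glc
  list(mu_max = (spec$glc_cap - spec$g_m) / spec$g_x,
       a_glc = a_glc,
       pdna_capacity = (spec$glc_cap - spec$g_m) / a_glc,
       minimal_medium = c("EX_glc_e", "EX_o2_e", "EX_nh4_e", "EX_pi_e",
                          "EX_so4_e", "EX_k_e"),
       decouplers = c("EX_so4_e", "EX_k_e"))
}
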