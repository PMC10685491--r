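MW_GLUCOSE <- 180.156   # g/mol
MW_SULFATE <- 96.06     # g/mol

#' Feed specification for a fed-batch process
#'
#' @param mode `"linear"` (constant volumetric rate), `"exponential"`
#'   (rate tracking a set specific growth rate), or `"none"` (batch).
#' @param r_lin constant feed rate, L/h (linear mode). The default is the
#'   0.26 g/min (13.91 mL/h) feed of a 1 L-scale process.
#' @param mu_set set specific growth rate, 1/h (exponential mode).
#' @param y_feed_per_biomass feed volume demand per g biomass, L/g
#'   (exponential mode).
#' @param c_glc_feed glucose concentration of the feed medium, g/L. The
#'   default supplies 48.5 g biomass at a biomass/glucose yield of 0.303 g/g
#'   in 0.5 L of feed.
#' @param density feed density, g/mL (mass/volume rate conversion only).
#' @param sulfate_free logical; the feed contains no sulfate (sulfate is dosed
#'   entirely in the starting volume).
#' @return object of class `feed_spec`.
#' @export
feed_spec <- function(mode = c("linear", "exponential", "none"),
                      r_lin = 0.01391, mu_set = 0.2,
                      y_feed_per_biomass = 0.0103,
                      c_glc_feed = 48.5 / 0.303 / 0.5, density = 1.12,
                      sulfate_free = TRUE) {
  mode <- match.arg(mode)
  if (r_lin < 0 || mu_set < 0 || y_feed_per_biomass < 0 || c_glc_feed < 0)
    stop("feed rates and concentrations must be >= 0")
  structure(list(mode = mode, r_lin = r_lin, mu_set = mu_set,
                 y_feed_per_biomass = y_feed_per_biomass,
                 c_glc_feed = c_glc_feed, density = density,
                 sulfate_free = sulfate_free),
            class = "feed_spec")
}

#' Volumetric feed rate
#'
#' Constant `r_lin` for a linear feed; `mu_set * x0v0 * y_feed_per_biomass *
#' exp(mu_set t)` for an exponential feed; zero for batch.
#'
#' @param t time since feed start, h (>= 0).
#' @param feed a [feed_spec()].
#' @param x0v0 biomass amount at feed start (g), required in exponential mode.
#' @return feed rate in L/h.
#' @export
feed_rate <- function(t, feed, x0v0 = NULL) {
  stopifnot(inherits(feed, "feed_spec"))
  if (any(t < 0)) stop("negative time")
  switch(feed$mode,
         linear = rep_len(feed$r_lin, length(t)),
         exponential = {
           if (is.null(x0v0)) stop("exponential feed needs the initial biomass amount x0v0")
           feed$mu_set * x0v0 * feed$y_feed_per_biomass * exp(feed$mu_set * t)
         },
         none = rep_len(0, length(t)))
}

#' Specific glucose uptake implied by the feed
#'
#' The fed-batch regime is designed so that residual glucose stays at zero:
#' the specific uptake rate equals the momentary glucose supply divided by
#' the biomass amount, `q_glc = r_feed * C_glc_feed / (C_biomass V)`,
#' converted to mmol gDW^-1 h^-1.
#'
#' @param t time, h.
#' @param feed a [feed_spec()].
#' @param biomass biomass amount `C_biomass V`, g (> 0).
#' @param x0v0 initial biomass amount (exponential mode).
#' @return specific glucose uptake, mmol gDW^-1 h^-1.
#' @export
specific_glucose_uptake <- function(t, feed, biomass, x0v0 = NULL) {
  if (any(biomass <= 0)) stop("biomass amount must be positive")
  feed_rate(t, feed, x0v0) * feed$c_glc_feed / MW_GLUCOSE * 1000 / biomass
}

#' Fed-batch process configuration
#'
#' Initial state and production parameters of the three-stage process
#' (growth fed-batch, then sulfate-starved production fed-batch). Defaults
#' follow a 1 L-scale linear fed-batch: 0.5 L starting volume containing
#' 1.51 g biomass, 0.5 L of feed, 36 h feed phase.
#'
#' @param v0,v_max initial and maximal volume, L.
#' @param c_biomass0 initial biomass concentration, g/L.
#' @param c_pdna0 initial plasmid concentration, g/L.
#' @param c_so4_0 initial sulfate concentration, g/L.
#' @param c_glc0 initial residual glucose, g/L (batch mode).
#' @param q_pdna_mu specific plasmid synthesis rate during growth,
#'   mg gDW^-1 h^-1.
#' @param kappa ratio of the starvation-phase to the growth-phase synthesis
#'   rate (`q* = kappa * q_mu`, dimensionless >= 1).
#' @param feed a [feed_spec()].
#' @param t_end simulation cap, h.
#' @param q_slope linear time drift of `q_pdna_mu`, mg gDW^-1 h^-2 (0 for the
#'   constant-rate model; the time-dependent variant clamps `q_mu(t) >= 0`).
#' @param q_star_offset if non-`NULL`, the starvation rate is
#'   `q_mu(t) + q_star_offset` (parallel-offset variant) instead of
#'   `kappa * q_mu(t)`.
#' @param production_cutoff duration (h) after starvation onset for which
#'   plasmid production is sustained; beyond it synthesis stops entirely
#'   (used for breakthrough analyses). `Inf` keeps production up throughout.
#' @return object of class `process_config`.
#' @export
process_config <- function(v0 = 0.5, v_max = 1.0,
                           c_biomass0 = 1.51 / 0.5, c_pdna0 = 0, c_so4_0 = 3.8,
                           c_glc0 = 0,
                           q_pdna_mu = 4.9, kappa = 2, feed = feed_spec(),
                           t_end = 36, q_slope = 0, q_star_offset = NULL,
                           production_cutoff = Inf) {
  if (v0 >= v_max) stop("v0 must be below v_max")
  if (kappa < 1) stop("kappa must be >= 1")
  if (any(c(c_biomass0, c_pdna0, c_so4_0, c_glc0) < 0))
    stop("concentrations must be >= 0")
  if (q_pdna_mu < 0) stop("q_pdna_mu must be >= 0")
  structure(list(v0 = v0, v_max = v_max, c_biomass0 = c_biomass0,
                 c_pdna0 = c_pdna0, c_so4_0 = c_so4_0, c_glc0 = c_glc0,
                 q_pdna_mu = q_pdna_mu, kappa = kappa, feed = feed,
                 t_end = t_end, q_slope = q_slope,
                 q_star_offset = q_star_offset,
                 production_cutoff = production_cutoff),
            class = "process_config")
}

# plasmid synthesis bounds (mg gDW^-1 h^-1) at time t, given starvation onset
pdna_rate_bounds <- function(config, t, t_switch = NA_real_) {
  qmu <- max(config$q_pdna_mu + config$q_slope * t, 0)
  qstar <- if (!is.null(config$q_star_offset)) qmu + config$q_star_offset
           else config$kappa * qmu
  if (!is.na(t_switch) && t > t_switch + config$production_cutoff)
    return(c(0, 0))
  c(qmu, max(qstar, qmu))
}

#' Lexicographic flux state of the fed-batch at one instant
#'
#' Applies the momentary constraints (glucose uptake fixed to the feed-implied
#' rate, sulfate exchange open while dissolved sulfate remains and blocked
#' once it is depleted, plasmid synthesis bounded between the growth-phase and
#' starvation-phase rates) and solves the staged objectives: maximize growth,
#' minimize sulfate uptake, maximize plasmid synthesis.
#'
#' During growth the plasmid flux sits at its lower bound; during starvation
#' growth is zero and the plasmid flux reaches its upper bound whenever the
#' carbon supply suffices. If fixing glucose uptake as an equality is
#' infeasible (carbon cannot be disposed of), the equality is relaxed to an
#' upper limit on uptake and a warning is issued.
#'
#' @param model plasmid-augmented `metabolic_model`.
#' @param q_glc specific glucose uptake to impose, mmol gDW^-1 h^-1.
#' @param sulfate_open logical; dissolved sulfate still present.
#' @param pdna_bounds plasmid synthesis bounds, mg gDW^-1 h^-1 (length 2).
#' @param mw plasmid molecular weight g/mol (defaults to the spec attached to
#'   the model).
#' @param sulfate_rxn,glucose_rxn exchange reaction ids.
#' @return list with `mu` (1/h), `q_so4` (uptake magnitude, mmol gDW^-1
#'   h^-1), `q_pdna` (mg gDW^-1 h^-1), `q_glc` (realized uptake), `fluxes`
#'   (full named vector), `relaxed` (logical).
#' @export
step_fluxes <- function(model, q_glc, sulfate_open, pdna_bounds,
                        mw = NULL,
                        sulfate_rxn = "EX_so4_e", glucose_rxn = "EX_glc_e") {
  spec <- attr(model, "plasmid_spec")
  syn <- attr(model, "pdna_synthesis_id")
  if (is.null(spec) || is.null(syn))
    stop("model has no plasmid pathway; run add_plasmid_pathway() first")
  if (is.null(mw)) mw <- spec$molecular_weight
  bounds_mmol <- pdna_bounds / mw
  m <- set_bounds(model, syn, lb = bounds_mmol[1], ub = bounds_mmol[2])
  m <- set_bounds(m, sulfate_rxn, lb = if (sulfate_open) -1000 else 0)
  m <- set_bounds(m, glucose_rxn, lb = -q_glc, ub = -q_glc)
  if (!is.null(m$ngam_id)) {    # maintenance held constant during the process
    ng <- get_bounds(m, m$ngam_id)
    m <- set_bounds(m, m$ngam_id, ub = ng$lb)
  }
  objs <- list(list(reaction = model$biomass_id, sense = "max"),
               list(reaction = sulfate_rxn, sense = "max"),
               list(reaction = syn, sense = "max"))
  sol <- tryCatch(lexicographic_fba(m, objs), error = function(e) NULL)
  relaxed <- FALSE
  if (is.null(sol)) {
    # carbon disposal impossible at forced uptake: allow residual glucose
    m <- set_bounds(m, glucose_rxn, lb = -q_glc, ub = 0)
    sol <- lexicographic_fba(m, objs)
    relaxed <- TRUE
    warning("glucose uptake equality infeasible; relaxed to an upper limit",
            call. = FALSE)
  }
  list(mu = unname(sol$fluxes[model$biomass_id]),
       q_so4 = unname(-sol$fluxes[sulfate_rxn]),
       q_pdna = unname(sol$fluxes[syn]) * mw,
       q_glc = unname(-sol$fluxes[glucose_rxn]),
       fluxes = sol$fluxes,
       relaxed = relaxed)
}

#' Simulate a sulfate-switched fed-batch by dynamic FBA
#'
#' Integrates the extracellular state (biomass, plasmid, sulfate, glucose,
#' volume, tracked secreted byproducts) with the flux state re-solved by
#' lexicographic FBA at every right-hand-side evaluation. State variables are
#' total amounts rather than concentrations, which removes dilution terms
#' from the balance equations; concentrations are derived on output. Sulfate
#' depletion is located by root-finding (the sulfate on/off rule is a
#' discontinuity that fixed steps would smear) and splits the integration
#' into a growth phase and a starvation phase. The run terminates when the
#' reactor volume reaches `v_max`, at `t_end`, or (batch mode) when glucose
#' is exhausted.
#'
#' @param model plasmid-augmented `metabolic_model`.
#' @param config a [process_config()].
#' @param n_out number of output grid points.
#' @param secretion_rxns exchange reactions whose secreted products are
#'   tracked as concentration columns (default acetate).
#' @return a `trajectory`: data.frame with columns `time`, `volume`,
#'   `c_biomass`, `c_pdna`, `c_so4`, `c_glc`, one `c_<met>` per tracked
#'   secretion, and instantaneous `mu`, `q_so4`, `q_pdna`, `q_glc`;
#'   attributes `t_switch` (h, `NA` if no starvation occurred), `t_end`,
#'   `termination`, and the config.
#' @export
simulate_fedbatch <- function(model, config, n_out = 121,
                              secretion_rxns = "EX_ac_e") {
  stopifnot(inherits(config, "process_config"))
  spec <- attr(model, "plasmid_spec")
  if (is.null(spec)) stop("model has no plasmid pathway")
  mw <- spec$molecular_weight
  feed <- config$feed
  x0v0 <- config$c_biomass0 * config$v0
  f_mmol <- feed$c_glc_feed / MW_GLUCOSE * 1000          # feed glucose mmol/L
  glc_cap <- -get_bounds(model, "EX_glc_e")$lb           # batch-mode uptake cap

  nsec <- length(secretion_rxns)
  y0 <- c(xv = x0v0,
          np = config$c_pdna0 * config$v0 * 1000,        # mg
          ns = config$c_so4_0 * config$v0 / MW_SULFATE * 1000,  # mmol
          v = config$v0,
          nglc = config$c_glc0 * config$v0 / MW_GLUCOSE * 1000, # mmol
          stats::setNames(numeric(nsec), paste0("sec", seq_len(nsec))))

  t_switch <- NA_real_
  relaxed_any <- FALSE

  rhs_factory <- function(sulfate_open, t_sw) {
    function(t, y, parms) {
      r <- feed_rate(t, feed, x0v0)
      if (feed$mode == "none") {
        q_glc <- if (y[["nglc"]] > 1e-9) glc_cap else 0
        if (q_glc == 0)    # substrate spent: culture is dormant, no LP needed
          return(list(c(0, 0, 0, r, 0, numeric(nsec)),
                      mu = 0, q_so4 = 0, q_pdna = 0, q_glc = 0))
      } else {
        q_glc <- r * f_mmol / y[["xv"]]
      }
      fl <- step_fluxes(model, q_glc, sulfate_open,
                        pdna_rate_bounds(config, t, t_sw), mw = mw)
      if (fl$relaxed) relaxed_any <<- TRUE
      sec <- vapply(secretion_rxns, function(rx) unname(fl$fluxes[rx]), 0)
      list(c(fl$mu * y[["xv"]],
             fl$q_pdna * y[["xv"]],
             -fl$q_so4 * y[["xv"]],
             r,
             r * f_mmol - fl$q_glc * y[["xv"]],
             sec * y[["xv"]]),
           mu = fl$mu, q_so4 = fl$q_so4, q_pdna = fl$q_pdna, q_glc = fl$q_glc)
    }
  }

  run_phase <- function(y0, t0, t1, sulfate_open, t_sw) {
    root <- function(t, y, parms) {
      c(if (sulfate_open) y[["ns"]] else 1,
        config$v_max - y[["v"]],
        if (feed$mode == "none") y[["nglc"]] + 1e-12 else 1)
    }
    times <- sort(unique(c(seq(t0, t1, length.out = max(
      3, ceiling((t1 - t0) / (config$t_end) * n_out))), t1)))
    deSolve::lsodar(y = y0, times = times, func = rhs_factory(sulfate_open, t_sw),
                    parms = NULL, rootfunc = root,
                    rtol = 1e-8, atol = 1e-8)
  }

  out1 <- run_phase(y0, 0, config$t_end, sulfate_open = TRUE, t_sw = NA_real_)
  tlast <- out1[nrow(out1), "time"]
  ylast <- out1[nrow(out1), names(y0)]
  segs <- list(out1)
  termination <- "t_end"

  root_hit <- !is.null(attr(out1, "troot")) && length(attr(out1, "troot")) > 0
  if (root_hit && ylast[["ns"]] <= max(1e-7, 1e-7 * y0[["ns"]]) &&
      ylast[["v"]] < config$v_max - 1e-9 && tlast < config$t_end - 1e-9) {
    # sulfate depleted: switch to starvation phase
    t_switch <- tlast
    ylast[["ns"]] <- 0
    out2 <- run_phase(ylast, tlast, config$t_end, sulfate_open = FALSE,
                      t_sw = t_switch)
    segs <- c(segs, list(out2[-1, , drop = FALSE]))
    tlast <- out2[nrow(out2), "time"]
    ylast <- out2[nrow(out2), names(y0)]
  }
  if (ylast[["v"]] >= config$v_max - 1e-6) termination <- "volume"
  else if (feed$mode == "none" && ylast[["nglc"]] <= 1e-9)
    termination <- "glucose_exhausted"

  tab <- do.call(rbind, lapply(segs, as.data.frame))
  traj <- data.frame(
    time = tab$time,
    volume = tab$v,
    c_biomass = tab$xv / tab$v,
    c_pdna = tab$np / tab$v / 1000,                     # g/L
    c_so4 = pmax(tab$ns, 0) * MW_SULFATE / 1000 / tab$v,
    c_glc = pmax(tab$nglc, 0) * MW_GLUCOSE / 1000 / tab$v,
    mu = tab$mu, q_so4 = tab$q_so4, q_pdna = tab$q_pdna, q_glc = tab$q_glc)
  for (i in seq_len(nsec)) {
    met <- sub("^EX_", "", secretion_rxns[i])
    traj[[paste0("c_", sub("_e$", "", met))]] <- tab[[paste0("sec", i)]] / tab$v
  }
  structure(traj, class = c("trajectory", "data.frame"),
            t_switch = unname(t_switch), t_end = unname(tlast),
            termination = termination, relaxed = relaxed_any, config = config)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d points, 0-%.2f h; switch at %s h; terminated by %s\n",
              nrow(x), attr(x, "t_end"),
              if (is.na(attr(x, "t_switch"))) "-" else
                sprintf("%.2f", attr(x, "t_switch")),
              attr(x, "termination")))
  print(utils::head(data.frame(x, check.names = FALSE), 3))
  invisible(x)
}
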