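#' Yield and productivity curves of a trajectory
#'
#' Specific yield `Y_pDNA/biomass(t) = C_pDNA(t)/C_biomass(t)` and average
#' volumetric productivity `p_pDNA(t) = (C_pDNA(t) - C_pDNA(0))/(t - t0)`
#' with `t0 = 0` (feed start). With no initial product the productivity
#' reduces to `C_pDNA(t)/t`. The productivity at `t = t0` is undefined and
#' reported as `NA`.
#'
#' @param trajectory a `trajectory` from [simulate_fedbatch()], or any
#'   data.frame with `time`, `c_biomass`, `c_pdna` columns.
#' @return data.frame with `time`, `yield` (g/g), `productivity` (g/L/h).
#' @export
performance <- function(trajectory) {
  t <- trajectory$time
  p0 <- trajectory$c_pdna[1]
  data.frame(
    time = t,
    yield = trajectory$c_pdna / trajectory$c_biomass,
    productivity = ifelse(t > 0, (trajectory$c_pdna - p0) / t, NA_real_))
}

#' Sulfate dose above which no starvation occurs
#'
#' The initial sulfate concentration that exactly covers the biomass growth
#' of the full (never-starved) feed phase: dosing more leaves the process
#' sulfate-replete throughout. Computed by simulating with sulfate in excess
#' and converting the final biomass gain through the biomass sulfate
#' coefficient.
#'
#' @param model plasmid-augmented `metabolic_model`.
#' @param config a [process_config()].
#' @return concentration in g/L (referred to the initial volume).
#' @export
so4_no_limitation <- function(model, config) {
  s_x <- -reaction_stoich(model, model$biomass_id)["so4_e"]
  if (is.na(s_x) || s_x <= 0) stop("biomass reaction has no sulfate requirement")
  cfg <- config
  cfg$c_so4_0 <- 1e6   # effectively unlimited
  tr <- simulate_fedbatch(model, cfg, n_out = 7)
  last <- tr[nrow(tr), ]
  dxv <- last$c_biomass * last$volume - config$c_biomass0 * config$v0
  unname(s_x * dxv * MW_SULFATE / 1000 / config$v0)
}

#' Productivity surface over kappa and initial sulfate dose
#'
#' Simulates the fed-batch for every combination of the production boost
#' `kappa` and the initial sulfate concentration, recording end-of-process
#' average volumetric productivity, specific yield, and starvation length
#' `t* = t_end - t_switch`. The sulfate grid spans (0, C_no-limitation] by
#' default; the reference design uses 41 kappa levels in \[1, 5\] and 301
#' sulfate steps. Scans are deterministic: repeated runs give identical
#' surfaces.
#'
#' @param model plasmid-augmented `metabolic_model`.
#' @param config a [process_config()] template (its `kappa` and `c_so4_0`
#'   are overridden cell-wise).
#' @param kappas vector of kappa levels.
#' @param so4_levels vector of initial sulfate concentrations (g/L); derived
#'   from `n_so4` when missing.
#' @param n_so4 number of equidistant sulfate steps when `so4_levels` is
#'   missing.
#' @param n_out output resolution per simulation (kept coarse in scans).
#' @return an `optimization_surface` data.frame with columns `kappa`,
#'   `c_so4_0`, `p_end`, `yield_end`, `t_star`, `t_switch`, `starved`,
#'   `error`; attribute `optima` is a per-kappa data.frame of the argmax
#'   rows.
#' @export
productivity_scan <- function(model, config, kappas = seq(1, 5, length.out = 41),
                              so4_levels = NULL, n_so4 = 301, n_out = 13) {
  if (is.null(so4_levels)) {
    cmax <- so4_no_limitation(model, config)
    so4_levels <- seq(cmax / n_so4, cmax, length.out = n_so4)
  }
  grid <- expand.grid(kappa = kappas, c_so4_0 = so4_levels,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$kappa <- grid$kappa[i]
    cfg$c_so4_0 <- grid$c_so4_0[i]
    tr <- tryCatch(simulate_fedbatch(model, cfg, n_out = n_out),
                   error = function(e) e)
    if (inherits(tr, "error"))
      return(data.frame(kappa = cfg$kappa, c_so4_0 = cfg$c_so4_0,
                        p_end = NA_real_, yield_end = NA_real_,
                        t_star = NA_real_, t_switch = NA_real_,
                        starved = NA, error = conditionMessage(tr)))
    last <- tr[nrow(tr), ]
    tsw <- attr(tr, "t_switch")
    data.frame(kappa = cfg$kappa, c_so4_0 = cfg$c_so4_0,
               p_end = last$c_pdna / last$time,
               yield_end = last$c_pdna / last$c_biomass,
               t_star = if (is.na(tsw)) 0 else last$time - tsw,
               t_switch = tsw, starved = !is.na(tsw), error = NA_character_)
  })
  surf <- do.call(rbind, rows)
  rownames(surf) <- NULL
  ok <- !is.na(surf$p_end)
  optima <- do.call(rbind, lapply(split(surf[ok, ], surf$kappa[ok]), function(d)
    d[which.max(d$p_end), ]))
  rownames(optima) <- NULL
  structure(surf, class = c("optimization_surface", "data.frame"),
            optima = optima)
}

#' Per-kappa optimum under a bounded starvation length
#'
#' Restricts the argmax of a productivity surface to cells whose starvation
#' phase does not exceed `t_star_max` (elevated production sustained only so
#' long being realistic). With an unbounded limit this equals the
#' unrestricted optimum; with `t_star_max = 0` it is the non-starved control.
#'
#' @param surface an `optimization_surface` from [productivity_scan()].
#' @param t_star_max maximal admissible starvation length, h.
#' @return data.frame of per-kappa optimum rows.
#' @export
bounded_starvation_optimum <- function(surface, t_star_max) {
  stopifnot(t_star_max >= 0)
  ok <- !is.na(surface$p_end) & surface$t_star <= t_star_max + 1e-12
  d <- surface[ok, ]
  out <- do.call(rbind, lapply(split(d, d$kappa), function(g)
    g[which.max(g$p_end), ]))
  rownames(out) <- NULL
  out
}

#' Optimal sulfate dose for one kappa
#'
#' Continuous search (golden-section via [stats::optimize()]) of the initial
#' sulfate concentration maximizing end-of-process productivity.
#'
#' @param model plasmid-augmented `metabolic_model`.
#' @param config a [process_config()].
#' @param kappa production boost during starvation.
#' @param so4_max upper end of the search interval (defaults to the
#'   no-limitation dose).
#' @param tol absolute tolerance on the dose, g/L.
#' @return list with `c_so4_0`, `p_end`, `t_star`, `t_switch`.
#' @export
optimal_so4_dose <- function(model, config, kappa = config$kappa,
                             so4_max = NULL, tol = 0.02) {
  cfg <- config
  cfg$kappa <- kappa
  if (is.null(so4_max)) so4_max <- so4_no_limitation(model, cfg)
  evalp <- function(c0) {
    cfg$c_so4_0 <- c0
    tr <- simulate_fedbatch(model, cfg, n_out = 7)
    last <- tr[nrow(tr), ]
    list(p = last$c_pdna / last$time, tr = tr)
  }
  op <- stats::optimize(function(c0) evalp(c0)$p, c(1e-6, so4_max),
                        maximum = TRUE, tol = tol)
  best <- evalp(op$maximum)
  tsw <- attr(best$tr, "t_switch")
  list(c_so4_0 = op$maximum, p_end = best$p,
       t_star = if (is.na(tsw)) 0 else attr(best$tr, "t_end") - tsw,
       t_switch = tsw)
}

#' Breakthrough production length
#'
#' The minimal duration for which elevated plasmid production must be
#' sustained after starvation onset so that the starved process performs at
#' least as well as a never-starved control. Production is assumed to stop
#' entirely once the sustained window ends (the conservative reading); the
#' control runs the same feed with sulfate in excess and the growth-phase
#' synthesis rate throughout. The starvation onset is set by the
#' kappa-optimal sulfate dose.
#'
#' @param model plasmid-augmented `metabolic_model`.
#' @param config a [process_config()].
#' @param kappa production boost (> 1; at `kappa = 1` starving cannot beat
#'   the control and the length is undefined).
#' @param dose optional result of [optimal_so4_dose()] to reuse.
#' @param tol root tolerance, h.
#' @return list with `t_breakthrough` (h; `NA` if even full-length production
#'   never reaches the control), `t_star`, `p_control`, `c_so4_0`.
#' @export
breakthrough_length <- function(model, config, kappa, dose = NULL, tol = 0.02) {
  if (kappa <= 1) stop("breakthrough length is undefined for kappa <= 1")
  cfg <- config
  cfg$kappa <- kappa
  if (is.null(dose)) dose <- optimal_so4_dose(model, cfg)
  ctrl_cfg <- cfg
  ctrl_cfg$c_so4_0 <- 1e6
  ctrl <- simulate_fedbatch(model, ctrl_cfg, n_out = 7)
  p_ctrl <- ctrl$c_pdna[nrow(ctrl)] / ctrl$time[nrow(ctrl)]

  p_at <- function(tb) {
    cfg$c_so4_0 <- dose$c_so4_0
    cfg$production_cutoff <- tb
    tr <- simulate_fedbatch(model, cfg, n_out = 7)
    tr$c_pdna[nrow(tr)] / tr$time[nrow(tr)]
  }
  f <- function(tb) p_at(tb) - p_ctrl
  if (f(dose$t_star) < 0)
    return(list(t_breakthrough = NA_real_, t_star = dose$t_star,
                p_control = p_ctrl, c_so4_0 = dose$c_so4_0))
  root <- stats::uniroot(f, c(0, dose$t_star), tol = tol)
  list(t_breakthrough = root$root, t_star = dose$t_star,
       p_control = p_ctrl, c_so4_0 = dose$c_so4_0)
}

#' Productivity scan with a time-dependent synthesis rate
#'
#' Variant of [productivity_scan()] in which the growth-phase synthesis rate
#' drifts linearly, `q_mu(t) = q0 + slope * t` (clamped at zero), and the
#' starvation-phase rate runs parallel at `q_mu(t) + offset`. With
#' `slope = 0` and `offset = (kappa - 1) * q0` this reduces exactly to the
#' constant-rate scan at that kappa.
#'
#' @param model plasmid-augmented `metabolic_model`.
#' @param config a [process_config()] template.
#' @param q0 growth-phase rate at feed start, mg gDW^-1 h^-1.
#' @param slope drift, mg gDW^-1 h^-2 (negative for decaying production).
#' @param offset additive starvation boost, mg gDW^-1 h^-1 (>= 0).
#' @param so4_levels,n_so4,n_out as in [productivity_scan()].
#' @return an `optimization_surface` (single kappa row labelled by the
#'   equivalent kappa at `t = 0`).
#' @export
time_dependent_q_scan <- function(model, config, q0, slope, offset,
                                  so4_levels = NULL, n_so4 = 31, n_out = 13) {
  stopifnot(q0 > 0, offset >= 0)
  cfg <- config
  cfg$q_pdna_mu <- q0
  cfg$q_slope <- slope
  cfg$q_star_offset <- offset
  cfg$kappa <- 1 + offset / q0
  productivity_scan(model, cfg, kappas = cfg$kappa,
                    so4_levels = so4_levels, n_so4 = n_so4, n_out = n_out)
}
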