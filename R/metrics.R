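N_AVOGADRO <- 6.02214076e23

#' Read a bioprocess measurement series from CSV
#'
#' Expected columns: `t_h`, `cdm_g_per_L`, `pdna_mg_per_L`, and optionally
#' `ccc_fraction`, `volume_L`, `replicate`, `arm`. Missing optional columns
#' are filled with defaults (volume 1 L, replicate 1, arm `"CTRL"`).
#'
#' @param path CSV file path.
#' @return validated measurement data.frame.
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(d)
}

#' Validate a measurement series
#'
#' Checks the schema and invariants: strictly increasing time within each
#' replicate/arm, non-negative concentrations, supercoiled (ccc) fraction in
#' \[0, 1\].
#'
#' @param d data.frame with at least `t_h`, `cdm_g_per_L`, `pdna_mg_per_L`.
#' @return the completed data.frame.
#' @export
validate_measurements <- function(d) {
  need <- c("t_h", "cdm_g_per_L", "pdna_mg_per_L")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(d$ccc_fraction)) d$ccc_fraction <- NA_real_
  if (is.null(d$volume_L)) d$volume_L <- 1
  if (is.null(d$replicate)) d$replicate <- 1L
  if (is.null(d$arm)) d$arm <- "CTRL"
  if (any(d$cdm_g_per_L < 0, na.rm = TRUE) || any(d$pdna_mg_per_L < 0, na.rm = TRUE))
    stop("negative concentrations")
  if (any(d$ccc_fraction < 0 | d$ccc_fraction > 1, na.rm = TRUE))
    stop("ccc_fraction outside [0, 1]")
  for (key in split(seq_len(nrow(d)), interaction(d$arm, d$replicate, drop = TRUE)))
    if (any(diff(d$t_h[key]) <= 0))
      stop("time must be strictly increasing within each replicate")
  d
}

#' Specific yield and average volumetric productivity of measured series
#'
#' Pointwise specific yield `Y = C_pDNA/C_CDM` (mg/g) and average volumetric
#' productivity `p = (C_pDNA(t) - C_pDNA(0))/t` (mg/L/h, t0 = 0 at feed
#' start; undefined at t = 0). With `ccc_only = TRUE` the plasmid
#' concentration is first multiplied by the supercoiled fraction.
#'
#' @param d measurement data.frame (see [validate_measurements()]).
#' @param ccc_only restrict to the supercoiled conformation.
#' @return input with `yield_mg_g` and `productivity_mg_L_h` columns added.
#' @export
yields_and_productivity <- function(d, ccc_only = FALSE) {
  d <- validate_measurements(d)
  pdna <- if (ccc_only) d$pdna_mg_per_L * d$ccc_fraction else d$pdna_mg_per_L
  d$yield_mg_g <- ifelse(d$cdm_g_per_L > 0, pdna / d$cdm_g_per_L, NA_real_)
  d$productivity_mg_L_h <- NA_real_
  for (key in split(seq_len(nrow(d)), interaction(d$arm, d$replicate, drop = TRUE))) {
    p0 <- if (min(d$t_h[key]) <= 0) pdna[key][which.min(d$t_h[key])] else 0
    d$productivity_mg_L_h[key] <- ifelse(d$t_h[key] > 0,
                                         (pdna[key] - p0) / d$t_h[key], NA_real_)
  }
  d
}

# second-order finite-difference derivative on a possibly non-uniform grid:
# three-point Lagrange stencils, one-sided at the ends
fd_derivative <- function(t, y) {
  n <- length(t)
  if (n < 3) stop("need at least 3 time points for a second-order derivative")
  dy <- numeric(n)
  for (i in seq_len(n)) {
    k <- if (i == 1) 1:3 else if (i == n) (n - 2):n else (i - 1):(i + 1)
    t0 <- t[k[1]]; t1 <- t[k[2]]; t2 <- t[k[3]]
    ti <- t[i]
    w0 <- (2 * ti - t1 - t2) / ((t0 - t1) * (t0 - t2))
    w1 <- (2 * ti - t0 - t2) / ((t1 - t0) * (t1 - t2))
    w2 <- (2 * ti - t0 - t1) / ((t2 - t0) * (t2 - t1))
    dy[i] <- w0 * y[k[1]] + w1 * y[k[2]] + w2 * y[k[3]]
  }
  dy
}

#' Finite-difference estimate of the specific plasmid synthesis rate
#'
#' `q_pDNA(t) = d(C_pDNA V)/dt / (C_CDM V)`: the derivative is taken on
#' amounts rather than concentrations because sampling during the feed phase
#' changes the volume. Second-order three-point stencils on the (possibly
#' non-uniform) time grid, one-sided at the endpoints.
#'
#' @param d measurement data.frame (>= 3 time points per replicate).
#' @param ccc_only restrict to the supercoiled conformation.
#' @return input with a `q_pdna_mg_g_h` column added.
#' @export
rate_estimate <- function(d, ccc_only = FALSE) {
  d <- validate_measurements(d)
  pdna <- if (ccc_only) d$pdna_mg_per_L * d$ccc_fraction else d$pdna_mg_per_L
  d$q_pdna_mg_g_h <- NA_real_
  for (key in split(seq_len(nrow(d)), interaction(d$arm, d$replicate, drop = TRUE))) {
    amt <- pdna[key] * d$volume_L[key]
    d$q_pdna_mg_g_h[key] <- fd_derivative(d$t_h[key], amt) /
      (d$cdm_g_per_L[key] * d$volume_L[key])
  }
  d
}

#' Plasmid copy number from a specific yield
#'
#' `PCN = Y * m_cell / (MW / N_A)` with the plasmid molecular weight derived
#' from length and GC content via [plasmid_mw()]. The customary convention
#' for E. coli is a cell mass of 110 fg and an assumed 50% GC.
#'
#' @param specific_yield specific plasmid yield, mg per g CDM.
#' @param plasmid_bp plasmid length, bp.
#' @param gc_fraction GC content.
#' @param cell_mass_fg single-cell dry mass, fg.
#' @return plasmids per cell.
#' @export
copy_number <- function(specific_yield, plasmid_bp, gc_fraction = 0.5,
                        cell_mass_fg = 110) {
  stopifnot(specific_yield >= 0, plasmid_bp >= 1, cell_mass_fg > 0)
  mw <- plasmid_mw(dntp_counts(plasmid_bp, gc_fraction))
  (specific_yield / 1000) * (cell_mass_fg * 1e-15) / (mw / N_AVOGADRO)
}

#' Compare a limited and a control process arm
#'
#' Percent improvements of the specific yield, volumetric productivity, and
#' plasmid concentration at one evaluation time, with one-sided two-sample
#' t-tests across replicates (the alternative being that the limited arm is
#' higher). Improvements are invariant to a common rescaling of both arms.
#'
#' @param d measurement data.frame containing both arms.
#' @param t_eval evaluation time (must be sampled in both arms).
#' @param arm_test,arm_ref arm labels (test vs reference).
#' @param var_equal Student's pooled-variance t-test (default); `FALSE` for
#'   Welch.
#' @param ccc_only restrict to the supercoiled conformation.
#' @return data.frame with one row per metric: means of both arms, percent
#'   improvement, and the one-sided p-value (`NA` with fewer than two
#'   replicates in either arm).
#' @export
compare_arms <- function(d, t_eval, arm_test = "SLIM", arm_ref = "CTRL",
                         var_equal = TRUE, ccc_only = FALSE) {
  d <- yields_and_productivity(d, ccc_only = ccc_only)
  at <- d[abs(d$t_h - t_eval) < 1e-9, ]
  for (a in c(arm_test, arm_ref))
    if (!any(at$arm == a)) stop("arm not sampled at t_eval: ", a)
  metrics <- c(yield_mg_g = "yield_mg_g",
               productivity_mg_L_h = "productivity_mg_L_h",
               pdna_mg_per_L = "pdna_mg_per_L")
  rows <- lapply(names(metrics), function(nm) {
    x <- at[[metrics[[nm]]]][at$arm == arm_test]
    y <- at[[metrics[[nm]]]][at$arm == arm_ref]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    pval <- if (length(x) >= 2 && length(y) >= 2)
      tryCatch(stats::t.test(x, y, alternative = "greater",
                             var.equal = var_equal)$p.value,
               error = function(e) NA_real_)    # zero-variance degenerate data
    else NA_real_
    data.frame(metric = nm, mean_test = mean(x), mean_ref = mean(y),
               improvement_pct = 100 * (mean(x) / mean(y) - 1),
               p_value = pval)
  })
  do.call(rbind, rows)
}
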