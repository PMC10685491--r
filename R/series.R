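#' Generate synthetic measurement series from a trajectory
#'
#' Samples a simulated (or closed-form) trajectory at given times and applies
#' multiplicative lognormal noise — concentrations are positive and assay
#' replicates typically show a coefficient of variation below 10% — to
#' produce replicate measurement series in the standard schema. Noise is
#' mean-preserving (`meanlog` shifted by `-sdlog^2/2`) and seeded for
#' reproducibility; the caller's random state is restored on exit.
#'
#' @param trajectory a `trajectory` from [simulate_fedbatch()] or a
#'   data.frame with `time`, `c_biomass`, `c_pdna`, `volume` columns.
#' @param times sampling times, h (within the trajectory range).
#' @param cv coefficient of variation of the multiplicative noise (0 =
#'   noiseless).
#' @param n_replicates number of replicates.
#' @param arm arm label (`"SLIM"`/`"CTRL"`).
#' @param seed integer seed.
#' @param ccc_fraction optional supercoiled fraction carried into the series
#'   (constant or one value per sampling time).
#' @return measurement data.frame (see [validate_measurements()]).
#' @export
make_series <- function(trajectory, times, cv = 0.1, n_replicates = 3,
                        arm = "CTRL", seed = 1, ccc_fraction = NA_real_) {
  stopifnot(cv >= 0, n_replicates >= 1)
  if (any(times < min(trajectory$time) - 1e-9) ||
      any(times > max(trajectory$time) + 1e-9))
    stop("sampling times outside the trajectory range")
  cdm <- stats::approx(trajectory$time, trajectory$c_biomass, times)$y
  pdna <- stats::approx(trajectory$time, trajectory$c_pdna, times)$y * 1000  # mg/L
  vol <- stats::approx(trajectory$time, trajectory$volume, times)$y
  ccc <- rep_len(ccc_fraction, length(times))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  noisy <- function(x) {
    if (cv == 0) return(x)
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  reps <- lapply(seq_len(n_replicates), function(r)
    data.frame(t_h = times,
               cdm_g_per_L = noisy(cdm),
               pdna_mg_per_L = noisy(pdna),
               ccc_fraction = ccc,
               volume_L = vol,
               replicate = r,
               arm = arm))
  validate_measurements(do.call(rbind, reps))
}
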