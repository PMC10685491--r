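# two-arm series derived from the published end-point summary of a
# sulfate-limited versus control fed-batch (values in mg/L and mg/g at 31 h)
table2_series <- function() {
  rbind(
    data.frame(t_h = c(0, 31), cdm_g_per_L = c(1.51 / 0.5, 2528 / 57.1),
               pdna_mg_per_L = c(0, 2528), replicate = 1, arm = "CTRL"),
    data.frame(t_h = c(0, 31), cdm_g_per_L = c(1.51 / 0.5, 2788 / 73.9),
               pdna_mg_per_L = c(0, 2788), replicate = 1, arm = "SLIM"))
}

test_that("specific yield and productivity reproduce the published summary row", {
  d <- yields_and_productivity(table2_series())
  ctrl <- d[d$arm == "CTRL" & d$t_h == 31, ]
  slim <- d[d$arm == "SLIM" & d$t_h == 31, ]
  expect_equal(ctrl$yield_mg_g, 57.1, tolerance = 1e-9)
  # the control yield and concentration imply the reported biomass density
  expect_equal(2528 / 57.1, 44.2, tolerance = 0.005)
  expect_equal(ctrl$productivity_mg_L_h, 2528 / 31, tolerance = 1e-9)
  expect_equal(slim$productivity_mg_L_h, 2788 / 31, tolerance = 1e-9)
  # constant concentrations give a constant yield
  flat <- data.frame(t_h = 1:5, cdm_g_per_L = 10, pdna_mg_per_L = 500)
  expect_equal(unique(yields_and_productivity(flat)$yield_mg_g), 50)
})

test_that("metrics on noiseless synthetic series invert the generator", {
  tr <- default_traj()
  times <- tr$time[seq(6, 56, by = 5)]      # exact trajectory grid points
  s <- make_series(tr, times, cv = 0, n_replicates = 1)
  got <- yields_and_productivity(s)
  idx <- match(times, tr$time)
  expect_equal(got$yield_mg_g, 1000 * tr$c_pdna[idx] / tr$c_biomass[idx],
               tolerance = 1e-9)
  expect_equal(got$productivity_mg_L_h, 1000 * tr$c_pdna[idx] / tr$time[idx],
               tolerance = 1e-9)
})

test_that("the finite-difference rate recovers the generating synthesis rate", {
  # exactly quadratic amounts: second-order stencils are exact
  t <- c(0, 1, 2.5, 4, 6)
  d <- data.frame(t_h = t, cdm_g_per_L = 2, pdna_mg_per_L = 3 * t + 0.5 * t^2,
                  volume_L = 1)
  q <- rate_estimate(d)$q_pdna_mg_g_h
  expect_equal(q, (3 + t) / 2, tolerance = 1e-10)
  # constant-rate series: q constant
  d2 <- data.frame(t_h = 0:4, cdm_g_per_L = 5, pdna_mg_per_L = 10 * (0:4))
  expect_equal(rate_estimate(d2)$q_pdna_mg_g_h, rep(2, 5))
  expect_error(rate_estimate(d2[1:2, ]), "3 time points")

  # on closed-form growth-phase data the error shrinks as O(dt^2)
  cf <- closed_form_linear()
  cfg <- cf$cfg
  err_at <- function(dt) {
    times <- seq(2, 20, by = dt)
    vol <- cfg$v0 + cfg$feed$r_lin * times
    s <- data.frame(t_h = times,
                    cdm_g_per_L = vapply(times, cf$XV, 0) / vol,
                    pdna_mg_per_L = vapply(times, cf$np, 0) / vol,
                    volume_L = vol)
    q <- rate_estimate(s)$q_pdna_mg_g_h
    max(abs(q - 4.9))
  }
  e2 <- err_at(2); e1 <- err_at(1)
  expect_lt(e1, e2 / 2)    # at least first-order gain on a curved signal
  expect_lt(e1, 0.05)      # 1% of the generating rate
})

test_that("copy number follows the mass-per-cell conversion", {
  expect_equal(copy_number(57.1, 12000), 510, tolerance = 1 / 510)
  expect_equal(copy_number(73.9, 12000), 660, tolerance = 1 / 660)
  expect_equal(copy_number(0, 12000), 0)
  # linear in yield, inverse in plasmid length
  expect_equal(copy_number(20, 6000), 2 * copy_number(10, 6000))
  expect_equal(copy_number(10, 6000), 2 * copy_number(10, 12000),
               tolerance = 1e-12)
})

test_that("arm comparison reports the published improvements", {
  cmp <- compare_arms(table2_series(), 31)
  expect_equal(cmp$improvement_pct[cmp$metric == "yield_mg_g"], 29,
               tolerance = 1 / 29)
  expect_equal(cmp$improvement_pct[cmp$metric == "productivity_mg_L_h"], 10,
               tolerance = 0.05)
  expect_true(all(is.na(cmp$p_value)))   # single replicates: no test
  # identical arms: no improvement, p = 0.5 under the one-sided test
  base <- table2_series()
  both <- rbind(base[base$arm == "CTRL", ],
                transform(base[base$arm == "CTRL", ], arm = "SLIM"))
  both <- rbind(transform(both, replicate = 1), transform(both, replicate = 2),
                transform(both, replicate = 3))
  both$cdm_g_per_L <- both$cdm_g_per_L * (1 + 0.001 * both$replicate)
  both$pdna_mg_per_L <- both$pdna_mg_per_L * (1 + 0.002 * both$replicate)
  cmp2 <- compare_arms(both, 31)
  expect_equal(cmp2$improvement_pct, rep(0, 3), tolerance = 1e-9)
  expect_equal(cmp2$p_value[!is.na(cmp2$p_value)][1], 0.5, tolerance = 1e-6)
  # improvements are invariant to a common rescaling of both arms
  scaled <- table2_series()
  scaled$pdna_mg_per_L <- scaled$pdna_mg_per_L * 3.7
  expect_equal(compare_arms(scaled, 31)$improvement_pct,
               cmp$improvement_pct, tolerance = 1e-9)
})

test_that("noisy replicate sets recover the generating improvement", {
  tr_slim <- default_traj()
  tr_ctrl <- cached("traj_ctrl", function()
    simulate_fedbatch(minisulf_pdna(), process_config(c_so4_0 = 100), n_out = 31))
  times <- seq(4, 34, by = 6)
  truth <- 100 * (stats::approx(tr_slim$time, tr_slim$c_pdna / tr_slim$c_biomass, 34)$y /
                  stats::approx(tr_ctrl$time, tr_ctrl$c_pdna / tr_ctrl$c_biomass, 34)$y - 1)
  d <- rbind(make_series(tr_slim, times, cv = 0.08, n_replicates = 6,
                         arm = "SLIM", seed = 41),
             make_series(tr_ctrl, times, cv = 0.08, n_replicates = 3,
                         arm = "CTRL", seed = 42))
  cmp <- compare_arms(d, 34)
  est <- cmp$improvement_pct[cmp$metric == "yield_mg_g"]
  # within ~3 relative standard errors of the generating contrast
  se_pct <- 100 * 0.08 * sqrt(1 / 6 + 1 / 3) * sqrt(2)
  expect_lt(abs(est - truth), 3 * se_pct)
  expect_true(cmp$p_value[cmp$metric == "yield_mg_g"] >= 0 &&
                cmp$p_value[cmp$metric == "yield_mg_g"] <= 1)
})

test_that("measurement validation catches schema and invariant violations", {
  good <- table2_series()
  expect_silent(validate_measurements(good))
  expect_error(validate_measurements(good[, -2]), "missing column")
  bad <- good; bad$t_h[2] <- 0
  expect_error(validate_measurements(bad), "strictly increasing")
  neg <- good; neg$pdna_mg_per_L[1] <- -1
  expect_error(validate_measurements(neg), "negative")
  frac <- good; frac$ccc_fraction <- 1.2
  expect_error(validate_measurements(frac), "ccc_fraction")
  # CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(good, path, row.names = FALSE)
  expect_equal(read_measurements(path)$pdna_mg_per_L, good$pdna_mg_per_L)
})
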