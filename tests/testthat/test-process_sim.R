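test_that("feed laws reproduce their defining arithmetic", {
  lin <- feed_spec("linear", r_lin = 0.01391)
  expect_equal(feed_rate(c(0, 10, 35), lin), rep(0.01391, 3))
  # time to feed 0.5 L at 13.91 mL/h
  expect_equal(0.5 / feed_rate(0, lin), 35.94, tolerance = 1e-3)
  ex <- feed_spec("exponential", mu_set = 0.25, y_feed_per_biomass = 0.0103)
  expect_equal(feed_rate(0, ex, x0v0 = 1.51), 0.25 * 1.51 * 0.0103)
  expect_equal(feed_rate(4, ex, x0v0 = 1.51),
               0.25 * 1.51 * 0.0103 * exp(0.25 * 4))
  expect_equal(feed_rate(5, feed_spec("none")), 0)
  expect_error(feed_rate(-1, lin), "negative")
})

test_that("the feed-implied glucose uptake follows its defining ratio", {
  lin <- feed_spec("linear", r_lin = 0.01391, c_glc_feed = 320)
  q <- specific_glucose_uptake(0, lin, biomass = 1.51)
  expect_equal(q, 0.01391 * 320 / 180.156 * 1000 / 1.51, tolerance = 1e-12)
  expect_equal(q, 16.4, tolerance = 0.005)
  # inverse proportionality to biomass
  expect_equal(specific_glucose_uptake(0, lin, biomass = 3.02), q / 2)
  expect_equal(specific_glucose_uptake(3, feed_spec("none"), biomass = 2), 0)
  expect_error(specific_glucose_uptake(0, lin, biomass = 0), "positive")
})

test_that("instantaneous fluxes switch from growth to production mode", {
  m <- minisulf_pdna()
  spec <- minisulf_spec()
  tru <- minisulf_truth()
  kap <- 2
  q_glc <- 5
  grown <- step_fluxes(m, q_glc, sulfate_open = TRUE, pdna_bounds = c(4.9, 4.9 * kap))
  q_mu_mmol <- 4.9 / plasmid_spec()$molecular_weight
  mu_expect <- (q_glc - spec$g_m - tru$a_glc * q_mu_mmol) / spec$g_x
  expect_equal(grown$mu, mu_expect, tolerance = 1e-5)
  expect_equal(grown$q_so4, spec$s_x * mu_expect, tolerance = 1e-4)
  expect_equal(grown$q_pdna, 4.9, tolerance = 2e-3)  # objective-fixing slack

  starved <- step_fluxes(m, q_glc, sulfate_open = FALSE, pdna_bounds = c(4.9, 4.9 * kap))
  expect_lt(abs(starved$mu), 1e-5)
  expect_lt(abs(starved$q_so4), 1e-5)
  expect_equal(starved$q_pdna, 4.9 * kap, tolerance = 1e-4)

  # kappa = 1: identical production in both phases
  g1 <- step_fluxes(m, q_glc, TRUE, c(4.9, 4.9))
  s1 <- step_fluxes(m, q_glc, FALSE, c(4.9, 4.9))
  expect_equal(g1$q_pdna, s1$q_pdna, tolerance = 1e-6)
})

test_that("the simulated fed-batch matches the exact closed form to within 0.1%", {
  tr <- default_traj()
  cf <- closed_form_linear()
  expect_equal(attr(tr, "t_switch"), cf$t_switch, tolerance = 1e-3)
  expect_equal(attr(tr, "t_end"), cf$t_end, tolerance = 1e-6)
  expect_equal(attr(tr, "termination"), "volume")
  # biomass and plasmid curves
  xv_sim <- tr$c_biomass * tr$volume
  np_sim <- tr$c_pdna * tr$volume * 1000
  xv_cf <- vapply(tr$time, function(t) cf$XV(min(t, cf$t_switch)), 0)
  np_cf <- vapply(tr$time, cf$np, 0)
  expect_lt(max(abs(xv_sim - xv_cf) / xv_cf), 1e-3)
  expect_lt(max(abs(np_sim[-1] - np_cf[-1]) / np_cf[-1]), 1e-3)
  # volume exactness at termination
  expect_lt(abs(tr$volume[nrow(tr)] - 1.0), 1e-6)
})

test_that("trajectory invariants hold: sulfur balance, dilution, residual glucose", {
  tr <- default_traj()
  spec <- minisulf_spec()
  cfg <- attr(tr, "config")
  ns <- tr$c_so4 * tr$volume / 96.06 * 1000
  xv <- tr$c_biomass * tr$volume
  # sulfur conservation during growth
  grow <- tr$time < attr(tr, "t_switch") - 1e-6 & tr$time > 0
  lhs <- ns[1] - ns[grow]
  rhs <- spec$s_x * (xv[grow] - xv[1])
  expect_lt(max(abs(lhs - rhs) / pmax(rhs, 1e-9)), 1e-3)
  # volume is the integral of the feed
  expect_equal(tr$volume, cfg$v0 + cfg$feed$r_lin * tr$time, tolerance = 1e-9)
  # biomass amount constant, concentration strictly diluted during starvation
  starve <- tr$time > attr(tr, "t_switch") + 1e-6
  expect_lt(diff(range(xv[starve])) / mean(xv[starve]), 1e-5)
  expect_true(all(diff(tr$c_biomass[starve]) < 0))
  # residual glucose stays at zero while feeding
  expect_lt(max(tr$c_glc), 1e-6)
  # sulfate never negative
  expect_true(all(tr$c_so4 >= -1e-12))
})

test_that("a sulfate dose above the no-limitation threshold never starves", {
  m <- minisulf_pdna()
  cmax <- cached("so4max", function() so4_no_limitation(m, process_config()))
  tr <- simulate_fedbatch(m, process_config(c_so4_0 = cmax * 1.05), n_out = 7)
  expect_true(is.na(attr(tr, "t_switch")))
  expect_gt(min(tr$c_so4), 0)
  tr2 <- simulate_fedbatch(m, process_config(c_so4_0 = cmax * 0.8), n_out = 7)
  expect_false(is.na(attr(tr2, "t_switch")))
})

test_that("batch mode runs on an initial glucose pool and stops when it is spent", {
  m <- minisulf_pdna()
  cfg <- process_config(c_glc0 = 10, c_so4_0 = 0.1, t_end = 24,
                        feed = feed_spec("none"))
  tr <- simulate_fedbatch(m, cfg, n_out = 31)
  expect_equal(attr(tr, "termination"), "glucose_exhausted")
  expect_false(is.na(attr(tr, "t_switch")))   # small dose starves first
  expect_equal(max(tr$volume), cfg$v0)        # no feed, no volume change
  expect_lt(tr$c_glc[nrow(tr)], 1e-6)
})
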