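# a shared coarse scan (kappa 1 and 2, 9 sulfate levels) reused across tests
coarse_scan <- function() cached("scan", function()
  productivity_scan(minisulf_pdna(), process_config(), kappas = c(1, 2),
                    n_so4 = 9, n_out = 7))

test_that("yield and productivity curves follow their definitions", {
  tr <- default_traj()
  perf <- performance(tr)
  expect_true(is.na(perf$productivity[1]))
  expect_equal(perf$yield, tr$c_pdna / tr$c_biomass)
  # with no initial product, productivity is concentration over time
  expect_equal(perf$productivity[-1], tr$c_pdna[-1] / tr$time[-1])
  # a linearly accumulating product gives a constant productivity
  lin <- data.frame(time = 0:10, c_biomass = 5, c_pdna = 0.3 * (0:10))
  expect_equal(performance(lin)$productivity[-1], rep(0.3, 10))
})

test_that("the productivity scan finds the closed-form optimum within one grid cell", {
  surf <- coarse_scan()
  opt <- attr(surf, "optima")
  cf <- closed_form_linear()
  # kappa = 1: production is phase-independent, so not starving is best
  expect_lt(opt$t_star[opt$kappa == 1], surf$t_star[surf$kappa == 1][1] + 1e-6)
  expect_equal(opt$c_so4_0[opt$kappa == 1], max(surf$c_so4_0))
  # kappa = 2: optimum dose within one grid step of the closed-form argmax
  ts_opt <- stats::optimize(function(ts) cf$np_end_at(ts, 2),
                            c(0, cf$t_end), maximum = TRUE)$maximum
  dose_opt <- cf$dose_for_ts(ts_opt)
  cell <- diff(sort(unique(surf$c_so4_0)))[1]
  expect_lt(abs(opt$c_so4_0[opt$kappa == 2] - dose_opt), cell + 1e-9)
  # optimal productivity non-decreasing in kappa
  expect_gte(opt$p_end[opt$kappa == 2], opt$p_end[opt$kappa == 1] - 1e-9)
})

test_that("scans are deterministic", {
  s1 <- productivity_scan(minisulf_pdna(), process_config(), kappas = 2,
                          so4_levels = c(1, 2.5), n_out = 7)
  s2 <- productivity_scan(minisulf_pdna(), process_config(), kappas = 2,
                          so4_levels = c(1, 2.5), n_out = 7)
  expect_identical(s1$p_end, s2$p_end)
  expect_identical(s1$t_star, s2$t_star)
})

test_that("bounding the starvation length restricts the optimum sensibly", {
  surf <- coarse_scan()
  opt <- attr(surf, "optima")
  # no starvation allowed: the control-like cell wins
  b0 <- bounded_starvation_optimum(surf, 0 + 1e-3)
  expect_lt(max(b0$t_star), 1e-3 + 1e-9)
  # a loose bound reproduces the unrestricted optimum
  bfree <- bounded_starvation_optimum(surf, Inf)
  expect_equal(bfree$p_end, opt$p_end)
  # for kappa > 1 even the bounded optimum beats the non-starved control
  ctrl_p <- b0$p_end[b0$kappa == 2]
  b6 <- bounded_starvation_optimum(surf, 6)
  expect_gte(b6$p_end[b6$kappa == 2], ctrl_p - 1e-9)
})

test_that("the breakthrough production length matches the algebraic oracle", {
  kap <- 1.6
  bt <- cached("breakthrough", function()
    breakthrough_length(minisulf_pdna(), process_config(), kappa = kap))
  cf <- closed_form_linear()
  ts_opt <- stats::optimize(function(ts) cf$np_end_at(ts, kap),
                            c(0, cf$t_end), maximum = TRUE)$maximum
  # control equals growth-phase production over the whole feed; production
  # sustained for t_b at kappa q_mu must make up the forgone growth output
  tb_oracle <- (cf$iXV(cf$t_end) - cf$iXV(ts_opt)) / (kap * cf$XV(ts_opt))
  expect_equal(bt$t_breakthrough, tb_oracle, tolerance = 0.05)
  expect_lte(bt$t_breakthrough, bt$t_star + 1e-6)
  expect_error(breakthrough_length(minisulf_pdna(), process_config(), kappa = 1),
               "kappa")
})

test_that("the time-dependent-rate variant reduces to and extends the constant scan", {
  m <- minisulf_pdna()
  cfg <- process_config()
  lev <- c(1.5, 2.8)
  const <- productivity_scan(m, cfg, kappas = 2, so4_levels = lev, n_out = 7)
  # slope 0, offset (kappa-1) q0 is exactly the constant-rate model
  varq <- time_dependent_q_scan(m, cfg, q0 = 4.9, slope = 0, offset = 4.9,
                                so4_levels = lev, n_out = 7)
  expect_equal(varq$p_end, const$p_end, tolerance = 1e-9)
  # a positive starvation offset beats the offset-free variant
  noboost <- time_dependent_q_scan(m, cfg, q0 = 4.9, slope = -0.05, offset = 0,
                                   so4_levels = lev, n_out = 7)
  boost <- time_dependent_q_scan(m, cfg, q0 = 4.9, slope = -0.05, offset = 4.9,
                                 so4_levels = lev, n_out = 7)
  expect_true(all(boost$p_end >= noboost$p_end - 1e-9))
  expect_gt(max(boost$p_end), max(noboost$p_end))
})
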