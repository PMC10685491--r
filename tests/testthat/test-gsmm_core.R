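test_that("FBA reproduces the hand-solved growth optimum", {
  m <- minisulf_base()
  tru <- minisulf_truth()
  sol <- fba(m, "GROWTH")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objectives[[1]]$value, tru$mu_max, tolerance = 1e-8)
  # steady state and bounds
  expect_lt(max(abs(as.numeric(m$S %*% sol$fluxes))), 1e-6)
  expect_true(all(sol$fluxes >= m$rxns$lb - 1e-8 & sol$fluxes <= m$rxns$ub + 1e-8))
})

test_that("growth is impossible with all uptakes closed and reported as such", {
  m <- minisulf_base()
  m <- set_bounds(m, exchanges(m), lb = 0)
  m <- set_bounds(m, m$ngam_id, lb = 0)        # no maintenance demand either
  sol <- fba(m, "GROWTH")
  expect_equal(sol$objectives[[1]]$value, 0, tolerance = 1e-9)
  # with the maintenance demand in place the model is infeasible outright
  m2 <- set_bounds(minisulf_base(), exchanges(minisulf_base()), lb = 0)
  sol2 <- fba(m2, "GROWTH")
  expect_equal(sol2$status, "infeasible")
  expect_null(sol2$fluxes)
})

test_that("plasmid synthesis stays feasible without sulfate, at the documented capacity", {
  m <- set_bounds(minisulf_pdna(), "EX_so4_e", lb = 0)
  sol <- fba(m, "SK_pdna_c")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objectives[[1]]$value, minisulf_truth()$pdna_capacity,
               tolerance = 1e-6)
})

test_that("pFBA keeps the FBA optimum and minimizes total flux over the optimal face", {
  m <- minisulf_base()
  plain <- fba(m, "GROWTH")
  pars <- pfba(m, "GROWTH")
  expect_equal(pars$objectives[[1]]$value, plain$objectives[[1]]$value,
               tolerance = 1e-8)
  # alternate optima: fix growth, push each reaction to its extremes; the
  # parsimonious total flux must not exceed any of them
  opt <- plain$objectives[[1]]$value
  mfix <- set_bounds(m, "GROWTH", lb = opt - 1e-9, ub = opt + 1e-9)
  for (rxn in c("OVERFLOW", "NGAM", "EX_h2o_e", "SULFRED")) {
    for (sense in c("max", "min")) {
      alt <- fba(mfix, rxn, sense)
      if (alt$status == "optimal")
        expect_gte(sum(abs(alt$fluxes)) + 1e-6, pars$total_flux)
    }
  }
  # infeasible bounds propagate
  bad <- set_bounds(m, "EX_glc_e", lb = 0, ub = 0)
  expect_equal(pfba(bad, "GROWTH")$status, "infeasible")
})

test_that("lexicographic FBA reproduces the staged optima of the process objectives", {
  m <- apply_minimal_medium(minisulf_pdna(), minisulf_medium())
  tru <- minisulf_truth()
  spec <- minisulf_spec()
  objs <- list(list(reaction = "GROWTH", sense = "max"),
               list(reaction = "EX_so4_e", sense = "max"),
               list(reaction = "SK_pdna_c", sense = "max"))
  open <- lexicographic_fba(m, objs)
  expect_equal(open$objectives[[1]]$value, tru$mu_max, tolerance = 1e-6)
  expect_equal(-open$objectives[[2]]$value, spec$s_x * tru$mu_max, tolerance = 1e-5)
  expect_equal(open$objectives[[3]]$value, 0, tolerance = 1e-5)  # lower bound

  blocked <- lexicographic_fba(set_bounds(m, "EX_so4_e", lb = 0), objs)
  expect_equal(blocked$objectives[[1]]$value, 0, tolerance = 1e-8)
  expect_equal(blocked$objectives[[3]]$value, tru$pdna_capacity, tolerance = 1e-5)

  # a single-objective list reduces to plain FBA
  one <- lexicographic_fba(m, objs[1])
  expect_equal(one$objectives[[1]]$value, fba(m, "GROWTH")$objectives[[1]]$value,
               tolerance = 1e-10)

  # infeasibility is reported with the offending level
  m_bad <- set_bounds(m, "EX_glc_e", lb = 0, ub = 0)
  expect_error(lexicographic_fba(m_bad, objs), "level 1")
})

test_that("lexicographic prefixes are stable under downstream perturbation", {
  m <- apply_minimal_medium(minisulf_pdna(), minisulf_medium())
  objs <- list(list(reaction = "GROWTH", sense = "max"),
               list(reaction = "EX_so4_e", sense = "max"),
               list(reaction = "SK_pdna_c", sense = "max"))
  base <- lexicographic_fba(m, objs)
  # changing the third objective's feasible range must not move levels 1-2
  m2 <- set_bounds(m, "PDNAS", ub = 0.1)
  pert <- lexicographic_fba(m2, objs)
  for (k in 1:2)
    expect_equal(pert$objectives[[k]]$value, base$objectives[[k]]$value,
                 tolerance = 1e-6)
})

test_that("the minimal medium is the documented six-component set", {
  med <- minisulf_medium()
  expect_setequal(names(med), minisulf_truth()$minimal_medium)
  expect_true(all(med > 0))
  # uptake magnitudes follow the biomass stoichiometry
  spec <- minisulf_spec()
  mu <- minisulf_truth()$mu_max
  expect_equal(unname(med["EX_so4_e"]), spec$s_x * mu, tolerance = 1e-4)
  expect_equal(unname(med["EX_k_e"]), spec$k_x * mu, tolerance = 1e-4)
  # no growth possible -> no medium derivable
  closed <- set_bounds(minisulf_base(), exchanges(minisulf_base()), lb = 0)
  expect_error(minimal_medium(closed), "infeasible|no growth")
})

test_that("SBML round-trips preserve the network", {
  m <- minisulf_pdna()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_equal(nrow(m2$mets), nrow(m$mets))
  expect_equal(m2$rxns$id, m$rxns$id)
  expect_lt(max(abs(m2$S[m$mets$id, m$rxns$id] - m$S)), 1e-12)
  expect_equal(m2$rxns$lb, m$rxns$lb, tolerance = 1e-12)
  expect_equal(m2$rxns$ub, m$rxns$ub, tolerance = 1e-12)
  expect_equal(m2$biomass_id, "GROWTH")
  expect_equal(m2$ngam_id, "NGAM")
  expect_equal(fba(m2, "GROWTH")$objectives[[1]]$value,
               fba(m, "GROWTH")$objectives[[1]]$value, tolerance = 1e-9)

  empty <- withr::local_tempfile(fileext = ".xml")
  file.create(empty)
  expect_error(read_sbml(empty), "parse error")
  expect_error(read_sbml(file.path(tempdir(), "nope.xml")), "exist")
})

test_that("an independent SBML/FBA implementation agrees on the fixture", {
  # cross-check against cobrapy + GLPK via the system python
  m <- minisulf_pdna()
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  write_sbml(m, path)
  script <- paste(
    "import cobra, sys",
    sprintf("m = cobra.io.read_sbml_model('%s')", path),
    "mu = m.slim_optimize()",
    "m.reactions.EX_so4_e.lower_bound = 0",
    "m.objective = 'SK_pdna_c'",
    "cap = m.slim_optimize()",
    "print(repr(mu)); print(repr(cap))",
    sep = "\n")
  out <- suppressWarnings(system2("python", "-", input = script,
                                  stdout = TRUE, stderr = FALSE))
  vals <- as.numeric(utils::tail(out, 2))
  expect_equal(vals[1], fba(m, "GROWTH")$objectives[[1]]$value, tolerance = 1e-6)
  expect_equal(vals[2], minisulf_truth()$pdna_capacity, tolerance = 1e-6)
})
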