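test_that("the inner community LP behaves across the mu range", {
  cm <- toybin_community(co2 = c(-1000, 1000), o2 = c(-1000, 1000),
                         nh4 = c(-1000, 1000))
  # zero growth is always feasible under open exchanges; abundance capped at 1
  r0 <- steadycom_lp_at_mu(cm, 0)
  expect_equal(r0$status, "optimal")
  expect_equal(r0$total, 1, tolerance = 1e-9)
  # far above any monoculture optimum no positive abundance survives
  rhi <- steadycom_lp_at_mu(cm, 1e5)
  expect_lt(rhi$total, 1e-7)
  # just above the constrained optimum, total abundance drops below 1
  cmc <- toybin_community()
  rob <- steadycom_lp_at_mu(cmc, 0.0367)
  expect_true(rob$status != "optimal" || rob$total < 1 - 1e-7)
})

test_that("bisection finds the hand-derived community optimum", {
  cm <- toybin_community()
  sol <- solve_steadycom(cm, tol = 1e-9)
  expect_equal(sol$mu, toybin_hand$mu, tolerance = 1e-6)
  expect_equal(unname(sol$X["M"]), toybin_hand$X_M, tolerance = 1e-6)
  expect_equal(unname(sol$X["C"]), toybin_hand$X_C, tolerance = 1e-6)
  expect_equal(sum(sol$X), 1, tolerance = 1e-6)
  expect_equal(-unname(sol$exchange["ch4"]), toybin_hand$ch4_uptake,
               tolerance = 1e-6)
  # per-species steady state and growth coupling hold in the solution
  expect_lt(max(abs(cm$S %*% sol$fluxes)), 1e-6)
  expect_equal(unname(sol$fluxes["M1BIO_M"]), sol$mu * unname(sol$X["M"]),
               tolerance = 1e-6)
})

test_that("feasibility is monotone in mu under inequality exchange bounds", {
  cm <- toybin_community(co2 = c(-0.680, 1000), o2 = c(0, 0))
  feas <- vapply(seq(0.002, 0.05, length.out = 13), function(mu) {
    r <- steadycom_lp_at_mu(cm, mu)
    r$status == "optimal" && r$total >= 1 - 1e-7
  }, TRUE)
  # TRUEs form a prefix: once infeasible, never feasible again
  expect_true(all(diff(as.integer(feas)) <= 0))
})

test_that("fixed-composition solves are consistent and diagnosable", {
  cm <- toybin_community()
  sol <- solve_steadycom(cm, tol = 1e-9)
  # re-solving at the optimal composition reproduces the exchange fluxes
  fx <- solve_fixed_composition(cm, abundances = sol$X,
                                growth_rates = c(M = sol$mu, C = sol$mu))
  expect_equal(fx$status, "optimal")
  expect_equal(fx$exchange, sol$exchange, tolerance = 1e-6)
  # all-zero composition problem (under open exchanges): no growth, no flux
  cm_open <- toybin_community(co2 = c(-1000, 1000), o2 = c(-1000, 1000),
                              nh4 = c(-1000, 1000))
  z <- solve_fixed_composition(cm_open, abundances = c(M = 0.5, C = 0.5),
                               growth_rates = c(M = 0, C = 0))
  expect_equal(z$status, "optimal")
  expect_lt(max(abs(z$fluxes)), 1e-8)
  # methanotroph N demand with every community N source closed: infeasible
  # with the nitrogen balance named
  cmN <- set_exchange_policy(cm, list(no3 = c(0, 0)))
  bad <- solve_fixed_composition(
    cmN, abundances = c(M = 0.5, C = 0.5),
    growth_rates = c(M = 0.1, C = 0.1))
  expect_equal(bad$status, "infeasible")
  expect_true(any(c("nh4", "no3") %in% attr(bad, "violated")))
})

test_that("abundance and growth-rate inputs are validated", {
  cm <- toybin_community()
  expect_error(solve_fixed_composition(cm, c(M = 0.7, C = 0.7),
                                       c(M = 0, C = 0)), "sum to 1")
  expect_error(solve_fixed_composition(cm, c(M = 0.5, C = 0.5),
                                       c(M = -1, C = 0)), ">= 0")
})

test_that("cross-feeding extraction identifies producers and consumers", {
  cm <- toybin_community()
  sol <- solve_steadycom(cm, tol = 1e-9)
  cf <- extract_crossfeeding(sol)
  expect_s3_class(cf, "crossfeeding_records")
  expect_true(all(cf$flux >= 0))
  rec <- function(met) cf[cf$metabolite == met &
                            cf$producer != "environment" &
                            cf$consumer != "environment", ]
  # the phototroph feeds the methanotroph O2 and ammonium; CO2 goes back
  expect_equal(rec("o2")$producer, "C")
  expect_equal(rec("o2")$consumer, "M")
  expect_equal(rec("nh4")$producer, "C")
  expect_equal(rec("nh4")$consumer, "M")
  expect_equal(rec("co2")$producer, "M")
  expect_equal(rec("co2")$consumer, "C")
  # signed per the convention: positive = produced by the methanotroph
  expect_lt(rec("nh4")$signed, 0)
  expect_gt(rec("co2")$signed, 0)
  expect_equal(rec("nh4")$flux, toybin_hand$nh4_crossfeed, tolerance = 1e-5)
  # closed net exchange: producer total equals consumer total for O2
  expect_equal(rec("o2")$flux, 45 * sol$mu * unname(sol$X["C"]),
               tolerance = 1e-6)
  # metabolites leaving to the environment carry an environment record
  expect_true("environment" %in% cf$producer[cf$metabolite == "ch4"])
})

test_that("blocking the ammonium transport strictly lowers the optimum", {
  cm <- toybin_community()
  cmB <- cm
  cmB$lb["TR_M1_nh4"] <- 0; cmB$ub["TR_M1_nh4"] <- 0
  solA <- solve_steadycom(cm, tol = 1e-9)
  solB <- solve_steadycom(cmB, tol = 1e-9)
  expect_equal(solB$mu, toybin_hand$mu_no_nh4, tolerance = 1e-6)
  expect_lt(solB$mu, solA$mu)
})
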