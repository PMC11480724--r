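tb <- make_toybin1()
sc <- make_scenario("batch_default")

dyncom_community <- function() {
  cm <- build_community(harmonize_ids(list(tb$M, tb$C)),
                        policy_preset("toybin"))
  set_exchange_policy(cm, list(nh4 = c(0, 0)))   # medium supplies nitrate only
}

test_that("kinetic rates translate into feasible constraint sets", {
  cm <- dyncom_community()
  # zero rates, zero growth force the all-zero solution
  r0 <- c(X_M = 0.5, X_C = 0.5, mu_M = 0, mu_C = 0, q_ch4_M = 0, q_o2_M = 0,
          q_co2_M = 0, q_co2_C = 0, q_o2_C = 0)
  cons <- constraints_from_rates(r0, cm, eps = 0.01)
  sol <- solve_fixed_composition(cm, cons$abundances, cons$growth_rates,
                                 cons$rate_constraints)
  expect_equal(sol$status, "optimal")
  expect_lt(max(abs(sol$fluxes)), 1e-8)
  # exactly yield-matched rates are feasible at 1% slack
  kt <- constant_trajectory(mu = 0.03)        # ammonium-route stoichiometry
  r <- rates_at(kt, 5)
  cons2 <- constraints_from_rates(r, cm, eps = 0.01)
  sol2 <- solve_fixed_composition(cm, cons2$abundances, cons2$growth_rates,
                                  cons2$rate_constraints)
  expect_equal(sol2$status, "optimal")
  expect_error(constraints_from_rates(
    c(r0[-(1:2)], X_M = 0, X_C = 0), cm), "zero total biomass")
})

test_that("yield-mismatched rates fail at tight slack and name the imbalance", {
  cm <- dyncom_community()
  kt <- constant_trajectory(mu = 0.03,
                            a_M = c(ch4 = 48, o2 = 52, co2 = 12))  # 20% off
  r <- rates_at(kt, 5)
  cons <- constraints_from_rates(r, cm, eps = 0.01)
  bad <- solve_fixed_composition(cm, cons$abundances, cons$growth_rates,
                                 cons$rate_constraints)
  expect_equal(bad$status, "infeasible")
  expect_true("ch4" %in% attr(bad, "violated"))   # the carbon balance
  cons25 <- constraints_from_rates(r, cm, eps = 0.25)
  ok <- solve_fixed_composition(cm, cons25$abundances, cons25$growth_rates,
                                cons25$rate_constraints)
  expect_equal(ok$status, "optimal")
})

test_that("the coupling is unidirectional and frequency-independent", {
  cm <- dyncom_community()
  kt <- simulate_kinetics(sc$params, sc$init, seq(0, 48, by = 2))
  snapshot <- serialize(kt, NULL)
  es1 <- run_dyncom(kt, cm, eps = sc$dyncom$eps, times = seq(0, 48, by = 2),
                    photon_cap = sc$dyncom$photon_cap)
  # the kinetic trajectory is byte-identical after the run
  expect_identical(serialize(kt, NULL), snapshot)
  # running at half the frequency gives identical values at shared times
  es2 <- run_dyncom(kt, cm, eps = sc$dyncom$eps, times = seq(0, 48, by = 4),
                    photon_cap = sc$dyncom$photon_cap)
  shared <- merge(es1$exchange, es2$exchange, by = c("time", "metabolite"))
  expect_equal(shared$flux.x, shared$flux.y, tolerance = 1e-9)
})

test_that("per-time growth in the LP equals the kinetic growth rates", {
  cm <- dyncom_community()
  kt <- simulate_kinetics(sc$params, sc$init, seq(0, 48, by = 6))
  for (t in c(6, 24, 42)) {
    r <- rates_at(kt, t)
    cons <- constraints_from_rates(r, cm, eps = sc$dyncom$eps,
                                   photon_cap = sc$dyncom$photon_cap)
    sol <- solve_fixed_composition(cm, cons$abundances, cons$growth_rates,
                                   cons$rate_constraints)
    expect_equal(sol$status, "optimal")
    # growth coupling is exact (abundance-weighted biomass fluxes)
    expect_equal(unname(sol$fluxes["M1BIO_M"]),
                 r[["mu_M"]] * cons$abundances[["M"]], tolerance = 1e-9)
    expect_equal(unname(sol$fluxes["C1BIO_C"]),
                 r[["mu_C"]] * cons$abundances[["C"]], tolerance = 1e-9)
  }
})

test_that("with closed O2 exchange producer and consumer balance exactly", {
  cm <- dyncom_community()
  cm <- set_exchange_policy(cm, list(o2 = c(0, 0)))
  kt <- constant_trajectory(mu = 0.03)   # O2 production = consumption
  es <- run_dyncom(kt, cm, eps = 0.01)
  tr <- es$transports
  o2C <- tr$flux[tr$species == "C" & tr$metabolite == "o2"]
  o2M <- tr$flux[tr$species == "M" & tr$metabolite == "o2"]
  expect_true(all(o2C > 0))
  expect_equal(o2M, -o2C, tolerance = 1e-9)
  # constant trajectory: the series is constant and equals a single solve
  ex <- es$exchange
  for (met in unique(ex$metabolite))
    expect_equal(diff(range(ex$flux[ex$metabolite == met])), 0,
                 tolerance = 1e-8)
  r <- rates_at(kt, 0)
  cons <- constraints_from_rates(r, cm, eps = 0.01)
  one <- solve_fixed_composition(cm, cons$abundances, cons$growth_rates,
                                 cons$rate_constraints)
  cf <- extract_crossfeeding(one)
  ss <- cf[cf$producer != "environment" & cf$consumer != "environment", ]
  expect_equal(ex$flux[ex$time == 0 & ex$metabolite == "o2"],
               ss$signed[ss$metabolite == "o2"], tolerance = 1e-8)
})

test_that("exchange fluxes vanish continuously as one species dies out", {
  cm <- dyncom_community()
  kt <- constant_trajectory(mu = 0.03)
  kt$state$X_M <- 1e-9                     # methanotroph effectively extinct
  kt$rates <- kt$rates                      # rates unchanged (specific basis)
  es <- run_dyncom(kt, cm, eps = 0.01)
  expect_lt(max(abs(es$exchange$flux), na.rm = TRUE), 1e-6)
})

test_that("the batch run reproduces the nitrogen-source handover", {
  cm <- dyncom_community()
  kt <- simulate_kinetics(sc$params, sc$init, seq(0, 96, by = 4))
  es <- run_dyncom(kt, cm, eps = sc$dyncom$eps,
                   photon_cap = sc$dyncom$photon_cap)
  expect_true(all(es$exchange$status == "optimal"))
  tr <- es$transports
  no3M <- with(tr[tr$species == "M" & tr$metabolite == "no3", ],
               stats::setNames(-flux, time))
  nh4x <- es$exchange[es$exchange$metabolite == "nh4", ]
  # ammonium is cross-fed from the phototroph once both species grow
  mid <- nh4x$time > 0 & nh4x$time <= 48
  expect_true(all(nh4x$flux[mid] < 0))
  # early: substantial nitrate uptake; late: handed over to ammonium
  expect_gt(no3M[["8"]], 0.05)
  expect_lt(no3M[["72"]], 1e-3)
  expect_gt(abs(nh4x$flux[nh4x$time == 44]), abs(nh4x$flux[nh4x$time == 8]))
})

test_that("normalization rescales by CH4 uptake and by total growth", {
  cm <- dyncom_community()
  kt <- constant_trajectory(mu = 0.03)
  es <- run_dyncom(kt, cm, eps = 0.01)
  # hand value: nh4 crossfeed / CH4 uptake = (8 mu X_M) / (40 mu X_M) = 0.2
  per_ch4 <- normalize_series(es, "per_CH4")
  nh4 <- per_ch4$exchange
  expect_equal(abs(nh4$flux[nh4$metabolite == "nh4"][1]), 0.2,
               tolerance = 1e-6)
  expect_equal(per_ch4$normalization, "per_CH4")
  # per-growth normalization of a biomass-proportional flux is constant
  per_mu <- normalize_series(es, "per_growth")
  v <- per_mu$exchange$flux[per_mu$exchange$metabolite == "nh4"]
  expect_equal(diff(range(v)), 0, tolerance = 1e-8)
  expect_equal(abs(v[1]), 8 * (45 / 97), tolerance = 1e-6)
  # zero total growth yields missing values, not errors
  kt0 <- constant_trajectory(mu = 0.03)
  kt0$rates$mu_M <- 0; kt0$rates$mu_C <- 0
  kt0$rates[, grep("^q_", names(kt0$rates))] <- 0
  es0 <- run_dyncom(kt0, cm, eps = 0.01)
  n0 <- normalize_series(es0, "per_growth")
  expect_true(all(is.na(n0$exchange$flux)))
  expect_error(normalize_series(per_mu, "per_CH4"), "already")
})

test_that("widespread infeasibility aborts with a summary error", {
  cm <- dyncom_community()
  kt <- constant_trajectory(mu = 0.03, a_M = c(ch4 = 60, o2 = 52, co2 = 12))
  expect_error(run_dyncom(kt, cm, eps = 0.01), "infeasible")
})
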