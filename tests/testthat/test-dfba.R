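tb <- make_toybin1()

test_that("Michaelis-Menten uptake follows the closed form", {
  expect_equal(mm_uptake(0.5, 10, 0.5), 5)          # half-saturation
  expect_equal(mm_uptake(0, 10, 0.5), 0)
  expect_equal(mm_uptake(9 * 0.5, 10, 0.5), 9)      # 0.9 vmax at 9 Km
  expect_error(mm_uptake(-1, 10, 0.5), "negative")
  expect_error(mm_uptake(1, 10, 0), "Km")
})

test_that("lexicographic FBA yields unique programmed fluxes", {
  prog <- data.frame(reaction = c("BIO_M", "EX_ch4"),
                     sense = c("max", "min"))
  sol <- lexicographic_fba(tb$M, prog,
                           extra_bounds = list(EX_ch4 = c(-40, 1000)))
  expect_equal(sol$objective, -40, tolerance = 1e-6)   # last-level objective
  expect_equal(unname(sol$fluxes["BIO_M"]), 1, tolerance = 1e-6)
  expect_equal(unname(sol$fluxes["EX_ch4"]), -40, tolerance = 1e-6)
  # a one-level program is plain FBA
  sol1 <- lexicographic_fba(tb$M, data.frame(reaction = "BIO_M", sense = "max"),
                            extra_bounds = list(EX_ch4 = c(-40, 1000)))
  expect_equal(sol1$objective,
               fba(tb$M, extra_bounds = list(EX_ch4 = c(-40, 1000)))$objective)
  # programmed fluxes are invariant under reaction-column permutation
  set.seed(3)
  perm <- sample(n_reactions(tb$M))
  solp <- lexicographic_fba(permute_reactions(tb$M, perm), prog,
                            extra_bounds = list(EX_ch4 = c(-40, 1000)))
  expect_equal(solp$fluxes[c("BIO_M", "EX_ch4")],
               sol$fluxes[c("BIO_M", "EX_ch4")], tolerance = 1e-8)
  # an unsatisfiable constraint set reports the failing level
  mN <- set_maintenance(tb$M, gam = 0, ngam = 5)
  bad <- lexicographic_fba(mN, prog,
                           extra_bounds = list(EX_ch4 = c(0, 0)))
  # maintenance ATP demands CH4, but CH4 uptake is closed
  expect_equal(bad$status, "infeasible")
  expect_equal(attr(bad, "level"), "BIO_M")
  expect_true(all(is.na(bad$fluxes)))
  expect_error(lexicographic_fba(tb$M,
    data.frame(reaction = c("EX_ch4", "BIO_M"), sense = "max")), "first")
})

test_that("dynamic FBA holds biomass constant without substrate", {
  kin <- uptake_kinetics(data.frame(species = "M",
                                    substrate = c("ch4", "o2"),
                                    vmax = c(5, 7), Km = c(0.03, 0.01)))
  tr <- dfba_simulate(list(M = tb$M), kin,
                      init = list(X = c(M = 0.01),
                                  conc = c(ch4 = 0, o2 = 0, co2 = 0,
                                           nh4 = 1, no3 = 1)),
                      dt = 0.5, t_end = 5)
  expect_equal(tr$state$X_M, rep(0.01, nrow(tr$state)), tolerance = 1e-12)
})

test_that("monoculture dynamic FBA matches exponential growth within 1%", {
  kin <- uptake_kinetics(data.frame(species = "M",
                                    substrate = c("ch4", "o2"),
                                    vmax = c(5, 7), Km = c(0.03, 0.01)))
  S0 <- c(ch4 = 50, o2 = 50, co2 = 0, nh4 = 50, no3 = 50)  # S >> Km
  tr <- dfba_simulate(list(M = tb$M), kin,
                      init = list(X = c(M = 0.01), conc = S0),
                      dt = 0.05, t_end = 10)
  # expected growth rate: FBA at the saturated uptake caps
  cap_ch4 <- mm_uptake(50, 5, 0.03) * 50 / (0.01 + 50)
  mu_ref <- fba(tb$M, extra_bounds = list(
    EX_ch4 = c(-mm_uptake(50, 5, 0.03), 1000),
    EX_o2 = c(-mm_uptake(50, 7, 0.01), 1000)))$objective
  fit <- unname(coef(lm(log(X_M) ~ time, tr$state))[2])
  expect_equal(fit, mu_ref, tolerance = 0.01)
})

test_that("per-step fluxes conserve carbon on the ammonium route", {
  kin <- uptake_kinetics(data.frame(species = "M",
                                    substrate = c("ch4", "o2"),
                                    vmax = c(5, 7), Km = c(0.03, 0.01)))
  tr <- dfba_simulate(list(M = tb$M), kin,
                      init = list(X = c(M = 0.05),
                                  conc = c(ch4 = 5, o2 = 5, co2 = 0,
                                           nh4 = 50, no3 = 0)),
                      dt = 0.25, t_end = 6)
  fx <- tr$fluxes
  for (t in unique(fx$time)) {
    v <- stats::setNames(fx$flux[fx$time == t], fx$metabolite[fx$time == t])
    # biomass carbon is 28 mmol C per unit growth: CH4 in = 28 mu + CO2 out
    growth <- -v[["ch4"]] - v[["co2"]]   # net carbon into biomass per gDCW
    expect_equal(growth, 28 * (-v[["ch4"]] / 40), tolerance = 1e-8)
  }
})

test_that("halving the step changes the outcome by less than 1%", {
  sc <- make_scenario("o2_limited")
  init <- list(X = c(M = 0.05, C = 0.05),
               conc = c(ch4 = 2, o2 = 0.4, co2 = 1.5, nh4 = 20, no3 = 20,
                        photon = 1e4))
  run <- function(dt) dfba_simulate(
    list(M = tb$M, C = tb$C), sc$dfba$kinetics, init = init, dt = dt,
    t_end = 12, coupling = TRUE, roles = c(methanotroph = "M",
                                           phototroph = "C"),
    dual_mm = list(M = c("ch4", "o2")))
  fin <- function(tr) sum(tr$state[nrow(tr$state), c("X_M", "X_C")])
  expect_equal(fin(run(0.1)), fin(run(0.05)), tolerance = 0.01)
})

test_that("O2/CO2 coupling strictly helps under O2 limitation", {
  sc <- make_scenario("o2_limited")
  init <- list(X = c(M = 0.05, C = 0.05),
               conc = c(ch4 = 2, o2 = 0.4, co2 = 1.5, nh4 = 20, no3 = 20,
                        photon = 1e4))
  run <- function(coup) dfba_simulate(
    list(M = tb$M, C = tb$C), sc$dfba$kinetics, init = init, dt = 0.1,
    t_end = 24, coupling = coup, roles = c(methanotroph = "M",
                                           phototroph = "C"),
    dual_mm = list(M = c("ch4", "o2")))
  fin <- function(tr) sum(tr$state[nrow(tr$state), c("X_M", "X_C")])
  expect_gt(fin(run(TRUE)), fin(run(FALSE)) * 1.05)
})
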