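sc <- make_scenario("batch_default")

test_that("the kinetic right-hand side respects its limiting cases", {
  p <- sc$params
  # no cells and liquid at Henry equilibrium: nothing moves
  eq <- reactor_state(X_M = 0, X_C = 0,
                      C_ch4 = p$henry[["ch4"]] * 0.6,
                      C_o2 = 0, C_co2 = p$henry[["co2"]] * 0.3,
                      p_ch4 = 0.6, p_o2 = 0, p_co2 = 0.3, p_n2 = 0.1)
  d <- kinetic_rhs(eq, p)
  expect_lt(max(abs(d[setdiff(names(d), "time")])), 1e-12)
  # kLa = 0 with cells: headspace frozen, liquid depletes
  p0 <- p; p0$kLa[] <- 0
  st <- reactor_state(X_M = 0.1, X_C = 0.1, C_ch4 = 1, C_o2 = 1, C_co2 = 1,
                      p_ch4 = 0.6, p_o2 = 0, p_co2 = 0.3, p_n2 = 0.1)
  d0 <- kinetic_rhs(st, p0)
  expect_equal(unname(d0[c("p_ch4", "p_o2", "p_co2")]), c(0, 0, 0))
  expect_lt(d0[["C_ch4"]], 0)
  # half-saturation: C_ch4 = K_ch4 with O2 far above its K halves mu_max
  st2 <- reactor_state(X_M = 1, X_C = 0, C_ch4 = p$K[["ch4"]],
                       C_o2 = 1e6, C_co2 = 0,
                       p_ch4 = 0, p_o2 = 0, p_co2 = 0, p_n2 = 1)
  r <- coflux:::kinetic_rates_at_state(st2, p)
  expect_equal(r[["mu_M"]], p$mu_max[["M"]] / 2, tolerance = 1e-6)
  # rates are yield-consistent: q_ch4 = a_ch4 * mu (uptake negative)
  expect_equal(r[["q_ch4_M"]], -p$a_M[["ch4"]] * r[["mu_M"]],
               tolerance = 1e-9)
})

test_that("gas-liquid transfer is mole-antisymmetric", {
  p <- sc$params
  st <- reactor_state(X_M = 0.05, X_C = 0.05, C_ch4 = 0.2, C_o2 = 0.01,
                      C_co2 = 2, p_ch4 = 0.5, p_o2 = 0.02, p_co2 = 0.25,
                      p_n2 = 0.1)
  d <- kinetic_rhs(st, p)
  for (g in c("ch4", "o2", "co2")) {
    transfer <- p$kLa[[g]] * (p$henry[[g]] * st[[paste0("p_", g)]] -
                                st[[paste0("C_", g)]])
    dmol_gas <- d[[paste0("p_", g)]] * p$V_G / (coflux:::RGAS * p$temperature)
    expect_equal(dmol_gas, -transfer * p$V_L, tolerance = 1e-12)
  }
})

test_that("gas-saturated growth matches the exponential closed form", {
  p <- sc$params
  p$kLa[] <- 500                       # transfer never limiting
  init <- reactor_state(X_M = 0.01, X_C = 0, C_ch4 = p$henry[["ch4"]] * 0.6,
                        C_o2 = p$henry[["o2"]] * 0.35,
                        C_co2 = 0, p_ch4 = 0.6, p_o2 = 0.35, p_co2 = 0,
                        p_n2 = 0.05)
  # huge headspace so composition is effectively constant over the window
  p$V_G <- 1000
  kt <- simulate_kinetics(p, init, seq(0, 10, by = 0.5))
  st0 <- c(unclass(init), time = 0)
  mu <- coflux:::kinetic_rates_at_state(st0, p)[["mu_M"]]
  expect_equal(kt$state$X_M, 0.01 * exp(mu * kt$state$time),
               tolerance = 1e-3)
})

test_that("a closed system conserves carbon through a full batch", {
  kt <- simulate_kinetics(sc$params, sc$init, sc$t_grid)
  ci <- carbon_inventory(kt)
  expect_lt(max(abs(ci - ci[1])) / ci[1], 0.005)
})

test_that("refeed events reset the headspace and are right-continuous", {
  scr <- make_scenario("refeed")
  kt <- simulate_kinetics(scr$params, scr$init, scr$t_grid,
                          refeeds = scr$refeeds)
  i <- which(kt$state$time == 48)
  # stored state at the event time is the post-reset headspace
  expect_equal(kt$state$p_ch4[i], 0.60)
  expect_equal(kt$state$p_co2[i], 0.30)
  # liquid is untouched by the event: continuous across the reset
  before <- kt$state$C_ch4[i - 1]; at <- kt$state$C_ch4[i]
  expect_lt(abs(at - before), 0.2 * max(before, 0.01) + 0.05)
  # interpolation at the event time returns the post-event (stored) values
  expect_equal(rates_at(kt, 48),
               unlist(cbind(kt$state[i, c("X_M", "X_C")], kt$rates[i, -1])),
               tolerance = 1e-12)
  # a refeed into a CH4-depleted culture revives growth shortly after the
  # event (once the headspace re-dissolves), but not before it
  late <- data.frame(time = 72, p_ch4 = 0.60, p_o2 = 0, p_co2 = 0.30,
                     p_n2 = 0.10)
  kt2 <- simulate_kinetics(scr$params, scr$init, seq(0, 90, by = 1),
                           refeeds = late)
  expect_gt(rates_at(kt2, 76)[["mu_M"]], 5 * rates_at(kt2, 71)[["mu_M"]])
})

test_that("rate interpolation is exact on the grid and linear between", {
  kt <- simulate_kinetics(sc$params, sc$init, seq(0, 20, by = 2))
  r10 <- rates_at(kt, 10)
  stored <- unlist(cbind(kt$state[kt$state$time == 10, c("X_M", "X_C")],
                         kt$rates[kt$rates$time == 10, -1]))
  expect_equal(r10, stored, tolerance = 1e-12)
  mid <- rates_at(kt, 11)
  lo <- rates_at(kt, 10); hi <- rates_at(kt, 12)
  expect_equal(mid, (lo + hi) / 2, tolerance = 1e-12)
  expect_error(rates_at(kt, 21), "range")
})

test_that("known parameters are recoverable from noisy biomass data", {
  # identifiable design: CH4-limited methanotroph monoculture whose
  # dissolved CH4 sweeps down through K during the batch (30/60/10
  # CH4/O2/N2 headspace), n = 30 observation times, 2% multiplicative noise
  p <- sc$params
  p$K[["ch4"]] <- 0.2
  init <- reactor_state(X_M = 0.02, X_C = 0, C_ch4 = 0, C_o2 = 0, C_co2 = 0,
                        p_ch4 = 0.3, p_o2 = 0.6, p_co2 = 0, p_n2 = 0.1)
  t_obs <- seq(0, 87, by = 3)
  truth <- simulate_kinetics(p, init, t_obs)
  for (seed in 1:5) {
    set.seed(seed)
    noisy <- truth$state["X_M"] * exp(rnorm(length(t_obs), 0, 0.02))
    start <- p
    start$mu_max[["M"]] <- p$mu_max[["M"]] * 1.3
    start$K[["ch4"]] <- p$K[["ch4"]] * 0.6
    fit <- fit_monod_growth(t_obs, noisy, start, init,
                            fit = c("mu_max_M", "K_ch4"), observe = "X_M")
    expect_lt(abs(fit$estimates[["mu_max_M"]] - p$mu_max[["M"]]) /
                p$mu_max[["M"]], 0.10)
    expect_lt(abs(fit$estimates[["K_ch4"]] - p$K[["ch4"]]) / p$K[["ch4"]],
              0.10)
  }
})
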