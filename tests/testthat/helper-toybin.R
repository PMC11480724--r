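# Shared fixtures and small oracles for the test suite.

# the reference coculture constraint set: net O2 exchange closed, net CO2
# uptake fixed at 0.680 mmol/gDCW/hr, ammonium unavailable from the medium
toybin_community <- function(co2 = c(-0.680, -0.680), o2 = c(0, 0),
                             nh4 = c(0, 0)) {
  tb <- make_toybin1()
  cm <- build_community(harmonize_ids(list(tb$M, tb$C)),
                        policy_preset("toybin"))
  set_exchange_policy(cm, list(o2 = o2, co2 = co2, nh4 = nh4))
}

# hand linear-algebra oracle for the reference constraint set (ammonium
# route): O2 balance 45 mu X_C = 52 mu X_M fixes the composition, the CO2
# equality mu (45 X_C - 12 X_M) = 0.680 fixes mu
toybin_hand <- list(
  mu = 0.680 * 97 / 1800,
  X_M = 45 / 97, X_C = 52 / 97,
  ch4_uptake = 0.680,
  nh4_crossfeed = 8 * (0.680 * 97 / 1800) * (45 / 97),
  mu_no_nh4 = 0.680 * 101 / 1980    # nitrate route forced (mode B)
)

# independent brute-force search for the largest feasible community growth
# rate: two-stage grid scan over mu (never calls the bisection code path)
brute_force_mu <- function(cm, lo = 1e-4, hi = 0.2, coarse = 40, tol = 1e-6) {
  feasible <- function(mu) {
    r <- steadycom_lp_at_mu(cm, mu)
    r$status == "optimal" && r$total >= 1 - 1e-7
  }
  grid <- seq(lo, hi, length.out = coarse)
  ok <- vapply(grid, feasible, TRUE)
  if (!any(ok)) return(NA_real_)
  best <- max(grid[ok])
  step <- grid[2] - grid[1]
  while (step > tol) {
    grid <- seq(best, best + step, length.out = 11)
    ok <- vapply(grid, feasible, TRUE)
    best <- max(grid[ok])
    step <- step / 10
  }
  best
}

# a steady (balanced-growth) kinetic trajectory with rates exactly matched
# to the ammonium-route stoichiometry and O2 production = consumption;
# constant in time, for closed-pool and normalization tests
constant_trajectory <- function(mu = 0.03, t_grid = 0:10,
                                a_M = c(ch4 = 40, o2 = 52, co2 = 12)) {
  params <- kinetic_params(
    mu_max = c(M = mu, C = mu),
    K = c(ch4 = 1e-9, o2 = 1e-9, co2 = 1e-9),  # saturated: mu == mu_max
    light = c(I = 1, K_I = 1e-12),
    a_M = a_M, a_C = c(co2 = 45, o2 = 45),
    kLa = c(ch4 = 0, o2 = 0, co2 = 0),
    henry = c(ch4 = 1.3, o2 = 1.2, co2 = 30),
    V_L = 1, V_G = 1)
  st <- data.frame(time = t_grid, X_M = 45 / 97, X_C = 52 / 97,
                   C_ch4 = 1, C_o2 = 1, C_co2 = 1,
                   p_ch4 = 0, p_o2 = 0, p_co2 = 0, p_n2 = 1)
  rates <- t(apply(st, 1, function(row)
    coflux:::kinetic_rates_at_state(as.list(row), params)))
  structure(list(state = st, rates = data.frame(time = st$time, rates),
                 params = params, refeeds = NULL, t_grid = t_grid),
            class = "kinetic_trajectory")
}

# shuffle the reaction columns of a model (tests order invariance)
permute_reactions <- function(m, perm) {
  m$rxns <- m$rxns[perm]
  m$S <- m$S[, perm, drop = FALSE]
  m$lb <- m$lb[perm]; m$ub <- m$ub[perm]
  m
}
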