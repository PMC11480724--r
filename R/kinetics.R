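#' Kinetic parameters of the semi-structured coculture model
#'
#' Parameter block for the two-species gas-liquid bioreactor model:
#' Monod growth of the methanotroph on dissolved CH4 and O2 and of the
#' phototroph on dissolved CO2 with a light-saturation factor; specific
#' gas consumption/production linked to growth by per-growth requirement
#' coefficients `a` (mmol/gDCW) plus optional maintenance offsets `m`
#' (mmol/gDCW/hr), i.e. `q_i = a_i * mu + m_i` (a Pirt-type law; the
#' inverse of `a` is the growth yield); two-film gas-liquid transfer with
#' per-gas kLa and Henry constants; ideal-gas headspace.
#'
#' @param mu_max named `c(M=, C=)` maximal specific growth rates (1/hr).
#' @param K Monod constants `c(ch4=, o2=, co2=)` (mmol/L).
#' @param light `c(I=, K_I=)` incident intensity and half-saturation
#'   (arbitrary but mutually consistent units).
#' @param a_M,m_M methanotroph requirement coefficients for
#'   `c(ch4=, o2=, co2=)` (co2 is produced).
#' @param a_C,m_C phototroph coefficients for `c(co2=, o2=)` (o2 is
#'   produced; `a_C["o2"]/a_C["co2"]` is the photosynthetic quotient).
#' @param kLa volumetric transfer coefficients `c(ch4=, o2=, co2=)` (1/hr).
#' @param henry Henry solubilities (mmol/L/bar).
#' @param V_L,V_G liquid and headspace volumes (L).
#' @param temperature reactor temperature (K).
#' @param growth_law `"product"` (default) or `"minimum"`: how the two
#'   substrate saturation terms combine for the methanotroph.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(mu_max, K, light, a_M, m_M = c(ch4 = 0, o2 = 0, co2 = 0),
                           a_C, m_C = c(co2 = 0, o2 = 0),
                           kLa, henry, V_L = 1, V_G = 1, temperature = 303,
                           growth_law = c("product", "minimum")) {
  growth_law <- match.arg(growth_law)
  p <- list(mu_max = mu_max, K = K, light = light, a_M = a_M, m_M = m_M,
            a_C = a_C, m_C = m_C, kLa = kLa, henry = henry, V_L = V_L,
            V_G = V_G, temperature = temperature, growth_law = growth_law)
  num <- unlist(p[c("mu_max", "K", "light", "a_M", "m_M", "a_C", "m_C",
                    "kLa", "henry", "V_L", "V_G", "temperature")])
  if (any(num < 0)) stop("kinetic parameters must be non-negative")
  if (any(p$K <= 0)) stop("Monod constants must be positive")
  if (any(p$a_M <= 0) || any(p$a_C <= 0)) stop("requirement coefficients must be positive")
  structure(p, class = "kinetic_params")
}

#' Bioreactor state
#'
#' @param X_M,X_C biomass (gDCW/L).
#' @param C_ch4,C_o2,C_co2 dissolved concentrations (mmol/L).
#' @param p_ch4,p_o2,p_co2,p_n2 headspace partial pressures (bar).
#' @param time time (hr).
#' @return object of class `reactor_state` (named numeric).
#' @export
reactor_state <- function(X_M, X_C, C_ch4, C_o2, C_co2,
                          p_ch4, p_o2, p_co2, p_n2, time = 0) {
  s <- c(X_M = X_M, X_C = X_C, C_ch4 = C_ch4, C_o2 = C_o2, C_co2 = C_co2,
         p_ch4 = p_ch4, p_o2 = p_o2, p_co2 = p_co2, p_n2 = p_n2,
         time = time)
  if (any(s[setdiff(names(s), "time")] < 0)) stop("negative state")
  structure(s, class = "reactor_state")
}

## per-species growth and specific rates at a state; uptakes negative,
## excretions positive (mmol/gDCW/hr)
kinetic_rates_at_state <- function(state, params) {
  p <- params
  sat <- function(C, K) max(C, 0) / (K + max(C, 0))
  f_ch4 <- sat(state[["C_ch4"]], p$K[["ch4"]])
  f_o2 <- sat(state[["C_o2"]], p$K[["o2"]])
  f_co2 <- sat(state[["C_co2"]], p$K[["co2"]])
  f_I <- p$light[["I"]] / (p$light[["K_I"]] + p$light[["I"]])
  mu_M <- p$mu_max[["M"]] *
    if (p$growth_law == "product") f_ch4 * f_o2 else min(f_ch4, f_o2)
  mu_C <- p$mu_max[["C"]] * f_co2 * f_I
  c(mu_M = mu_M, mu_C = mu_C,
    q_ch4_M = -(p$a_M[["ch4"]] * mu_M + p$m_M[["ch4"]]),
    q_o2_M  = -(p$a_M[["o2"]] * mu_M + p$m_M[["o2"]]),
    q_co2_M =  (p$a_M[["co2"]] * mu_M + p$m_M[["co2"]]),
    q_co2_C = -(p$a_C[["co2"]] * mu_C + p$m_C[["co2"]]),
    q_o2_C  =  (p$a_C[["o2"]] * mu_C + p$m_C[["o2"]]))
}

#' Time derivatives of the bioreactor state
#'
#' The right-hand side of the semi-structured kinetic model: biomass
#' growth, liquid mass balance (gas-liquid transfer + biological
#' consumption/production), and ideal-gas headspace mole balance (the
#' negated transfer term). A pure function of state and parameters.
#'
#' @param state a [reactor_state()].
#' @param params a [kinetic_params()].
#' @return named numeric of derivatives for every state field (time
#'   derivative 1).
#' @export
kinetic_rhs <- function(state, params) {
  p <- params
  r <- kinetic_rates_at_state(state, params)
  X_M <- state[["X_M"]]; X_C <- state[["X_C"]]
  transfer <- vapply(c("ch4", "o2", "co2"), function(g)
    p$kLa[[g]] * (p$henry[[g]] * state[[paste0("p_", g)]] -
                    state[[paste0("C_", g)]]), 0)
  bio <- c(ch4 = r[["q_ch4_M"]] * X_M,
           o2 = r[["q_o2_M"]] * X_M + r[["q_o2_C"]] * X_C,
           co2 = r[["q_co2_M"]] * X_M + r[["q_co2_C"]] * X_C)
  gasfac <- p$V_L * RGAS * p$temperature / p$V_G   # bar per (mmol/L) moved
  c(X_M = r[["mu_M"]] * X_M, X_C = r[["mu_C"]] * X_C,
    C_ch4 = transfer[["ch4"]] + bio[["ch4"]],
    C_o2 = transfer[["o2"]] + bio[["o2"]],
    C_co2 = transfer[["co2"]] + bio[["co2"]],
    p_ch4 = -transfer[["ch4"]] * gasfac,
    p_o2 = -transfer[["o2"]] * gasfac,
    p_co2 = -transfer[["co2"]] * gasfac,
    p_n2 = 0, time = 1)
}

#' Simulate the kinetic bioreactor model
#'
#' Integrates the semi-structured kinetic model with `deSolve::ode`
#' (lsoda, stiff-capable) over `t_grid`, applying refeed events as
#' instantaneous headspace resets (the liquid phase is untouched at the
#' event). Emits the state and the per-species specific rates at every
#' output time.
#'
#' @param params a [kinetic_params()].
#' @param init a [reactor_state()].
#' @param t_grid increasing output times (hr).
#' @param refeeds NULL or data.frame with columns `time`, `p_ch4`,
#'   `p_o2`, `p_co2`, `p_n2` (bar) giving the post-reset headspace.
#' @param rtol,atol integrator tolerances.
#' @return object of class `kinetic_trajectory`: `state` data.frame (one
#'   row per output time) and `rates` data.frame (mu and signed specific
#'   rates per time).
#' @export
simulate_kinetics <- function(params, init, t_grid, refeeds = NULL,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(diff(t_grid) > 0))
  y0 <- unclass(init)[c("X_M", "X_C", "C_ch4", "C_o2", "C_co2",
                        "p_ch4", "p_o2", "p_co2", "p_n2")]
  deriv <- function(t, y, parms) {
    st <- c(y, time = t)
    d <- kinetic_rhs(st, params)
    list(d[names(y0)])
  }
  ev <- NULL
  times <- t_grid
  if (!is.null(refeeds) && nrow(refeeds)) {
    if (any(refeeds$time < min(t_grid) | refeeds$time > max(t_grid)))
      stop("refeed times outside the simulation range")
    evfun <- function(t, y, parms) {
      row <- refeeds[which.min(abs(refeeds$time - t)), ]
      for (g in c("p_ch4", "p_o2", "p_co2", "p_n2")) y[g] <- row[[g]]
      y
    }
    ev <- list(func = evfun, time = refeeds$time)
    times <- sort(unique(c(t_grid, refeeds$time)))
  }
  out <- try(deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol,
                          events = ev), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("integration failure: ", attr(out, "condition")$message)
  st <- as.data.frame(out)
  names(st)[1] <- "time"
  attr(st, "istate") <- NULL; attr(st, "rstate") <- NULL
  # right-continuous convention: the stored row at an event time is the
  # post-event headspace (the integrator reports the pre-event state)
  if (!is.null(refeeds) && nrow(refeeds)) {
    for (i in seq_len(nrow(refeeds))) {
      j <- which(st$time == refeeds$time[i])
      if (length(j))
        st[j, c("p_ch4", "p_o2", "p_co2", "p_n2")] <-
          refeeds[i, c("p_ch4", "p_o2", "p_co2", "p_n2")]
    }
  }
  rates <- t(apply(st, 1, function(row)
    kinetic_rates_at_state(as.list(row), params)))
  rates <- data.frame(time = st$time, rates)
  structure(list(state = st, rates = rates, params = params,
                 refeeds = refeeds, t_grid = t_grid),
            class = "kinetic_trajectory")
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  cat("<kinetic_trajectory>", nrow(x$state), "output times, t in [",
      min(x$state$time), ",", max(x$state$time), "] hr\n")
  last <- x$state[nrow(x$state), ]
  cat(sprintf("  final biomass: X_M = %.4g, X_C = %.4g gDCW/L\n",
              last$X_M, last$X_C))
  invisible(x)
}

#' @export
plot.kinetic_trajectory <- function(x, what = c("biomass", "liquid", "gas"),
                                    ...) {
  what <- match.arg(what)
  st <- x$state
  cols <- switch(what, biomass = c("X_M", "X_C"),
                 liquid = c("C_ch4", "C_o2", "C_co2"),
                 gas = c("p_ch4", "p_o2", "p_co2"))
  ylab <- switch(what, biomass = "biomass (gDCW/L)",
                 liquid = "dissolved (mmol/L)", gas = "headspace (bar)")
  graphics::matplot(st$time, as.matrix(st[cols]), type = "l", lty = 1,
                    xlab = "time (hr)", ylab = ylab, ...)
  graphics::legend("right", legend = cols, col = seq_along(cols), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Interpolate kinetic rates and abundances at a time point
#'
#' Linear interpolation between stored output times. At a refeed
#' discontinuity the stored value at the event time is the post-event
#' state, so interpolation just after an event is right-continuous.
#'
#' @param trajectory a `kinetic_trajectory`.
#' @param t time (hr) within the trajectory range.
#' @return named numeric: `X_M`, `X_C` (gDCW/L), `mu_M`, `mu_C` (1/hr)
#'   and the signed specific rates (mmol/gDCW/hr).
#' @export
rates_at <- function(trajectory, t) {
  tt <- trajectory$state$time
  if (t < min(tt) || t > max(tt)) stop("t outside trajectory range")
  vals <- cbind(trajectory$state[c("X_M", "X_C")],
                trajectory$rates[-1])
  i <- findInterval(t, tt)
  if (tt[i] == t || i == length(tt)) {
    out <- unlist(vals[i, ])
  } else {
    w <- (t - tt[i]) / (tt[i + 1] - tt[i])
    out <- (1 - w) * unlist(vals[i, ]) + w * unlist(vals[i + 1, ])
  }
  out
}

#' Closed-system carbon inventory of a kinetic trajectory
#'
#' Total carbon (mmol) in headspace CH4 + CO2, dissolved CH4 + CO2, and
#' biomass, with biomass carbon contents implied by the yield
#' coefficients: the methanotroph fixes `a_M[ch4] - a_M[co2]` and the
#' phototroph `a_C[co2]` mmol C per gDCW grown.
#'
#' @param trajectory a `kinetic_trajectory`.
#' @return numeric vector of total carbon per output time.
#' @export
carbon_inventory <- function(trajectory) {
  p <- trajectory$params
  st <- trajectory$state
  head_mol <- function(pp) pp * p$V_G / (RGAS * p$temperature)
  cx_M <- p$a_M[["ch4"]] - p$a_M[["co2"]]
  cx_C <- p$a_C[["co2"]]
  head_mol(st$p_ch4) + head_mol(st$p_co2) +
    (st$C_ch4 + st$C_co2) * p$V_L +
    (cx_M * st$X_M + cx_C * st$X_C) * p$V_L
}

#' Fit Monod growth parameters to biomass observations
#'
#' Least-squares recovery of selected kinetic parameters (on a log scale)
#' from noisy biomass time courses, by re-simulating the kinetic model
#' inside the objective. Used to verify that the model's parameters are
#' identifiable from the kind of data it emulates.
#'
#' @param times observation times.
#' @param X_obs matrix/data.frame with columns `X_M` and `X_C` (gDCW/L).
#' @param params starting [kinetic_params()] (also supplies all fixed
#'   parameters).
#' @param init initial [reactor_state()].
#' @param fit character vector of parameters to fit, from
#'   `"mu_max_M"`, `"K_ch4"`, `"mu_max_C"`, `"K_co2"`.
#' @param observe which biomass columns enter the objective (default both;
#'   use `"X_M"` for monoculture observations).
#' @param refeeds passed to [simulate_kinetics()].
#' @return list with `params` (fitted [kinetic_params()]), `estimates`
#'   (named numeric) and `sse`.
#' @export
fit_monod_growth <- function(times, X_obs, params, init,
                             fit = c("mu_max_M", "K_ch4"),
                             observe = c("X_M", "X_C"), refeeds = NULL) {
  get_par <- function(p, nm) switch(nm,
    mu_max_M = p$mu_max[["M"]], mu_max_C = p$mu_max[["C"]],
    K_ch4 = p$K[["ch4"]], K_co2 = p$K[["co2"]])
  set_par <- function(p, nm, v) {
    switch(nm,
      mu_max_M = p$mu_max[["M"]] <- v, mu_max_C = p$mu_max[["C"]] <- v,
      K_ch4 = p$K[["ch4"]] <- v, K_co2 = p$K[["co2"]] <- v)
    p
  }
  theta0 <- log(vapply(fit, function(nm) get_par(params, nm), 0))
  obs <- log(as.matrix(X_obs[observe]))
  objective <- function(theta) {
    p <- params
    for (i in seq_along(fit)) p <- set_par(p, fit[i], exp(theta[i]))
    sim <- try(simulate_kinetics(p, init, times, refeeds = refeeds,
                                 rtol = 1e-6, atol = 1e-8), silent = TRUE)
    if (inherits(sim, "try-error")) return(1e6)
    pred <- log(pmax(as.matrix(sim$state[match(times, sim$state$time),
                                         observe, drop = FALSE]), 1e-12))
    sum((pred - obs)^2)
  }
  opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  est <- exp(opt$par); names(est) <- fit
  p <- params
  for (i in seq_along(fit)) p <- set_par(p, fit[i], est[[i]])
  list(params = p, estimates = est, sse = opt$value)
}
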