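#' Fixed-composition constraints from kinetic rates
#'
#' Converts one time point of the kinetic trajectory into the constraint
#' set for [solve_fixed_composition()]: normalised abundances, per-species
#' growth rates, and equality-with-slack bounds (relative slack `eps`) on
#' the species-pool transport fluxes of CH4, O2 and CO2, in the specific
#' (per gDCW of species) basis. The photon transport of the phototroph is
#' left free or capped at `photon_cap` when given. The slack absorbs the
#' inevitable mismatch between kinetic yield coefficients and
#' genome-scale stoichiometry.
#'
#' @param rates named vector from [rates_at()] (contains `X_M`, `X_C`,
#'   `mu_M`, `mu_C` and the signed specific rates).
#' @param community the `community_model` the constraints address (its
#'   member prefixes name the transport reactions).
#' @param eps relative slack on each rate constraint.
#' @param photon_cap optional specific photon-uptake capacity of the
#'   phototroph (mmol/gDCW/hr).
#' @return list with `abundances`, `growth_rates`, `rate_constraints`
#'   ready for [solve_fixed_composition()].
#' @export
constraints_from_rates <- function(rates, community, eps = 0.01,
                                   photon_cap = NULL) {
  X_tot <- rates[["X_M"]] + rates[["X_C"]]
  if (X_tot <= 0) stop("zero total biomass")
  members <- community$members
  sp_M <- names(members)[1]; sp_C <- names(members)[2]
  ab <- stats::setNames(c(rates[["X_M"]], rates[["X_C"]]) / X_tot,
                        c(sp_M, sp_C))
  gr <- stats::setNames(c(rates[["mu_M"]], rates[["mu_C"]]), c(sp_M, sp_C))
  band <- function(q) sort(c(q * (1 - eps), q * (1 + eps)))
  rc <- list()
  trM <- members[[sp_M]]$transports
  rc[[sp_M]] <- list()
  for (g in c("ch4", "o2", "co2")) {
    q <- rates[[paste0("q_", g, "_M")]]
    if (!is.na(trM[g])) rc[[sp_M]][[unname(trM[g])]] <- band(q)
  }
  trC <- members[[sp_C]]$transports
  rc[[sp_C]] <- list()
  for (g in c("co2", "o2")) {
    q <- rates[[paste0("q_", g, "_C")]]
    if (!is.na(trC[g])) rc[[sp_C]][[unname(trC[g])]] <- band(q)
  }
  if (!is.null(photon_cap) && !is.na(trC["photon"]))
    rc[[sp_C]][[unname(trC["photon"])]] <- c(-photon_cap, 0)
  list(abundances = ab, growth_rates = gr, rate_constraints = rc)
}

#' Track interspecies exchange fluxes along a kinetic trajectory
#'
#' The coupling loop of the kinetically constrained dynamic community
#' method: at every output time of the (already computed, experimentally
#' validatable) kinetic trajectory, the kinetic growth rates, abundances
#' and specific gas exchange rates are imposed on the steady-state
#' community model via [solve_fixed_composition()], and the cross-feeding
#' fluxes through the shared `[u]` compartment are recorded. The coupling
#' is strictly unidirectional: nothing computed here feeds back into the
#' trajectory, so the constraint frequency can be chosen freely.
#'
#' @param trajectory a `kinetic_trajectory`.
#' @param community a `community_model` of the same two species.
#' @param eps relative slack on the kinetic-rate constraints.
#' @param times output times (default: the trajectory's grid).
#' @param photon_cap optional phototroph photon capacity
#'   (mmol/gDCW/hr), see [constraints_from_rates()].
#' @param max_infeasible_frac error out when more than this fraction of
#'   time points is infeasible.
#' @return object of class `exchange_series`: data.frame with columns
#'   `time`, `metabolite`, `flux` (signed species-species cross-feeding
#'   flux, mmol/gDCW_community/hr, positive when produced by the
#'   methanotroph member), `status`; plus per-time denominators for
#'   [normalize_series()].
#' @export
run_dyncom <- function(trajectory, community, eps = 0.01, times = NULL,
                       photon_cap = NULL, max_infeasible_frac = 0.5) {
  stopifnot(inherits(trajectory, "kinetic_trajectory"),
            inherits(community, "community_model"))
  if (is.null(times)) times <- trajectory$state$time
  members <- community$members
  sp_M <- names(members)[1]
  u_mets <- community$u_mets
  rows <- list(); denom <- list(); trans <- list()
  n_inf <- 0L
  for (t in times) {
    r <- rates_at(trajectory, t)
    status <- "optimal"
    fl <- stats::setNames(rep(0, length(u_mets)), u_mets)
    ch4_up <- NA_real_; mu_tot <- NA_real_
    if (r[["X_M"]] + r[["X_C"]] <= 0) {
      status <- "no_biomass"
    } else {
      cons <- constraints_from_rates(r, community, eps = eps,
                                     photon_cap = photon_cap)
      sol <- solve_fixed_composition(community, cons$abundances,
                                     cons$growth_rates,
                                     cons$rate_constraints, diagnose = FALSE)
      if (sol$status != "optimal") {
        status <- "infeasible"; n_inf <- n_inf + 1L
        fl[] <- NA_real_
      } else {
        cf <- extract_crossfeeding(sol)
        ss <- cf[cf$producer != "environment" & cf$consumer != "environment", ]
        fl[ss$metabolite] <- ss$signed
        ch4_up <- if ("ch4" %in% u_mets) max(-sol$exchange[["ch4"]], 0) else NA
        mu_tot <- sol$mu
        for (sp in names(members)) {
          tr <- members[[sp]]$transports
          trans[[length(trans) + 1L]] <- data.frame(
            time = t, species = sp, metabolite = names(tr),
            flux = unname(sol$fluxes[unname(tr)]),
            stringsAsFactors = FALSE)
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      time = t, metabolite = u_mets, flux = unname(fl), status = status,
      stringsAsFactors = FALSE)
    denom[[length(denom) + 1L]] <- data.frame(
      time = t, ch4_uptake = ch4_up, mu_total = mu_tot)
  }
  if (n_inf > max_infeasible_frac * length(times))
    stop("community LP infeasible at ", n_inf, " of ", length(times),
         " time points; kinetic rates and model stoichiometry disagree ",
         "beyond eps = ", eps)
  structure(list(exchange = do.call(rbind, rows),
                 transports = if (length(trans)) do.call(rbind, trans) else NULL,
                 denominators = do.call(rbind, denom),
                 normalization = "raw", eps = eps,
                 species = names(members), reference = sp_M),
            class = "exchange_series")
}

#' Normalize an exchange-flux series
#'
#' Rescales the cross-feeding fluxes either by the community CH4 uptake
#' rate at the same time (`per_CH4`, giving dimensionless mmol per mmol
#' CH4) or by the total community growth rate (`per_growth`, giving
#' mmol/gDCW of biomass formed). Times with a zero or missing denominator
#' yield missing values, not errors.
#'
#' @param series an `exchange_series` with `normalization == "raw"`.
#' @param mode `"per_CH4"` or `"per_growth"`.
#' @return a new `exchange_series` with rescaled `flux` and the
#'   normalization tag set.
#' @export
normalize_series <- function(series, mode = c("per_CH4", "per_growth")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "exchange_series"))
  if (series$normalization != "raw")
    stop("series is already normalized (", series$normalization, ")")
  den <- series$denominators
  key <- if (mode == "per_CH4") "ch4_uptake" else "mu_total"
  d <- den[[key]][match(series$exchange$time, den$time)]
  d[!is.na(d) & d <= 0] <- NA_real_
  out <- series
  out$exchange$flux <- series$exchange$flux / d
  out$normalization <- mode
  out
}

#' @export
print.exchange_series <- function(x, ...) {
  tt <- unique(x$exchange$time)
  cat("<exchange_series>", length(tt), "time points,",
      length(unique(x$exchange$metabolite)), "shared metabolites;",
      "normalization:", x$normalization, "\n")
  inf <- sum(x$exchange$status == "infeasible") /
    max(length(unique(x$exchange$metabolite)), 1)
  if (inf > 0) cat("  ", inf, "infeasible time points\n")
  cat("  sign: + produced by", x$reference,
      "(methanotroph), - by its partner\n")
  invisible(x)
}

#' @export
plot.exchange_series <- function(x, metabolites = NULL, ...) {
  ex <- x$exchange[x$exchange$status == "optimal", ]
  if (is.null(metabolites)) {
    rng <- tapply(abs(ex$flux), ex$metabolite, max)
    metabolites <- names(sort(rng, decreasing = TRUE))[seq_len(min(6, length(rng)))]
  }
  ex <- ex[ex$metabolite %in% metabolites, ]
  wide <- stats::reshape(ex[c("time", "metabolite", "flux")],
                         idvar = "time", timevar = "metabolite",
                         direction = "wide")
  ylab <- switch(x$normalization, raw = "flux (mmol/gDCW/hr)",
                 per_CH4 = "flux (mmol per mmol CH4)",
                 per_growth = "flux (mmol/gDCW)")
  graphics::matplot(wide$time, as.matrix(wide[-1]), type = "l", lty = 1,
                    xlab = "time (hr)", ylab = ylab, ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("topright", legend = sub("^flux\\.", "", names(wide)[-1]),
                   col = seq_len(ncol(wide) - 1), lty = 1, bty = "n")
  invisible(x)
}
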