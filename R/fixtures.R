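#' The frozen two-species toy community ("toybin-1")
#'
#' A deterministic, hand-checkable stand-in for a refined
#' methanotroph/cyanobacteria model pair. It reproduces, at toy scale, the
#' structural features the community methods need: O2/CO2 coupling between
#' an obligate aerobic methanotroph and an oxygenic photoautotroph, dual
#' nitrogen assimilation (ammonium vs. nitrate), a photon pseudo-substrate,
#' and an ATP maintenance subsystem in each species.
#'
#' Frozen stoichiometry (fluxes mmol/gDCW/hr; biomass in 1/hr):
#' \describe{
#'   \item{methanotroph `BIO_M`}{40 ch4 + 52 o2 + 8 n_int (+ GAM atp) ->
#'     biomass + 12 co2}
#'   \item{`R_nh4`}{nh4 -> n_int}
#'   \item{`R_no3`}{no3 + 0.25 ch4 + 0.5 o2 -> n_int (dissimilatory energy
#'     cost of nitrate reduction; this CH4 is oxidised for energy and its
#'     carbon is excluded from the elemental audit, see
#'     [audit_toybin1_elements()])}
#'   \item{`R_atp`}{0.25 ch4 + 0.5 o2 -> atp + 0.25 co2}
#'   \item{phototroph `BIO_C`}{45 co2 + 400 photon + 6 nh4 (+ GAM atp) ->
#'     biomass + 45 o2}
#'   \item{`R_no3C`}{no3 + 2 photon -> nh4}
#'   \item{`R_atpC`}{2 photon -> atp}
#' }
#' plus an ATP-hydrolysis maintenance reaction (`ATPM`) and exchange
#' reactions for every extracellular metabolite in each species. Photon,
#' `n_int` and `atp` are massless bookkeeping species. By construction the
#' headline optima are exact rationals: monoculture FBA of the methanotroph
#' at a CH4 uptake cap of 40 gives growth rate exactly 1, and with ammonium
#' blocked 40/42.
#'
#' @param perturb relative amplitude of a seeded random perturbation of the
#'   non-unit stoichiometric coefficients (0 = canonical frozen model).
#' @param seed integer seed used when `perturb > 0`.
#' @return list with elements `M` and `C`, each a [stoich_model()].
#' @export
make_toybin1 <- function(perturb = 0, seed = 1L) {
  jit <- function(x) x  # identity for the canonical model
  if (perturb > 0) {
    rng <- local({
      set.seed(as.integer(seed))
      stats::runif(20, 1 - perturb, 1 + perturb)
    })
    i <- 0L
    jit <- function(x) {
      i <<- i + length(x)
      x * rng[(i - length(x) + 1L):i]
    }
  }

  mets_M <- c("ch4[e]", "o2[e]", "co2[e]", "nh4[e]", "no3[e]",
              "n_int[c]", "atp[c]")
  rxns_M <- c("BIO_M", "R_nh4", "R_no3", "R_atp", "ATPM",
              "EX_ch4", "EX_o2", "EX_co2", "EX_nh4", "EX_no3")
  S_M <- matrix(0, length(mets_M), length(rxns_M),
                dimnames = list(mets_M, rxns_M))
  cf <- jit(c(40, 52, 8, 12))
  S_M[c("ch4[e]", "o2[e]", "n_int[c]"), "BIO_M"] <- -cf[1:3]
  S_M["co2[e]", "BIO_M"] <- cf[4]
  S_M[c("nh4[e]", "n_int[c]"), "R_nh4"] <- c(-1, 1)
  cf <- jit(c(0.25, 0.5))
  S_M[c("no3[e]", "ch4[e]", "o2[e]", "n_int[c]"), "R_no3"] <-
    c(-1, -cf[1], -cf[2], 1)
  S_M[c("ch4[e]", "o2[e]", "atp[c]", "co2[e]"), "R_atp"] <-
    c(-0.25, -0.5, 1, 0.25)
  S_M["atp[c]", "ATPM"] <- -1
  S_M["ch4[e]", "EX_ch4"] <- -1
  S_M["o2[e]", "EX_o2"] <- -1
  S_M["co2[e]", "EX_co2"] <- -1
  S_M["nh4[e]", "EX_nh4"] <- -1
  S_M["no3[e]", "EX_no3"] <- -1
  lb_M <- c(0, 0, 0, 0, 0, rep(-1000, 5))
  ub_M <- rep(1000, 10)
  M <- stoich_model(mets_M, rxns_M, S_M, lb_M, ub_M,
                    biomass_id = "BIO_M", maintenance_id = "ATPM",
                    gam = 0, ngam = 0, species = "M")

  mets_C <- c("co2[e]", "o2[e]", "nh4[e]", "no3[e]", "photon[e]", "atp[c]")
  rxns_C <- c("BIO_C", "R_no3C", "R_atpC", "ATPM",
              "EX_co2", "EX_o2", "EX_nh4", "EX_no3", "EX_photon")
  S_C <- matrix(0, length(mets_C), length(rxns_C),
                dimnames = list(mets_C, rxns_C))
  cf <- jit(c(45, 400, 6, 45))
  S_C[c("co2[e]", "photon[e]", "nh4[e]"), "BIO_C"] <- -cf[1:3]
  S_C["o2[e]", "BIO_C"] <- cf[4]
  S_C[c("no3[e]", "photon[e]", "nh4[e]"), "R_no3C"] <- c(-1, -2, 1)
  S_C[c("photon[e]", "atp[c]"), "R_atpC"] <- c(-2, 1)
  S_C["atp[c]", "ATPM"] <- -1
  S_C["co2[e]", "EX_co2"] <- -1
  S_C["o2[e]", "EX_o2"] <- -1
  S_C["nh4[e]", "EX_nh4"] <- -1
  S_C["no3[e]", "EX_no3"] <- -1
  S_C["photon[e]", "EX_photon"] <- -1
  lb_C <- c(0, 0, 0, 0, rep(-1000, 5))
  ub_C <- rep(1000, 9)
  C <- stoich_model(mets_C, rxns_C, S_C, lb_C, ub_C,
                    biomass_id = "BIO_C", maintenance_id = "ATPM",
                    gam = 0, ngam = 0, species = "C")
  list(M = M, C = C)
}

#' Elemental bookkeeping audit of the toy community
#'
#' Checks carbon and nitrogen balance of every toybin-1 reaction under the
#' declared pseudo-formulas: ch4/co2 carry 1 C; nh4/no3/n_int carry 1 N;
#' photon and atp are massless; biomass carbon/nitrogen contents are
#' yield-implied (methanotroph: 28 C and 8 N per unit growth; phototroph:
#' 45 C and 6 N). Exchange, maintenance and transport reactions move mass
#' across the boundary and are skipped. The dissimilatory CH4 term of
#' `R_no3` (0.25 CH4 oxidised to drive nitrate reduction) is the single
#' declared carbon exemption.
#'
#' @param models list as returned by [make_toybin1()].
#' @return data.frame of per-reaction C and N imbalances (all 0 when the
#'   audit passes).
#' @export
audit_toybin1_elements <- function(models = make_toybin1()) {
  carbon <- c(ch4 = 1, co2 = 1)
  nitrogen <- c(nh4 = 1, no3 = 1, n_int = 1)
  bio_content <- list(BIO_M = c(C = 28, N = 8), BIO_C = c(C = 45, N = 6))
  exempt_C <- list(R_no3 = 0.25)   # dissimilated CH4, documented above
  rows <- list()
  for (sp in names(models)) {
    m <- models[[sp]]
    internal <- setdiff(m$rxns, c(exchange_reactions(m), m$maintenance_id))
    for (r in internal) {
      st <- m$S[, r]
      base <- met_base(rownames(m$S))
      cbal <- sum(st * ifelse(base %in% names(carbon), carbon[base], 0),
                  na.rm = TRUE)
      nbal <- sum(st * ifelse(base %in% names(nitrogen), nitrogen[base], 0),
                  na.rm = TRUE)
      if (r %in% names(bio_content)) {
        cbal <- cbal + bio_content[[r]]["C"]
        nbal <- nbal + bio_content[[r]]["N"]
      }
      if (r %in% names(exempt_C)) cbal <- cbal + exempt_C[[r]]
      rows[[paste(sp, r)]] <- data.frame(species = sp, reaction = r,
                                         C = cbal, N = nbal)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ideal-gas constant in L bar / (mmol K)
RGAS <- 8.314e-5

#' Built-in kinetic/bioreactor scenarios for the toy coculture
#'
#' Deterministic scenario configurations that emulate closed-bottle batch
#' growth of the methanotroph-phototroph coculture on a CH4/CO2/N2
#' headspace. `batch_default` starts from a 60/30/10 CH4/CO2/N2 headspace
#' at 1 bar (the gas composition of the reference batch experiments) with
#' kinetic coefficients yield-matched to the toy stoichiometry; `refeed`
#' adds a headspace reset to the initial composition at 48 h; `o2_limited`
#' is a liquid-only scenario in which dissolved O2 is the binding resource,
#' used to contrast coupled vs. uncoupled O2/CO2 cross-feeding in dynamic
#' FBA.
#'
#' @param name one of `"batch_default"`, `"refeed"`, `"o2_limited"`.
#' @param seed integer seed stored in the scenario (all built-in scenarios
#'   are themselves deterministic; the seed governs derived perturbations).
#' @return a scenario list with elements `params` ([kinetic_params()]),
#'   `init` ([reactor_state()]), `t_grid`, `refeeds`, `dfba` (uptake
#'   kinetics, step size, horizon, coupling flag) and `dyncom`
#'   (constraint slack `eps` and the phototroph photon capacity cap).
#' @export
make_scenario <- function(name = c("batch_default", "refeed", "o2_limited"),
                          seed = 1L) {
  name <- match.arg(name)
  params <- kinetic_params(
    mu_max   = c(M = 0.12, C = 0.08),
    K        = c(ch4 = 0.03, o2 = 0.01, co2 = 0.05),
    light    = c(I = 100, K_I = 50),
    # per-growth requirement coefficients, mmol/gDCW (q_i = a_i * mu + m_i)
    a_M      = c(ch4 = 41, o2 = 54, co2 = 13),
    m_M      = c(ch4 = 0, o2 = 0, co2 = 0),
    a_C      = c(co2 = 45, o2 = 45),           # PQ = 1
    m_C      = c(co2 = 0, o2 = 0),
    kLa      = c(ch4 = 5, o2 = 5, co2 = 5),    # 1/hr
    henry    = c(ch4 = 1.3, o2 = 1.2, co2 = 30),  # mmol/L/bar
    V_L = 1, V_G = 1, temperature = 303,
    growth_law = "product"
  )
  init <- reactor_state(X_M = 0.02, X_C = 0.02,
                        C_ch4 = 0, C_o2 = 0, C_co2 = 0,
                        p_ch4 = 0.60, p_o2 = 0, p_co2 = 0.30, p_n2 = 0.10,
                        time = 0)
  refeeds <- NULL
  t_grid <- seq(0, 96, by = 1)
  if (name == "refeed") {
    refeeds <- data.frame(time = 48, p_ch4 = 0.60, p_o2 = 0,
                          p_co2 = 0.30, p_n2 = 0.10)
  }
  dfba <- list(
    kinetics = uptake_kinetics(data.frame(
      species   = c("M", "M", "C"),
      substrate = c("ch4", "o2", "co2"),
      vmax      = c(5, 7, 4),
      Km        = c(0.03, 0.01, 0.05),
      stringsAsFactors = FALSE)),
    dual_mm = list(M = c("ch4", "o2")),  # CH4 cap multiplied by O2 saturation
    dt = 0.1, t_end = 48, coupling = TRUE,
    roles = c(methanotroph = "M", phototroph = "C")
  )
  dyncom <- list(eps = 0.10,
                 # phototroph light-harvesting capacity, mmol photon/gDCW/hr:
                 # own growth at light-saturated mu_max needs
                 # (400 + 2*6) * mu_max,eff; surplus capacity is exportable
                 # as ammonium (2 photons per NH4 via nitrate reduction)
                 photon_cap = 412 * 0.08 * (100 / 150))
  if (name == "o2_limited") {
    init <- reactor_state(X_M = 0.05, X_C = 0.05,
                          C_ch4 = 2.0, C_o2 = 0.40, C_co2 = 1.5,
                          p_ch4 = 0, p_o2 = 0, p_co2 = 0, p_n2 = 1,
                          time = 0)
    params$kLa[] <- 0                       # liquid-only
    t_grid <- seq(0, 24, by = 0.5)
    dfba$t_end <- 24
  }
  structure(list(name = name, seed = as.integer(seed), params = params,
                 init = init, t_grid = t_grid, refeeds = refeeds,
                 dfba = dfba, dyncom = dyncom),
            class = "coflux_scenario")
}

#' @export
print.coflux_scenario <- function(x, ...) {
  cat("<coflux_scenario>", x$name, " seed:", x$seed, "\n")
  cat("  t: [", min(x$t_grid), ",", max(x$t_grid), "] hr;",
      if (is.null(x$refeeds)) "no refeeds" else
        paste("refeeds at", paste(x$refeeds$time, collapse = ", "), "hr"), "\n")
  invisible(x)
}

#' Write the toy fixture models and scenarios to a directory
#'
#' Emits the two toybin-1 species models in the JSON dialect plus the three
#' built-in scenarios as YAML.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
emit_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tb <- make_toybin1()
  paths <- c(file.path(dir, "toybin1_methanotroph.json"),
             file.path(dir, "toybin1_phototroph.json"))
  write_model(tb$M, paths[1])
  write_model(tb$C, paths[2])
  for (nm in c("batch_default", "refeed", "o2_limited")) {
    p <- file.path(dir, paste0("scenario_", nm, ".yaml"))
    write_scenario(make_scenario(nm), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
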