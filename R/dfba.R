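#' Michaelis-Menten uptake rate
#'
#' @param S substrate concentration (mmol/L, >= 0).
#' @param vmax maximal specific uptake rate (mmol/gDCW/hr, >= 0).
#' @param Km half-saturation constant (mmol/L, > 0).
#' @return specific uptake rate `vmax * S / (Km + S)`.
#' @export
mm_uptake <- function(S, vmax, Km) {
  if (any(S < 0)) stop("negative substrate concentration")
  if (any(vmax < 0) || any(Km <= 0)) stop("vmax must be >= 0 and Km > 0")
  vmax * S / (Km + S)
}

#' Uptake kinetics table
#'
#' @param df data.frame with columns `species`, `substrate` (base
#'   metabolite name), `vmax` (mmol/gDCW/hr), `Km` (mmol/L).
#' @return validated object of class `uptake_kinetics`.
#' @export
uptake_kinetics <- function(df) {
  stopifnot(all(c("species", "substrate", "vmax", "Km") %in% names(df)))
  if (any(df$vmax < 0) || any(df$Km <= 0))
    stop("vmax must be >= 0 and Km > 0")
  structure(df, class = c("uptake_kinetics", "data.frame"))
}

#' Lexicographic flux balance analysis
#'
#' Solves an ordered list of LP objectives, fixing each attained optimum
#' (to within `fix_tol` absolute) as a constraint before optimising the
#' next. The fluxes of all programmed reactions are unique in the returned
#' solution regardless of alternate optima elsewhere in the network, which
#' keeps dynamic simulations continuous in time.
#'
#' @param model a [stoich_model()].
#' @param program data.frame with columns `reaction`, `sense`
#'   (`"max"`/`"min"`); the first entry must be the biomass reaction.
#' @param extra_bounds named list of `c(lb, ub)` overrides.
#' @param fix_tol absolute slack used when pinning attained optima.
#' @return a `flux_solution`; on failure, status `"infeasible"` with
#'   attribute `level` naming the objective at which it occurred.
#' @export
lexicographic_fba <- function(model, program, extra_bounds = NULL,
                              fix_tol = 1e-9) {
  program <- as.data.frame(program)
  stopifnot(all(c("reaction", "sense") %in% names(program)),
            nrow(program) >= 1)
  if (anyDuplicated(program$reaction))
    stop("duplicate reactions in lexicographic program")
  if (program$reaction[1] != model$biomass_id)
    stop("first lexicographic objective must be the biomass reaction")
  bounds <- if (is.null(extra_bounds)) list() else extra_bounds
  sol <- NULL
  for (i in seq_len(nrow(program))) {
    rid <- program$reaction[i]
    sense <- match.arg(program$sense[i], c("max", "min"))
    sol <- fba(model, objective = rid, extra_bounds = bounds,
               maximize = sense == "max")
    if (sol$status != "optimal") {
      out <- flux_solution("infeasible", NA_real_,
                           stats::setNames(rep(NA_real_, length(model$rxns)),
                                           model$rxns))
      attr(out, "level") <- rid
      return(out)
    }
    opt <- sol$objective
    bounds[[rid]] <- if (sense == "max") c(opt - fix_tol, Inf) else
      c(-Inf, opt + fix_tol)
    # stay within original bounds
    bounds[[rid]][1] <- max(bounds[[rid]][1], model$lb[[rid]],
                            if (!is.null(extra_bounds[[rid]]))
                              extra_bounds[[rid]][1] else -Inf)
    bounds[[rid]][2] <- min(bounds[[rid]][2], model$ub[[rid]],
                            if (!is.null(extra_bounds[[rid]]))
                              extra_bounds[[rid]][2] else Inf)
  }
  sol
}

#' Dynamic FBA of a (co)culture bioreactor
#'
#' Static-optimisation dynamic FBA: at each step, specific uptake caps are
#' computed from the current liquid concentrations by Michaelis-Menten
#' kinetics, a lexicographic FBA is solved per species, and biomass and
#' concentrations are updated by an explicit Euler step
#' (`dX_k/dt = mu_k X_k`, `dS_i/dt = sum_k v_ik X_k`). Each species is an
#' independent model (no shared community compartment); interactions are
#' carried only by the shared liquid. The optional manual O2/CO2 coupling
#' pools the phototroph's O2 excretion and the methanotroph's CO2
#' excretion into the shared liquid within the same step; with coupling
#' off those excretions are vented and lost.
#'
#' @param models named list of [stoich_model()]s (names = species labels).
#' @param kinetics an [uptake_kinetics()] table.
#' @param programs named list of lexicographic programs (see
#'   [lexicographic_fba()]); defaults to max biomass, then min each
#'   substrate uptake (declared order), then max each excretion.
#' @param init list with `X` (named gDCW/L) and `conc` (named mmol/L by
#'   substrate base name).
#' @param dt Euler step (hr).
#' @param t_end simulation horizon (hr).
#' @param coupling logical, manual O2/CO2 cross-feed pooling.
#' @param roles named character, `c(methanotroph = , phototroph = )`;
#'   needed only when `coupling = TRUE`.
#' @param dual_mm named list, species -> pair of substrates whose uptake
#'   cap is the product of both saturation terms (e.g. CH4 uptake scaled
#'   by O2 saturation for an obligate aerobe).
#' @return object of class `reactor_trajectory`: data.frame `state`
#'   (time, biomass, concentrations), data.frame `fluxes` (per time,
#'   species, exchanged metabolite), and `diagnostic` (NULL or the
#'   termination message).
#' @export
dfba_simulate <- function(models, kinetics, programs = NULL, init, dt = 0.1,
                          t_end = 48, coupling = FALSE, roles = NULL,
                          dual_mm = NULL) {
  stopifnot(dt > 0, t_end > 0)
  sps <- names(models)
  X <- unlist(init$X)[sps]
  conc <- unlist(init$conc)
  if (any(X < 0) || any(conc < 0)) stop("negative initial state")
  # map substrate base name -> exchange reaction per species
  exmap <- lapply(models, function(m) {
    ex <- exchange_reactions(m)
    mets <- vapply(ex, function(r) rownames(m$S)[which(m$S[, r] != 0)], "")
    stats::setNames(ex, met_base(mets))
  })
  if (is.null(programs)) {
    programs <- lapply(sps, function(sp) {
      kin <- kinetics[kinetics$species == sp, , drop = FALSE]
      subs <- exmap[[sp]][kin$substrate]
      prods <- setdiff(unname(exmap[[sp]]), subs)
      data.frame(reaction = c(models[[sp]]$biomass_id, unname(subs), prods),
                 sense = c("max", rep("min", length(subs)),
                           rep("max", length(prods))),
                 stringsAsFactors = FALSE)
    })
    names(programs) <- sps
  }
  vented <- character(0)
  if (!coupling && length(sps) >= 2) {
    if (is.null(roles)) roles <- c(methanotroph = sps[1], phototroph = sps[2])
    vented <- c(paste0(roles[["phototroph"]], ".o2"),
                paste0(roles[["methanotroph"]], ".co2"))
  }

  times <- seq(0, t_end, by = dt)
  nsteps <- length(times)
  state <- matrix(NA_real_, nsteps, length(sps) + length(conc),
                  dimnames = list(NULL, c(paste0("X_", sps), names(conc))))
  fx <- list()
  diagnostic <- NULL
  for (ti in seq_len(nsteps)) {
    state[ti, ] <- c(X, conc)
    if (ti == nsteps) break
    dS <- stats::setNames(numeric(length(conc)), names(conc))
    dX <- stats::setNames(numeric(length(sps)), sps)
    step_ok <- TRUE
    for (sp in sps) {
      kin <- kinetics[kinetics$species == sp, , drop = FALSE]
      eb <- list()
      caps <- stats::setNames(numeric(nrow(kin)), kin$substrate)
      for (i in seq_len(nrow(kin))) {
        s <- kin$substrate[i]
        caps[s] <- mm_uptake(max(conc[[s]], 0), kin$vmax[i], kin$Km[i])
      }
      if (!is.null(dual_mm[[sp]])) {
        pair <- dual_mm[[sp]]
        km2 <- kin$Km[match(pair[2], kin$substrate)]
        sat2 <- conc[[pair[2]]] / (km2 + max(conc[[pair[2]]], 0))
        caps[pair[1]] <- caps[pair[1]] * max(sat2, 0)
      }
      for (s in names(caps)) {
        rid <- exmap[[sp]][[s]]
        eb[[rid]] <- c(-caps[[s]], models[[sp]]$ub[[rid]])
      }
      sol <- lexicographic_fba(models[[sp]], programs[[sp]], extra_bounds = eb)
      if (sol$status != "optimal") {
        diagnostic <- paste0("LP infeasible for species ", sp, " at t = ",
                             times[ti], " (level ", attr(sol, "level"), ")")
        step_ok <- FALSE
        break
      }
      mu <- sol$fluxes[[models[[sp]]$biomass_id]]
      dX[sp] <- mu * X[[sp]]
      for (s in names(exmap[[sp]])) {
        if (!s %in% names(conc)) next
        v <- sol$fluxes[[exmap[[sp]][[s]]]]
        # vented excretions leave the reactor instead of joining the pool
        if (!(paste0(sp, ".", s) %in% vented && v > 0))
          dS[s] <- dS[s] + v * X[[sp]]
        fx[[length(fx) + 1L]] <- data.frame(
          time = times[ti], species = sp, metabolite = s, flux = v,
          stringsAsFactors = FALSE)
      }
    }
    if (!step_ok) {
      state <- state[seq_len(ti), , drop = FALSE]
      break
    }
    X <- X + dX * dt
    conc <- pmax(conc + dS * dt, 0)   # event-clamp at zero
  }
  flux_df <- if (length(fx)) do.call(rbind, fx) else
    data.frame(time = numeric(0), species = character(0),
               metabolite = character(0), flux = numeric(0))
  structure(list(
    state = data.frame(time = times[seq_len(nrow(state))], state),
    fluxes = flux_df, dt = dt, species = sps, diagnostic = diagnostic),
    class = "reactor_trajectory")
}

#' @export
print.reactor_trajectory <- function(x, ...) {
  cat("<reactor_trajectory>", nrow(x$state), "time points, species:",
      paste(x$species, collapse = ", "), "\n")
  if (!is.null(x$diagnostic)) cat("  terminated early:", x$diagnostic, "\n")
  last <- x$state[nrow(x$state), ]
  cat("  final t =", last$time, "hr; biomass:",
      paste(sprintf("%s = %.4g", paste0("X_", x$species),
                    unlist(last[paste0("X_", x$species)])), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.reactor_trajectory <- function(x, what = c("biomass", "conc"), ...) {
  what <- match.arg(what)
  st <- x$state
  if (what == "biomass") {
    cols <- paste0("X_", x$species)
    graphics::matplot(st$time, as.matrix(st[cols]), type = "l", lty = 1,
                      xlab = "time (hr)", ylab = "biomass (gDCW/L)", ...)
    graphics::legend("topleft", legend = x$species, col = seq_along(cols),
                     lty = 1, bty = "n")
  } else {
    cols <- setdiff(names(st), c("time", paste0("X_", x$species)))
    graphics::matplot(st$time, as.matrix(st[cols]), type = "l", lty = 1,
                      xlab = "time (hr)", ylab = "concentration (mmol/L)", ...)
    graphics::legend("topright", legend = cols, col = seq_along(cols),
                     lty = 1, bty = "n")
  }
  invisible(x)
}
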