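#' Flux balance analysis
#'
#' Maximises the flux through an objective reaction (the biomass reaction
#' by default) subject to steady-state mass balance `S v = 0` and the flux
#' bounds of the model, optionally merged with `extra_bounds`. FBA returns
#' one optimal vertex; only the objective value and fluxes that are unique
#' (checkable with [fva()]) are meaningful to downstream consumers.
#'
#' @param model a [stoich_model()].
#' @param objective reaction id to maximise (default: biomass reaction).
#' @param extra_bounds named list of `c(lb, ub)` overrides applied on top
#'   of the model bounds.
#' @param maximize maximise (default) or minimise the objective.
#' @return a `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective`, and named `fluxes`
#'   (units of the bounds; `NA` unless optimal).
#' @export
fba <- function(model, objective = model$biomass_id, extra_bounds = NULL,
                maximize = TRUE) {
  if (!objective %in% model$rxns) stop("unknown objective reaction: ", objective)
  lb <- model$lb; ub <- model$ub
  if (!is.null(extra_bounds)) {
    for (id in names(extra_bounds)) {
      if (!id %in% model$rxns) stop("unknown reaction in extra_bounds: ", id)
      bb <- extra_bounds[[id]]
      if (bb[1] > bb[2]) stop("extra_bounds lb > ub for ", id)
      lb[id] <- bb[1]; ub[id] <- bb[2]
    }
  }
  n <- length(model$rxns)
  objv <- as.numeric(model$rxns == objective)
  r <- solve_lp(objv, model$S, rep("=", nrow(model$S)),
                rep(0, nrow(model$S)), lb, ub, maximize = maximize)
  flux_solution(r$status, r$objective,
                stats::setNames(r$x, model$rxns))
}

flux_solution <- function(status, objective, fluxes) {
  structure(list(status = status, objective = objective, fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution>", x$status,
      if (x$status == "optimal") sprintf(" objective = %.6g", x$objective),
      "\n")
  invisible(x)
}

#' @export
coef.flux_solution <- function(object, ...) object$fluxes

#' Set maintenance-energy parameters
#'
#' Sets the growth-associated maintenance (GAM) as the ATP coefficient in
#' the biomass reaction and the non-growth-associated maintenance (NGAM)
#' as the lower bound of the ATP-hydrolysis maintenance reaction. The ATP
#' metabolite is identified as the substrate consumed by the maintenance
#' reaction.
#'
#' @param model a [stoich_model()].
#' @param gam mmol ATP/gDCW (coefficient, >= 0).
#' @param ngam mmol ATP/gDCW/hr (flux floor, >= 0).
#' @return the modified model.
#' @export
set_maintenance <- function(model, gam, ngam) {
  if (gam < 0 || ngam < 0) stop("gam and ngam must be non-negative")
  st <- model$S[, model$maintenance_id]
  consumed <- which(st < 0)
  if (length(consumed) != 1L)
    stop("maintenance reaction must consume exactly one (ATP) metabolite")
  atp <- rownames(model$S)[consumed]
  model$S[atp, model$biomass_id] <- -gam
  model$gam <- gam
  model$ngam <- ngam
  model$lb[model$maintenance_id] <- ngam
  if (model$ub[model$maintenance_id] < ngam)
    model$ub[model$maintenance_id] <- ngam
  validate_stoich_model(model)
  model
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective reaction
#' retaining at least `frac_opt` of its FBA optimum.
#'
#' @param model a [stoich_model()].
#' @param reactions reaction ids (default: all).
#' @param frac_opt fraction of the optimum to retain, in `[0, 1]`.
#' @param objective objective reaction id.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, reactions = model$rxns, frac_opt = 1,
                objective = model$biomass_id) {
  if (frac_opt < 0 || frac_opt > 1) stop("frac_opt must be in [0, 1]")
  base <- fba(model, objective)
  if (base$status != "optimal")
    stop("base model is ", base$status, "; FVA undefined")
  lb <- model$lb; ub <- model$ub
  if (frac_opt > 0) {
    floor_ <- frac_opt * base$objective
    # keep direction-safe for negative optima
    if (base$objective < 0) floor_ <- base$objective / max(frac_opt, 1e-12)
    lb[objective] <- max(lb[objective], floor_)
  }
  dirs <- rep("=", nrow(model$S)); z <- rep(0, nrow(model$S))
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_)
  for (i in seq_along(reactions)) {
    objv <- as.numeric(model$rxns == reactions[i])
    rmin <- solve_lp(objv, model$S, dirs, z, lb, ub, maximize = FALSE)
    rmax <- solve_lp(objv, model$S, dirs, z, lb, ub, maximize = TRUE)
    out$min[i] <- rmin$objective
    out$max[i] <- rmax$objective
  }
  out
}

#' Remove blocked (dead-end) reactions
#'
#' Identifies reactions that cannot carry flux under any admissible
#' condition -- all exchange reactions opened to the widest declared
#' limits (+/- `wide`) -- and removes them, iterating to a fixed point
#' (removing a reaction can block others). The feasible flux space
#' projected onto the kept reactions is unchanged.
#'
#' @param model a [stoich_model()] or community model.
#' @param wide magnitude used to open all exchange bounds (COBRA
#'   convention 1000).
#' @param tol flux magnitude below which a range counts as zero.
#' @return list with `model` (reduced) and `removed` (data.frame:
#'   reaction, species, reason).
#' @export
remove_blocked_reactions <- function(model, wide = 1000, tol = 1e-9) {
  removed <- character(0)
  m <- model
  repeat {
    ex <- exchange_reactions(m)
    probe <- m
    probe$lb[ex] <- -wide
    probe$ub[ex] <- wide
    rng <- fva(probe, frac_opt = 0)
    dead <- rng$reaction[abs(rng$min) < tol & abs(rng$max) < tol]
    protected <- c(m$biomass_id, m$maintenance_id)
    if (!is.null(m$members))
      protected <- c(protected,
                     unlist(lapply(m$members, function(mm)
                       c(mm$biomass_id, mm$maintenance_id))))
    dead <- setdiff(dead, protected)
    if (!length(dead)) break
    removed <- c(removed, dead)
    m <- drop_reactions(m, dead)
  }
  sp <- if (!is.null(model$members)) {
    vapply(removed, function(r) {
      hit <- vapply(model$members, function(mm) r %in% mm$rxns, TRUE)
      if (any(hit)) names(model$members)[which(hit)[1]] else "community"
    }, "")
  } else rep(model$species, length(removed))
  list(model = m,
       removed = data.frame(reaction = removed, species = unname(sp),
                            reason = rep("blocked", length(removed)),
                            stringsAsFactors = FALSE))
}

drop_reactions <- function(m, ids) {
  keep <- !(m$rxns %in% ids)
  m$rxns <- m$rxns[keep]
  m$S <- m$S[, keep, drop = FALSE]
  m$lb <- m$lb[keep]; m$ub <- m$ub[keep]
  orphan <- rowSums(m$S != 0) == 0L
  if (any(orphan)) {
    m$S <- m$S[!orphan, , drop = FALSE]
    m$mets <- m$mets[!orphan, , drop = FALSE]
  }
  if (!is.null(m$members)) {
    for (sp in names(m$members)) {
      m$members[[sp]]$rxns <- intersect(m$members[[sp]]$rxns, m$rxns)
      tr <- m$members[[sp]]$transports
      m$members[[sp]]$transports <- tr[tr %in% m$rxns]
    }
    keep_u <- m$exchange_u %in% m$rxns
    m$exchange_u <- m$exchange_u[keep_u]
    m$u_mets <- m$u_mets[keep_u]
  }
  m
}
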