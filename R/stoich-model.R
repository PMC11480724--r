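#' Construct a stoichiometric metabolic model
#'
#' The basic single-species container: a stoichiometric matrix `S`
#' (metabolites x reactions, mmol per unit flux), flux bounds in
#' mmol/gDCW/hr (the biomass reaction in 1/hr), a designated biomass
#' reaction, a designated ATP-maintenance reaction, and the two maintenance
#' parameters GAM (growth-associated, mmol ATP/gDCW, the ATP coefficient in
#' the biomass reaction) and NGAM (non-growth-associated,
#' mmol ATP/gDCW/hr, the lower bound of the maintenance reaction).
#'
#' Metabolite ids carry a compartment tag in square brackets, e.g.
#' `"ch4[e]"` (extracellular), `"atp[c]"` (cytosolic), `"ac[u]"` (shared
#' community pool). Uptake is a negative exchange flux, excretion positive.
#'
#' @param mets data.frame with columns `id` and `compartment`, or a
#'   character vector of tagged ids from which compartments are parsed.
#' @param rxns character vector of reaction ids.
#' @param S numeric matrix, `length(mets)` x `length(rxns)`.
#' @param lb,ub numeric flux bounds per reaction.
#' @param biomass_id,maintenance_id reaction ids.
#' @param gam,ngam maintenance parameters (see above).
#' @param species species label, e.g. `"M"`.
#' @return object of class `stoich_model`.
#' @export
stoich_model <- function(mets, rxns, S, lb, ub, biomass_id, maintenance_id,
                         gam = 0, ngam = 0, species = "X") {
  if (is.character(mets)) {
    mets <- data.frame(id = mets, compartment = met_compartment(mets),
                       stringsAsFactors = FALSE)
  }
  S <- as.matrix(S)
  dimnames(S) <- list(mets$id, rxns)
  m <- structure(list(
    mets = mets, rxns = rxns, S = S,
    lb = stats::setNames(as.numeric(lb), rxns),
    ub = stats::setNames(as.numeric(ub), rxns),
    biomass_id = biomass_id, maintenance_id = maintenance_id,
    gam = gam, ngam = ngam, species = species
  ), class = "stoich_model")
  validate_stoich_model(m)
}

#' Parse the compartment tag out of metabolite ids
#' @param ids tagged metabolite ids like `"ch4[e]"`.
#' @return character vector of compartment letters.
#' @export
met_compartment <- function(ids) {
  out <- sub("^.*\\[([A-Za-z0-9]+)\\]$", "\\1", ids)
  bad <- out == ids
  if (any(bad)) stop("metabolite id without compartment tag: ",
                     paste(ids[bad], collapse = ", "))
  out
}

#' Base name of a tagged metabolite id (strip species prefix and tag)
#' @param ids tagged metabolite ids.
#' @param prefix optional species prefix to strip.
#' @export
met_base <- function(ids, prefix = NULL) {
  x <- sub("\\[[A-Za-z0-9]+\\]$", "", ids)
  if (!is.null(prefix)) x <- sub(paste0("^", prefix), "", x)
  x
}

known_compartments <- c("c", "e", "u")

#' Validate a stoich_model's structural invariants
#' @param m stoich_model.
#' @return the model, invisibly unchanged, or an error.
#' @export
validate_stoich_model <- function(m) {
  if (!all(m$mets$compartment %in% known_compartments))
    stop("unknown compartment tag(s): ",
         paste(setdiff(m$mets$compartment, known_compartments), collapse = ", "))
  if (anyDuplicated(m$mets$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(m$rxns)) stop("duplicate reaction ids")
  if (nrow(m$S) != nrow(m$mets) || ncol(m$S) != length(m$rxns))
    stop("S dimensions do not match metabolite/reaction lists")
  if (any(m$lb > m$ub))
    stop("validation error: lb > ub for reaction(s) ",
         paste(m$rxns[m$lb > m$ub], collapse = ", "))
  if (!m$biomass_id %in% m$rxns)
    stop("validation error: biomass reaction '", m$biomass_id, "' not in model")
  if (!m$maintenance_id %in% m$rxns)
    stop("validation error: maintenance reaction '", m$maintenance_id,
         "' not in model")
  if (m$gam < 0 || m$ngam < 0) stop("gam and ngam must be non-negative")
  invisible(m)
}

#' Reaction ids of exchange reactions
#'
#' An exchange reaction moves a single boundary-compartment (`[e]` or
#' `[u]`) metabolite across the system boundary (exactly one nonzero
#' stoichiometric entry). Intracellular sinks such as the ATP-maintenance
#' hydrolysis are not exchanges.
#' @param m stoich_model.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(m) {
  single <- colSums(m$S != 0) == 1L
  boundary_met <- m$mets$compartment %in% c("e", "u")
  hit <- single & colSums(m$S[boundary_met, , drop = FALSE] != 0) == 1L
  m$rxns[hit]
}

#' Number of reactions / metabolites
#' @param m stoich_model.
#' @export
n_reactions <- function(m) length(m$rxns)

#' @rdname n_reactions
#' @export
n_metabolites <- function(m) nrow(m$mets)

#' Set flux bounds on a model
#' @param m stoich_model.
#' @param bounds named list or list of `c(lb, ub)` per reaction id.
#' @return modified model.
#' @export
set_bounds <- function(m, bounds) {
  for (id in names(bounds)) {
    if (!id %in% m$rxns) stop("unknown reaction: ", id)
    bb <- bounds[[id]]
    if (bb[1] > bb[2]) stop("lb > ub for ", id)
    m$lb[id] <- bb[1]; m$ub[id] <- bb[2]
  }
  m
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> species:", x$species, "\n")
  cat("  ", n_metabolites(x), "metabolites,", n_reactions(x), "reactions (",
      length(exchange_reactions(x)), "exchange )\n")
  cat("  biomass:", x$biomass_id, " maintenance:", x$maintenance_id,
      sprintf(" GAM=%g NGAM=%g\n", x$gam, x$ngam))
  invisible(x)
}
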