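#' Exchange policy for a community model
#'
#' Declares which extracellular metabolites (by base name, without
#' compartment tag) may enter the shared community compartment `[u]`,
#' which are excluded, and the community-level exchange bounds
#' (mmol per gDCW of total community biomass per hr; uptake negative).
#' Blacklisted metabolites get no `[u]` counterpart at all, so they cannot
#' be exchanged between species.
#'
#' @param whitelist character vector of base metabolite names allowed in
#'   `[u]`.
#' @param blacklist base names excluded from exchange.
#' @param bounds named list `met -> c(lb, ub)` of community exchange
#'   bounds; metabolites not listed default to open (+/- 1000).
#' @return object of class `exchange_policy`.
#' @export
exchange_policy <- function(whitelist, blacklist = character(0),
                            bounds = list()) {
  if (length(intersect(whitelist, blacklist)))
    stop("whitelist and blacklist overlap: ",
         paste(intersect(whitelist, blacklist), collapse = ", "))
  bad <- setdiff(names(bounds), whitelist)
  if (length(bad))
    stop("policy error: bounds given for non-whitelisted metabolite(s): ",
         paste(bad, collapse = ", "))
  structure(list(whitelist = whitelist, blacklist = blacklist,
                 bounds = bounds), class = "exchange_policy")
}

#' Named exchange-policy presets
#'
#' Six presets mirroring the published in-silico setups that vary which
#' central-carbon (TCA-cycle) metabolites may be exchanged; each also
#' whitelists the gas/nutrient backbone (o2, co2, ch4, photon, nh4, no3).
#' These presets only matter for genome-scale models that actually contain
#' the named organic metabolites; on the toy community they reduce to the
#' backbone.
#'
#' @param name `"setup1"` ... `"setup6"`, or `"toybin"` (backbone only).
#' @return an [exchange_policy()].
#' @export
policy_preset <- function(name) {
  backbone <- c("o2", "co2", "ch4", "photon", "nh4", "no3")
  tca <- c("succ", "pyr", "mal", "oaa", "fum", "akg")
  inc <- switch(name,
    toybin = character(0),
    setup1 = c("mal", "pyr"),
    setup2 = "pyr",
    setup3 = c("pyr", "succ"),
    setup4 = "succ",
    setup5 = c("mal", "succ"),
    setup6 = c("mal", "akg"),
    stop("unknown preset: ", name))
  exchange_policy(whitelist = c(backbone, inc),
                  blacklist = setdiff(tca, inc))
}

#' Harmonize metabolite naming across species models
#'
#' Maps extracellular metabolite base names onto a shared canonical
#' vocabulary via `synonym_map`, then namespaces each species with a
#' prefix (`M1`, `C1`, ...) derived from its species label, so that ids
#' never collide when models are merged.
#'
#' @param models list of [stoich_model()]s.
#' @param synonym_map named character vector or list, old base name ->
#'   canonical base name (applied to `[e]` metabolites).
#' @return list of models with `$prefix` set and all ids prefixed.
#' @export
harmonize_ids <- function(models, synonym_map = list()) {
  smap <- unlist(synonym_map)
  labels <- vapply(models, function(m) m$species, "")
  prefix <- paste0(labels, stats::ave(seq_along(labels), labels,
                                      FUN = seq_along))
  out <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    base <- met_base(m$mets$id)
    comp <- m$mets$compartment
    newbase <- ifelse(comp == "e" & base %in% names(smap),
                      smap[base], base)
    newid_unpfx <- paste0(newbase, "[", comp, "]")
    if (anyDuplicated(newid_unpfx))
      stop("collision error: synonym map sends two metabolites of species ",
           m$species, " to ",
           paste(unique(newid_unpfx[duplicated(newid_unpfx)]), collapse = ", "))
    m$mets$id <- paste0(prefix[i], newid_unpfx)
    rownames(m$S) <- m$mets$id
    m$rxns <- paste0(prefix[i], m$rxns)
    colnames(m$S) <- m$rxns
    names(m$lb) <- m$rxns; names(m$ub) <- m$rxns
    m$biomass_id <- paste0(prefix[i], m$biomass_id)
    m$maintenance_id <- paste0(prefix[i], m$maintenance_id)
    m$prefix <- prefix[i]
    out[[i]] <- m
  }
  names(out) <- labels
  out
}

#' Merge species models into a community model
#'
#' Adds a shared community compartment `[u]`: for every whitelisted
#' metabolite and every species whose extracellular compartment contains
#' it, a reversible transport `<prefix><met>[e] <-> <met>[u]` with open
#' bounds is added (replacing that species' own exchange reaction for the
#' metabolite), plus one community exchange reaction per `[u]` metabolite
#' carrying the policy bounds. Species exchange reactions for
#' non-whitelisted metabolites are kept, so private excretions still leave
#' the system without being shareable.
#'
#' @param models list of [stoich_model()]s (run through [harmonize_ids()]
#'   first; done automatically with an empty synonym map otherwise).
#' @param policy an [exchange_policy()].
#' @return object of class `community_model` (also a `stoich_model`).
#' @export
build_community <- function(models, policy) {
  if (inherits(models, "community_model")) return(models)
  stopifnot(inherits(policy, "exchange_policy"))
  if (!all(vapply(models, function(m) !is.null(m$prefix), TRUE)))
    models <- harmonize_ids(models)

  mets <- do.call(rbind, lapply(models, function(m) m$mets))
  n_rx <- sum(vapply(models, n_reactions, 0L))
  u_mets <- character(0)
  transports <- list()   # per species: named list met -> transport rxn id
  drop_ex <- character(0)

  for (w in policy$whitelist) {
    found <- FALSE
    for (m in models) {
      eid <- paste0(m$prefix, w, "[e]")
      if (eid %in% m$mets$id) found <- TRUE
    }
    if (!found) {
      warning("whitelisted metabolite '", w, "' absent from all species; skipped")
      next
    }
    u_mets <- c(u_mets, w)
  }
  for (b in policy$blacklist) {
    if (b %in% names(policy$bounds))
      stop("policy error: bound requested for blacklisted metabolite ", b)
  }

  # assemble block-diagonal S, then transports and [u] exchanges
  all_rxns <- unlist(lapply(models, function(m) m$rxns), use.names = FALSE)
  lb <- unlist(lapply(models, function(m) m$lb), use.names = FALSE)
  ub <- unlist(lapply(models, function(m) m$ub), use.names = FALSE)
  S <- matrix(0, nrow(mets) + length(u_mets), length(all_rxns))
  uid <- if (length(u_mets)) paste0(u_mets, "[u]") else character(0)
  rownames(S) <- c(mets$id, uid)
  colnames(S) <- all_rxns
  off <- 0L
  for (m in models) {
    S[m$mets$id, m$rxns] <- m$S
    off <- off + n_reactions(m)
  }
  mets <- rbind(mets, data.frame(id = uid, compartment = rep("u", length(uid)),
                                 stringsAsFactors = FALSE))

  tr_cols <- list(); tr_lb <- numeric(0); tr_ub <- numeric(0)
  members <- list()
  for (m in models) {
    sp_transports <- character(0)
    for (w in u_mets) {
      eid <- paste0(m$prefix, w, "[e]")
      if (!eid %in% rownames(S)) next
      tid <- paste0("TR_", m$prefix, "_", w)
      col <- numeric(nrow(S)); names(col) <- rownames(S)
      col[eid] <- -1; col[paste0(w, "[u]")] <- 1
      tr_cols[[tid]] <- col
      tr_lb <- c(tr_lb, -1000); tr_ub <- c(tr_ub, 1000)
      sp_transports <- c(sp_transports, tid)
      # retire the species' own exchange reaction for this metabolite
      ex_candidates <- all_rxns[colSums(S[, all_rxns, drop = FALSE] != 0) == 1L]
      ex_hit <- ex_candidates[S[eid, ex_candidates] != 0]
      drop_ex <- c(drop_ex, ex_hit)
    }
    members[[m$species]] <- list(
      species = m$species, prefix = m$prefix,
      biomass_id = m$biomass_id, maintenance_id = m$maintenance_id,
      ngam = m$ngam,
      rxns = c(m$rxns, sp_transports),
      transports = stats::setNames(sp_transports,
                                   sub(paste0("^TR_", m$prefix, "_"), "",
                                       sp_transports)),
      model = m)
  }
  ex_cols <- list(); ex_lb <- numeric(0); ex_ub <- numeric(0)
  for (w in u_mets) {
    xid <- paste0("EX_", w, "_u")
    col <- numeric(nrow(S)); names(col) <- rownames(S)
    col[paste0(w, "[u]")] <- -1
    ex_cols[[xid]] <- col
    bb <- policy$bounds[[w]]
    if (is.null(bb)) bb <- c(-1000, 1000)
    ex_lb <- c(ex_lb, bb[1]); ex_ub <- c(ex_ub, bb[2])
  }

  keep <- !(all_rxns %in% drop_ex)
  S <- cbind(S[, keep, drop = FALSE],
             do.call(cbind, tr_cols), do.call(cbind, ex_cols))
  rxns <- c(all_rxns[keep], names(tr_cols), names(ex_cols))
  colnames(S) <- rxns
  lb <- c(lb[keep], tr_lb, ex_lb); ub <- c(ub[keep], tr_ub, ex_ub)
  for (sp in names(members))
    members[[sp]]$rxns <- intersect(members[[sp]]$rxns, rxns)

  cm <- structure(list(
    mets = mets, rxns = rxns, S = S,
    lb = stats::setNames(lb, rxns), ub = stats::setNames(ub, rxns),
    biomass_id = members[[1]]$biomass_id,
    maintenance_id = members[[1]]$maintenance_id,
    gam = models[[1]]$gam, ngam = models[[1]]$ngam,
    species = "community",
    members = members,
    u_mets = u_mets,
    exchange_u = stats::setNames(as.character(names(ex_cols)), u_mets),
    policy = policy
  ), class = c("community_model", "stoich_model"))
  validate_stoich_model(cm)
  cm
}

#' Update community-level exchange bounds
#'
#' Sets bounds on the community exchange reactions of `[u]` metabolites
#' (mmol/gDCW_community/hr; uptake negative). Setting `c(0, 0)` closes the
#' net exchange, enforcing complete in-situ cross-feeding of that
#' metabolite.
#'
#' @param community a `community_model`.
#' @param bounds named list `met -> c(lb, ub)` (base names).
#' @return the modified community model.
#' @export
set_exchange_policy <- function(community, bounds) {
  stopifnot(inherits(community, "community_model"))
  for (met in names(bounds)) {
    if (!met %in% community$u_mets)
      stop("unknown community metabolite: ", met)
    xid <- community$exchange_u[[met]]
    bb <- bounds[[met]]
    if (bb[1] > bb[2]) stop("lb > ub for ", met)
    community$lb[xid] <- bb[1]; community$ub[xid] <- bb[2]
  }
  community
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model>", length(x$members), "species:",
      paste(names(x$members), collapse = ", "), "\n")
  cat("  ", n_metabolites(x), "metabolites,", n_reactions(x), "reactions;",
      length(x$u_mets), "shared [u] metabolites:",
      paste(x$u_mets, collapse = ", "), "\n")
  invisible(x)
}
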