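#' Community LP at a fixed community growth rate
#'
#' The inner feasibility problem of the steady-state community method:
#' maximise total abundance `sum(X_k)` subject to per-species steady state
#' `S_k V_k = 0`, abundance-scaled flux bounds
#' `lb_jk * X_k <= V_jk <= ub_jk * X_k`, growth coupling
#' `V_bio,k = mu * X_k`, absolute community exchange bounds on the `[u]`
#' compartment (interpreted per gDCW of total community, valid when the
#' total abundance is normalised to 1), and `sum(X_k) <= 1`.
#'
#' @param community a `community_model` from [build_community()].
#' @param mu community growth rate (1/hr, >= 0).
#' @param fixed_X optional named abundances; when given the `X_k` stop
#'   being variables (internal use by [solve_fixed_composition()]).
#' @param mu_k optional per-species growth rates overriding the shared
#'   `mu` (only with `fixed_X`).
#' @param extra list of extra constraint rows
#'   `list(coef = named numeric over reaction ids, dir, rhs)`.
#' @param extra_var_bounds named list of `c(lb, ub)` overrides on reaction
#'   flux variables (community basis).
#' @param growth_slack relative slack on the growth-coupling equality in
#'   the fixed-composition path (0 = hard equality).
#' @return list with `total` (max sum of X, `-Inf` if infeasible),
#'   `status`, `X`, and `fluxes` (community-basis, mmol/gDCW_community/hr).
#' @export
steadycom_lp_at_mu <- function(community, mu, fixed_X = NULL, mu_k = NULL,
                               extra = list(), extra_var_bounds = NULL,
                               growth_slack = 0) {
  cm <- community
  stopifnot(inherits(cm, "community_model"))
  if (is.null(fixed_X) && mu < 0) stop("mu must be >= 0")
  nr <- length(cm$rxns)
  members <- cm$members
  K <- length(members)
  ex_u <- unname(cm$exchange_u)

  fixed <- !is.null(fixed_X)
  nX <- if (fixed) 0L else K
  nv <- nr + nX
  rx_idx <- stats::setNames(seq_len(nr), cm$rxns)

  rows <- list(); dirs <- character(0); rhs <- numeric(0)
  add_row <- function(coef_idx, coef_val, dir, b) {
    r <- numeric(nv); r[coef_idx] <- coef_val
    rows[[length(rows) + 1L]] <<- r
    dirs <<- c(dirs, dir); rhs <<- c(rhs, b)
  }

  ## mass balance
  Smat <- cbind(cm$S, matrix(0, nrow(cm$S), nX))
  ## variable bounds
  lb <- unname(cm$lb); ub <- unname(cm$ub)
  if (fixed) {
    X <- fixed_X[names(members)]
    if (is.null(mu_k)) mu_k <- stats::setNames(rep(mu, K), names(members))
    for (k in seq_len(K)) {
      sp <- names(members)[k]
      for (j in members[[k]]$rxns) {
        i <- rx_idx[[j]]
        lo <- cm$lb[[j]] * X[[sp]]; hi <- cm$ub[[j]] * X[[sp]]
        lb[i] <- min(lo, hi); ub[i] <- max(lo, hi)
      }
      bi <- rx_idx[[members[[k]]$biomass_id]]
      v <- mu_k[[sp]] * X[[sp]]
      lb[bi] <- v * (1 - growth_slack); ub[bi] <- v * (1 + growth_slack)
    }
  } else {
    # static envelope bounds; the scaled bounds are rows
    for (k in seq_len(K)) {
      for (j in members[[k]]$rxns) {
        i <- rx_idx[[j]]
        lb[i] <- min(cm$lb[[j]], 0); ub[i] <- max(cm$ub[[j]], 0)
      }
    }
    for (k in seq_len(K)) {
      xcol <- nr + k
      for (j in members[[k]]$rxns) {
        i <- rx_idx[[j]]
        if (j == members[[k]]$biomass_id) next
        if (is.finite(cm$lb[[j]]) && cm$lb[[j]] != 0)
          add_row(c(i, xcol), c(1, -cm$lb[[j]]), ">=", 0)
        if (is.finite(cm$ub[[j]]) && cm$ub[[j]] != 0)
          add_row(c(i, xcol), c(1, -cm$ub[[j]]), "<=", 0)
      }
      bi <- rx_idx[[members[[k]]$biomass_id]]
      add_row(c(bi, xcol), c(1, -mu), "=", 0)         # growth coupling
      lb[bi] <- 0; ub[bi] <- max(cm$ub[[members[[k]]$biomass_id]], 0)
    }
    add_row(nr + seq_len(K), rep(1, K), "<=", 1)      # total abundance cap
  }
  if (!is.null(extra_var_bounds)) {
    for (id in names(extra_var_bounds)) {
      i <- rx_idx[[id]]
      bb <- extra_var_bounds[[id]]
      lb[i] <- bb[1]; ub[i] <- bb[2]
    }
  }
  for (e in extra) add_row(rx_idx[names(e$coef)], unname(e$coef), e$dir, e$rhs)

  if (!fixed) { lbX <- rep(0, K); ubX <- rep(1, K) } else { lbX <- ubX <- NULL }
  mat <- rbind(Smat, do.call(rbind, rows))
  dir_all <- c(rep("=", nrow(Smat)), dirs)
  rhs_all <- c(rep(0, nrow(Smat)), rhs)
  objv <- c(rep(0, nr), rep(1, nX))
  if (fixed) objv <- rep(0, nr)  # pure feasibility
  r <- solve_lp(objv, mat, dir_all, rhs_all, c(lb, lbX), c(ub, ubX),
                maximize = TRUE)
  if (r$status != "optimal")
    return(list(total = -Inf, status = r$status, X = NULL, fluxes = NULL))
  Xout <- if (fixed) unlist(fixed_X[names(members)]) else
    stats::setNames(r$x[nr + seq_len(K)], names(members))
  list(total = if (fixed) sum(Xout) else r$objective, status = "optimal",
       X = Xout, fluxes = stats::setNames(r$x[seq_len(nr)], cm$rxns))
}

#' Solve the steady-state community model for the maximal growth rate
#'
#' Finds the largest community growth rate `mu` at which the community LP
#' ([steadycom_lp_at_mu()]) supports total abundance 1, by bisection. The
#' initial bracket is `[0, min_k mu_max_k]` with `mu_max_k` the
#' monoculture FBA optimum of each member under wide-open exchanges. When
#' `mu = 0` is infeasible (possible when community exchange constraints
#' are equalities, e.g. a fixed net CO2 consumption that demands growth),
#' a descending geometric grid locates a feasible growth rate before
#' bisection; if none exists the constraints are inconsistent.
#'
#' The reported flux distribution is made unique by a lexicographic
#' tie-break at the optimal `mu`: first minimise total community substrate
#' uptake across `[u]` exchanges (photon excluded), then minimise the sum
#' of absolute species-pool transport fluxes (parsimonious cross-feeding).
#'
#' @param community a `community_model`.
#' @param tol bisection tolerance on `mu` (1/hr).
#' @param max_iter maximum bisection iterations.
#' @param scan_factor geometric spacing of the feasibility scan.
#' @param abund_tol slack on "total abundance reaches 1".
#' @return object of class `steadycom_solution`: community growth rate
#'   `mu`, abundance fractions `X`, community-basis `fluxes`, per-`[u]`
#'   metabolite community `exchange` fluxes, and `status`.
#' @export
solve_steadycom <- function(community, tol = 1e-6, max_iter = 60,
                            scan_factor = 1.15, abund_tol = 1e-7) {
  cm <- community
  mono_mu <- vapply(cm$members, function(mm) {
    m <- mm$model
    ex <- exchange_reactions(m)
    m$lb[ex] <- -1000; m$ub[ex] <- 1000
    f <- fba(m)
    if (f$status == "optimal") f$objective else 0
  }, 0)
  hi <- min(mono_mu)
  if (hi <= 0) stop("constraints inconsistent: a member cannot grow at all")
  feasible <- function(mu) {
    r <- steadycom_lp_at_mu(cm, mu)
    r$status == "optimal" && r$total >= 1 - abund_tol
  }
  lo <- 0
  if (!feasible(0)) {
    mu_try <- hi
    lo <- NA
    while (mu_try > tol) {
      if (feasible(mu_try)) { lo <- mu_try; break }
      mu_try <- mu_try / scan_factor
    }
    if (is.na(lo))
      stop("constraints inconsistent: no feasible community growth rate found")
  }
  if (feasible(hi)) {
    lo <- hi
  } else {
    hi_b <- if (lo > 0) min(hi, lo * scan_factor) else hi
    for (it in seq_len(max_iter)) {
      if (hi_b - lo <= tol) break
      mid <- (lo + hi_b) / 2
      if (feasible(mid)) lo <- mid else hi_b <- mid
    }
  }
  mu_star <- lo
  sol <- steadycom_lp_at_mu(cm, mu_star)
  ## unique reporting fluxes via the lexicographic tie-break at fixed X,
  ## with mu re-maximised as a free LP variable so that equality exchange
  ## constraints (which pin the true mu exactly at this composition) win
  ## over the bisection residual
  X <- sol$X / sum(sol$X)
  ref <- tryCatch(
    tiebreak_fluxes(cm, as.list(X),
                    growth_rates = stats::setNames(
                      rep(mu_star, length(cm$members)), names(cm$members)),
                    evb = list(), mu_free = TRUE),
    error = function(e) NULL)
  fluxes <- if (is.null(ref)) sol$fluxes else ref$fluxes
  mu_rep <- if (is.null(ref)) mu_star else ref$mu
  ex <- fluxes[unname(cm$exchange_u)]
  names(ex) <- cm$u_mets
  structure(list(mu = mu_rep, X = X, fluxes = fluxes,
                 exchange = ex, status = "optimal", tol = tol,
                 members = names(cm$members), community = cm),
            class = "steadycom_solution")
}

#' @export
print.steadycom_solution <- function(x, ...) {
  cat("<steadycom_solution> status:", x$status, "\n")
  cat(sprintf("  community growth rate mu = %.6g /hr\n", x$mu))
  comp <- paste(sprintf("%s %.1f%%", names(x$X), 100 * x$X), collapse = ", ")
  cat("  composition:", comp, "\n")
  invisible(x)
}

#' @export
summary.steadycom_solution <- function(object, ...) {
  cat(sprintf("Community growth rate: %.6g /hr (bisection tol %g)\n",
              object$mu, object$tol))
  cat("Abundance fractions:\n")
  print(round(object$X, 4))
  cat("Community exchange fluxes (mmol/gDCW/hr; uptake < 0):\n")
  print(round(object$exchange, 4))
  cf <- extract_crossfeeding(object)
  if (nrow(cf)) {
    cat("Cross-feeding records:\n")
    print(cf, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.steadycom_solution <- function(object, ...) object$X

#' Community solve at fixed composition and per-species growth rates
#'
#' The constrained community LP used by the kinetically driven dynamic
#' method: abundances `X_k` and per-species growth rates `mu_k` are fixed
#' (allowing unequal growth), per-species specific-rate constraints
#' (mmol/gDCW_k/hr, converted to community basis by multiplying by `X_k`)
#' are applied to the named reactions, and a unique flux vector is chosen
#' by the lexicographic tie-break: minimise total community substrate
#' uptake (photon excluded), then minimise the sum of absolute transport
#' fluxes.
#'
#' @param community a `community_model`.
#' @param abundances named abundances summing to 1.
#' @param growth_rates named per-species growth rates (1/hr).
#' @param rate_constraints per-species list:
#'   `list(M = list(TR_M1_ch4 = c(lo, hi), ...), ...)` of specific-rate
#'   bounds on that species' reactions (community transport sign
#'   convention: flux from `[e]` into `[u]` positive, so a specific uptake
#'   `q` appears as transport bounds around `-q`).
#' @param substrate_mets `[u]` metabolites counted as substrates in the
#'   tie-break (default: all but photon).
#' @param growth_slack relative slack on the growth-coupling equalities
#'   (default 0: hard `V_bio,k = mu_k X_k`).
#' @param diagnose when infeasible, run an elastic diagnosis of which
#'   shared-pool mass balances are violated.
#' @return a `steadycom_solution` (with `mu` the abundance-weighted mean
#'   growth rate); `status` `"infeasible"` carries a `violated` attribute
#'   naming the out-of-balance `[u]` metabolites.
#' @export
solve_fixed_composition <- function(community, abundances, growth_rates,
                                    rate_constraints = NULL,
                                    substrate_mets = NULL,
                                    growth_slack = 0,
                                    diagnose = TRUE) {
  cm <- community
  members <- cm$members
  X <- abundances[names(members)]
  if (abs(sum(unlist(X)) - 1) > 1e-6)
    stop("abundances must sum to 1")
  if (any(unlist(growth_rates)[names(members)] < 0))
    stop("growth rates must be >= 0")
  evb <- list()
  if (!is.null(rate_constraints)) {
    for (sp in names(rate_constraints)) {
      if (!sp %in% names(members)) stop("unknown species: ", sp)
      for (rid in names(rate_constraints[[sp]])) {
        if (!rid %in% cm$rxns) stop("unknown reaction: ", rid)
        bb <- sort(rate_constraints[[sp]][[rid]] * X[[sp]])
        evb[[rid]] <- bb
      }
    }
  }
  base <- steadycom_lp_at_mu(cm, mu = 0, fixed_X = X, mu_k = growth_rates,
                             extra_var_bounds = evb,
                             growth_slack = growth_slack)
  if (base$status != "optimal") {
    violated <- if (diagnose)
      diagnose_infeasibility(cm, X, growth_rates, evb) else character(0)
    out <- structure(list(mu = NA_real_, X = unlist(X), fluxes = NULL,
                          exchange = NULL, status = "infeasible",
                          members = names(members), community = cm),
                     class = "steadycom_solution")
    attr(out, "violated") <- violated
    return(out)
  }
  fluxes <- tiebreak_fluxes(cm, X, growth_rates, evb, substrate_mets,
                            growth_slack)$fluxes
  ex <- fluxes[unname(cm$exchange_u)]
  names(ex) <- cm$u_mets
  mu_bar <- sum(unlist(growth_rates)[names(members)] * unlist(X))
  structure(list(mu = mu_bar, mu_k = unlist(growth_rates)[names(members)],
                 X = unlist(X), fluxes = fluxes, exchange = ex,
                 status = "optimal", members = names(members),
                 community = cm),
            class = "steadycom_solution")
}

## lexicographic tie-break: (0, optional) re-maximise the shared growth
## rate as a free variable at the fixed composition, (1) min total
## substrate uptake on [u] exchanges (photon excluded), (2) min sum
## |transport fluxes|; implemented by augmenting the fixed-composition LP
## with auxiliary magnitude variables.
tiebreak_fluxes <- function(cm, X, growth_rates, evb, substrate_mets = NULL,
                            growth_slack = 0, mu_free = FALSE) {
  members <- cm$members
  nr <- length(cm$rxns)
  rx_idx <- stats::setNames(seq_len(nr), cm$rxns)
  if (is.null(substrate_mets)) substrate_mets <- setdiff(cm$u_mets, "photon")
  subs_ex <- unname(cm$exchange_u[cm$u_mets %in% substrate_mets])
  trans <- unlist(lapply(members, function(mm) unname(mm$transports)),
                  use.names = FALSE)

  lb <- unname(cm$lb); ub <- unname(cm$ub)
  for (k in seq_along(members)) {
    sp <- names(members)[k]
    for (j in members[[k]]$rxns) {
      i <- rx_idx[[j]]
      lo <- cm$lb[[j]] * X[[sp]]; hi <- cm$ub[[j]] * X[[sp]]
      lb[i] <- min(lo, hi); ub[i] <- max(lo, hi)
    }
    if (!mu_free) {
      bi <- rx_idx[[members[[k]]$biomass_id]]
      v <- growth_rates[[sp]] * X[[sp]]
      lb[bi] <- v * (1 - growth_slack); ub[bi] <- v * (1 + growth_slack)
    }
  }
  for (id in names(evb)) { lb[rx_idx[[id]]] <- evb[[id]][1]
                           ub[rx_idx[[id]]] <- evb[[id]][2] }

  n_u <- length(subs_ex); n_t <- length(trans)
  n_mu <- if (mu_free) 1L else 0L
  nv <- nr + n_u + n_t + n_mu
  mu_col <- nr + n_u + n_t + 1L
  Smat <- cbind(cm$S, matrix(0, nrow(cm$S), n_u + n_t + n_mu))
  rows <- list(); dirs <- character(0); rhs <- numeric(0)
  add_row <- function(idx, val, dir, b) {
    r <- numeric(nv); r[idx] <- val
    rows[[length(rows) + 1L]] <<- r
    dirs <<- c(dirs, dir); rhs <<- c(rhs, b)
  }
  if (mu_free) {  # equal growth coupled to the free mu variable
    for (k in seq_along(members)) {
      sp <- names(members)[k]
      bi <- rx_idx[[members[[k]]$biomass_id]]
      add_row(c(bi, mu_col), c(1, -X[[sp]]), "=", 0)
    }
  }
  # u_m >= -V_ex (uptake magnitude), u_m >= 0 via bound
  for (i in seq_len(n_u))
    add_row(c(rx_idx[[subs_ex[i]]], nr + i), c(1, 1), ">=", 0)
  # t_j >= V_tr, t_j >= -V_tr
  for (i in seq_len(n_t)) {
    j <- rx_idx[[trans[i]]]
    add_row(c(j, nr + n_u + i), c(-1, 1), ">=", 0)
    add_row(c(j, nr + n_u + i), c(1, 1), ">=", 0)
  }
  mat <- rbind(Smat, do.call(rbind, rows))
  dir_all <- c(rep("=", nrow(Smat)), dirs)
  rhs_all <- c(rep(0, nrow(Smat)), rhs)
  lb_all <- c(lb, rep(0, n_u + n_t), if (mu_free) 0)
  ub_all <- c(ub, rep(Inf, n_u + n_t), if (mu_free) Inf)

  mu_hat <- NULL
  if (mu_free) {  # stage 0: the exact growth rate at this composition
    obj0 <- numeric(nv); obj0[mu_col] <- 1
    r0 <- solve_lp(obj0, mat, dir_all, rhs_all, lb_all, ub_all,
                   maximize = TRUE)
    if (r0$status != "optimal") stop("tie-break stage 0: ", r0$status)
    mu_hat <- r0$objective
    lb_all[mu_col] <- mu_hat - 1e-11
    ub_all[mu_col] <- mu_hat
  }
  # stage 1: min sum u
  obj1 <- c(rep(0, nr), rep(1, n_u), rep(0, n_t + n_mu))
  r1 <- solve_lp(obj1, mat, dir_all, rhs_all, lb_all, ub_all,
                 maximize = FALSE)
  if (r1$status != "optimal") stop("tie-break stage 1: ", r1$status)
  # stage 2: fix stage-1 optimum, min sum t
  mat2 <- rbind(mat, obj1)
  dir2 <- c(dir_all, "<="); rhs2 <- c(rhs_all, r1$objective + 1e-9)
  obj2 <- c(rep(0, nr + n_u), rep(1, n_t), rep(0, n_mu))
  r2 <- solve_lp(obj2, mat2, dir2, rhs2, lb_all, ub_all, maximize = FALSE)
  if (r2$status != "optimal") stop("tie-break stage 2: ", r2$status)
  list(fluxes = stats::setNames(r2$x[seq_len(nr)], cm$rxns), mu = mu_hat)
}

## elastic relaxation of the shared-pool and extracellular mass balances:
## which metabolites cannot be balanced under the imposed rates?
diagnose_infeasibility <- function(cm, X, growth_rates, evb, tol = 1e-6) {
  members <- cm$members
  nr <- length(cm$rxns)
  rx_idx <- stats::setNames(seq_len(nr), cm$rxns)
  lb <- unname(cm$lb); ub <- unname(cm$ub)
  for (k in seq_along(members)) {
    sp <- names(members)[k]
    for (j in members[[k]]$rxns) {
      i <- rx_idx[[j]]
      lo <- cm$lb[[j]] * X[[sp]]; hi <- cm$ub[[j]] * X[[sp]]
      lb[i] <- min(lo, hi); ub[i] <- max(lo, hi)
    }
    bi <- rx_idx[[members[[k]]$biomass_id]]
    lb[bi] <- ub[bi] <- growth_rates[[sp]] * X[[sp]]
  }
  for (id in names(evb)) { lb[rx_idx[[id]]] <- evb[[id]][1]
                           ub[rx_idx[[id]]] <- evb[[id]][2] }
  soft_rows <- which(cm$mets$compartment %in% c("u", "e"))
  n_s <- length(soft_rows)
  # slack pair (s+, s-) on each boundary-compartment row
  Sel <- matrix(0, nrow(cm$S), 2 * n_s)
  for (i in seq_len(n_s)) {
    Sel[soft_rows[i], 2 * i - 1] <- 1
    Sel[soft_rows[i], 2 * i] <- -1
  }
  mat <- cbind(cm$S, Sel)
  obj <- c(rep(0, nr), rep(1, 2 * n_s))
  r <- solve_lp(obj, mat, rep("=", nrow(cm$S)), rep(0, nrow(cm$S)),
                c(lb, rep(0, 2 * n_s)), c(ub, rep(Inf, 2 * n_s)),
                maximize = FALSE)
  if (r$status != "optimal") return("(unresolved: intracellular infeasibility)")
  s <- r$x[nr + seq_len(2 * n_s)]
  viol <- abs(s[seq(1, 2 * n_s, 2)]) + abs(s[seq(2, 2 * n_s, 2)])
  ids <- cm$mets$id[soft_rows[viol > tol]]
  pfx <- paste(vapply(cm$members, function(mm) mm$prefix, ""), collapse = "|")
  unique(met_base(sub(paste0("^(", pfx, ")"), "", ids)))
}

#' Extract cross-feeding records from a community solution
#'
#' Decomposes each shared `[u]` metabolite's species transport fluxes into
#' producer and consumer roles. For a species pair the transferred flux is
#' the overlap `min(produced, consumed)`; surplus production leaving via
#' the community exchange is recorded against `"environment"`, as is
#' consumption fed from the medium. The signed value is positive when the
#' producer is the reference (first, methanotroph) member and negative
#' when it is the phototroph partner.
#'
#' @param solution a `steadycom_solution`.
#' @param tol flux magnitude below which a transport is ignored.
#' @return data.frame of class `crossfeeding_records`, ranked by
#'   magnitude: metabolite, producer, consumer, flux
#'   (mmol/gDCW_community/hr), signed.
#' @export
extract_crossfeeding <- function(solution, tol = 1e-8) {
  stopifnot(inherits(solution, "steadycom_solution"))
  if (solution$status != "optimal") stop("solution is not optimal")
  cm <- solution$community
  ref_sp <- names(cm$members)[1]
  rows <- list()
  for (i in seq_along(cm$u_mets)) {
    met <- cm$u_mets[i]
    tr <- vapply(cm$members, function(mm) {
      tid <- mm$transports[met]
      if (is.na(tid)) 0 else unname(solution$fluxes[tid])
    }, 0)
    env <- unname(solution$fluxes[cm$exchange_u[[met]]])
    prod <- tr[tr > tol]; cons <- -tr[tr < -tol]
    if (env < -tol) prod <- c(prod, environment = -env)
    if (env > tol) cons <- c(cons, environment = env)
    if (!length(prod) || !length(cons)) next
    # pair producers with consumers, species-species overlap first
    for (p in names(sort(prod, decreasing = TRUE))) {
      for (q in names(sort(cons, decreasing = TRUE))) {
        if (p == "environment" && q == "environment") next
        f <- min(prod[[p]], cons[[q]])
        if (f <= tol) next
        prod[[p]] <- prod[[p]] - f; cons[[q]] <- cons[[q]] - f
        sgn <- if (p == ref_sp) 1 else if (q == ref_sp) -1 else
          if (p == "environment") -1 else 1
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = met, producer = p, consumer = q, flux = f,
          signed = sgn * f, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite = character(0), producer = character(0),
               consumer = character(0), flux = numeric(0),
               signed = numeric(0))
  out <- out[order(-out$flux), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("crossfeeding_records", "data.frame")
  out
}
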