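#' Solve a linear program
#'
#' Dense two-phase primal simplex with variable bounds. This is the numerical
#' engine behind [fba()], [fva()], [solve_steadycom()] and the dynamic
#' simulators; it is written for the moderate problem sizes of reduced
#' genome-scale models and favours robustness over speed: Dantzig pricing
#' with an automatic switch to Bland's rule when the objective stalls, so
#' degenerate community LPs cannot cycle.
#'
#' @param obj numeric objective coefficients (length n).
#' @param mat constraint matrix (m x n), dense or coercible.
#' @param dir character vector of row directions, each `"<="`, `">="` or `"="`.
#' @param rhs numeric right-hand sides (length m).
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"` or `"unbounded"`),
#'   `objective`, and `x` (the primal solution, `NA` unless optimal).
#' @export
solve_lp <- function(obj, mat, dir, rhs, lb, ub, maximize = TRUE,
                     tol = 1e-9) {
  n <- length(obj)
  mat <- as.matrix(mat)
  m <- nrow(mat)
  stopifnot(ncol(mat) == n, length(dir) == m, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub)) stop("lower bound exceeds upper bound")
  if (!all(dir %in% c("<=", ">=", "="))) stop("bad constraint direction")

  ## --- transform variables to y >= 0 ------------------------------------
  ## x_j = shift[j] + sgn[j] * y_j (bounded) or y+ - y- (free)
  shift <- numeric(n); sgn <- numeric(n)
  map <- vector("list", n)
  ncol_y <- 0L
  ub_var <- integer(0); ub_val <- numeric(0)
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      shift[j] <- lb[j]; sgn[j] <- 1
      ncol_y <- ncol_y + 1L; map[[j]] <- ncol_y
      if (is.finite(ub[j])) {
        ub_var <- c(ub_var, ncol_y); ub_val <- c(ub_val, ub[j] - lb[j])
      }
    } else if (is.finite(ub[j])) {
      shift[j] <- ub[j]; sgn[j] <- -1
      ncol_y <- ncol_y + 1L; map[[j]] <- ncol_y
    } else {
      sgn[j] <- NA
      map[[j]] <- c(ncol_y + 1L, ncol_y + 2L)
      ncol_y <- ncol_y + 2L
    }
  }
  A <- matrix(0, m, ncol_y)
  cy <- numeric(ncol_y)
  osgn <- if (maximize) -1 else 1            # internally minimize
  for (j in seq_len(n)) {
    idx <- map[[j]]
    if (length(idx) == 1L) {
      A[, idx] <- mat[, j] * sgn[j]
      cy[idx] <- osgn * obj[j] * sgn[j]
    } else {
      A[, idx[1]] <- mat[, j]; A[, idx[2]] <- -mat[, j]
      cy[idx[1]] <- osgn * obj[j]; cy[idx[2]] <- -osgn * obj[j]
    }
  }
  b <- rhs - as.numeric(mat %*% shift)

  if (length(ub_var)) {                       # upper-bound rows y_k <= u
    Aub <- matrix(0, length(ub_var), ncol_y)
    Aub[cbind(seq_along(ub_var), ub_var)] <- 1
    A <- rbind(A, Aub); b <- c(b, ub_val)
    dir <- c(dir, rep("<=", length(ub_var)))
    m <- nrow(A)
  }

  ## --- standard form ----------------------------------------------------
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }
  n_slack <- sum(dir != "=")
  slack_col <- integer(m); k <- 0L
  Asl <- matrix(0, m, n_slack)
  for (i in seq_len(m)) {
    if (dir[i] == "=") next
    k <- k + 1L
    Asl[i, k] <- if (dir[i] == "<=") 1 else -1
    slack_col[i] <- ncol_y + k
  }
  need_art <- dir != "<="
  n_art <- sum(need_art)
  Aart <- matrix(0, m, n_art)
  if (n_art) Aart[cbind(which(need_art), seq_len(n_art))] <- 1
  art_col <- ncol_y + n_slack + seq_len(n_art)

  Tab <- cbind(A, Asl, Aart, b)
  ntot <- ncol_y + n_slack + n_art
  basis <- integer(m)
  basis[!need_art] <- slack_col[!need_art]
  basis[need_art] <- art_col

  ## --- tableau simplex --------------------------------------------------
  pivot <- function(Tab, pr, pc) {
    piv <- Tab[pr, pc]
    Tab[pr, ] <- Tab[pr, ] / piv
    fac <- Tab[, pc]
    fac[pr] <- 0
    Tab <- Tab - outer(fac, Tab[pr, ])
    Tab[, pc] <- 0; Tab[pr, pc] <- 1
    Tab
  }
  run <- function(Tab, basis, costs, allowed) {
    m <- nrow(Tab) - 1L
    ptol <- 1e-8
    maxit <- 500L * (m + ntot)
    stall <- 0L; bland <- FALSE; last <- -Inf
    for (it in seq_len(maxit)) {
      r <- Tab[m + 1L, seq_len(ntot)]
      cand <- which(r < -ptol & allowed)
      if (!length(cand)) return(list(Tab = Tab, basis = basis, status = "optimal"))
      enter <- if (bland) cand[1] else cand[which.min(r[cand])]
      col <- Tab[seq_len(m), enter]
      pos <- which(col > ptol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratios <- Tab[pos, ntot + 1L] / col[pos]
      rmin <- min(ratios)
      lc <- pos[ratios <= rmin + 1e-10]
      leave <- lc[which.min(basis[lc])]
      Tab <- pivot(Tab, leave, enter)
      basis[leave] <- enter
      objv <- Tab[m + 1L, ntot + 1L]  # equals minus the phase objective
      if (objv > last + 1e-12) { stall <- 0L; last <- objv } else stall <- stall + 1L
      if (stall > 2L * m + 100L) bland <- TRUE
    }
    stop("simplex: iteration limit reached")
  }
  obj_row <- function(Tab, basis, costs) {
    m <- nrow(Tab) - 1L
    r <- c(costs, 0)
    cb <- costs[basis]
    nz <- which(cb != 0)
    for (i in nz) r <- r - cb[i] * Tab[i, ]
    Tab[m + 1L, ] <- r
    Tab
  }

  Tab <- rbind(Tab, 0)
  allowed <- rep(TRUE, ntot)

  if (n_art > 0L) {
    c1 <- numeric(ntot); c1[art_col] <- 1
    Tab <- obj_row(Tab, basis, c1)
    res <- run(Tab, basis, c1, allowed)
    if (res$status != "optimal") stop("phase-1 simplex failed")
    Tab <- res$Tab; basis <- res$basis
    if (Tab[m + 1L, ntot + 1L] < -1e-7)
      return(list(status = "infeasible", objective = NA_real_,
                  x = rep(NA_real_, n)))
    # drive zero-level artificials out of the basis where possible
    for (i in which(basis %in% art_col)) {
      repl <- which(abs(Tab[i, seq_len(ntot)]) > 1e-8 &
                      !(seq_len(ntot) %in% c(basis, art_col)))
      if (length(repl)) {
        Tab <- pivot(Tab, i, repl[1])
        basis[i] <- repl[1]
      }
    }
    allowed[art_col] <- FALSE
  }

  c2 <- c(cy, rep(0, n_slack + n_art))
  Tab <- obj_row(Tab, basis, c2)
  res <- run(Tab, basis, c2, allowed)
  if (res$status == "unbounded")
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))
  Tab <- res$Tab; basis <- res$basis

  xfull <- numeric(ntot)
  xfull[basis] <- Tab[seq_len(m), ntot + 1L]
  if (n_art > 0L && sum(abs(xfull[art_col])) > 1e-7)
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  y <- xfull[seq_len(ncol_y)]
  x <- numeric(n)
  for (j in seq_len(n)) {
    idx <- map[[j]]
    x[j] <- if (length(idx) == 1L) shift[j] + sgn[j] * y[idx]
            else y[idx[1]] - y[idx[2]]
  }
  list(status = "optimal", objective = sum(obj * x), x = x)
}
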