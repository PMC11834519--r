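# Dense two-phase simplex for the small linear programs arising in the
# slacks-based DEA model (tens of constraints, around a hundred variables).
# Bland's pivoting rule throughout: finite termination on the heavily
# degenerate LPs this model produces, and a fully deterministic pivot path,
# so repeated runs give byte-identical solutions.

#' Solve a small dense linear program
#'
#' Maximises (or minimises) `obj %*% x` subject to `A x (dir) b` and
#' `x >= 0`, where `dir` is a vector of `"<="`, `">="` or `"="` per row.
#' Intended for internal use by the DEA solver; exported because the
#' formulation function for the slack-maximisation program is documented
#' in terms of it and because it is convenient for cross-checks.
#'
#' @param obj numeric objective coefficients, one per structural variable.
#' @param A constraint matrix (rows = constraints).
#' @param b right-hand side; rows with negative `b` are flipped internally.
#' @param dir character vector of constraint directions per row.
#' @param maximize logical; maximise when `TRUE` (default).
#' @param tol pivot/feasibility tolerance (default `1e-9`, applied to the
#'   internally rescaled problem).
#' @param max_iter safety cap on simplex pivots.
#' @return list with `x` (structural solution), `value` (objective at `x`
#'   on the original scale) and `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"` or `"iteration_limit"`).
#' @examples
#' # max x1 + x2 s.t. x1 + 2 x2 <= 4, x1 <= 3
#' lp_solve(c(1, 1), rbind(c(1, 2), c(1, 0)), c(4, 3), c("<=", "<="))$value
#' @export
lp_solve <- function(obj, A, b, dir, maximize = TRUE, tol = 1e-9,
                     max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(dir) == m,
            all(dir %in% c("<=", ">=", "=")))

  # flip rows so every right-hand side is nonnegative
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  # scale rows to unit max coefficient: keeps the fixed absolute tolerance
  # meaningful whatever the data units are
  rs <- pmax(apply(abs(A), 1, max), abs(b))
  rs[rs == 0] <- 1
  A <- A / rs
  b <- b / rs

  cmin <- if (maximize) -obj else obj

  n_le <- sum(dir == "<=")
  n_ge <- sum(dir == ">=")
  n_eq <- sum(dir == "=")
  n_art <- n_ge + n_eq
  nv <- n + n_le + n_ge + n_art

  Tm <- matrix(0, m, nv)
  Tm[, seq_len(n)] <- A
  rhs <- b
  basis <- integer(m)
  k_sl <- 0L
  k_su <- 0L
  k_ar <- 0L
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      k_sl <- k_sl + 1L
      col <- n + k_sl
      Tm[i, col] <- 1
      basis[i] <- col
    } else {
      if (dir[i] == ">=") {
        k_su <- k_su + 1L
        Tm[i, n + n_le + k_su] <- -1
      }
      k_ar <- k_ar + 1L
      col <- n + n_le + n_ge + k_ar
      Tm[i, col] <- 1
      basis[i] <- col
    }
  }
  art_cols <- if (n_art > 0L) n + n_le + n_ge + seq_len(n_art) else integer(0)
  A_cols <- Tm   # untouched copy of the standard-form columns
  b0 <- rhs

  env <- new.env(parent = emptyenv())
  env$Tm <- Tm
  env$rhs <- rhs
  env$basis <- basis

  piv_tol <- 1e-7  # entries below this (on row-scaled data) are treated as
                   # noise: pivoting on them corrupts the tableau

  run <- function(cost, blocked) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return("iteration_limit")
      red <- cost - as.vector(cost[env$basis] %*% env$Tm)
      red[blocked] <- 0
      improving <- which(red < -tol)
      if (length(improving) == 0L) return("optimal")
      # Bland order over improving columns, preferring the first that offers
      # a numerically clean pivot row; fall back to a tiny pivot only when
      # no improving column has one
      ent <- NA_integer_
      pos <- integer(0)
      for (j in improving) {
        pj <- which(env$Tm[, j] > piv_tol)
        if (length(pj) > 0L) { ent <- j; pos <- pj; break }
      }
      if (is.na(ent)) {
        for (j in improving) {
          pj <- which(env$Tm[, j] > tol)
          if (length(pj) > 0L) { ent <- j; pos <- pj; break }
        }
      }
      if (is.na(ent)) return("unbounded")
      colv <- env$Tm[, ent]
      ratios <- env$rhs[pos] / colv[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin * (1 + 1e-9) + tol]
      # among (near-)tied rows take the numerically safest (largest) pivot;
      # lowest basis index breaks exact ties deterministically
      cand <- cand[order(-colv[cand], env$basis[cand])]
      leave <- cand[1L]
      pv <- env$Tm[leave, ent]
      env$Tm[leave, ] <- env$Tm[leave, ] / pv
      env$rhs[leave] <- env$rhs[leave] / pv
      f <- env$Tm[, ent]
      f[leave] <- 0
      env$Tm <- env$Tm - outer(f, env$Tm[leave, ])
      env$rhs <- pmax(env$rhs - f * env$rhs[leave], 0)
      env$basis[leave] <- ent
    }
  }

  blocked <- rep(FALSE, nv)
  if (n_art > 0L) {
    cost1 <- rep(0, nv)
    cost1[art_cols] <- 1
    st <- run(cost1, blocked)
    if (st != "optimal") return(list(x = NULL, value = NA_real_, status = st))
    if (sum(env$rhs[env$basis %in% art_cols]) > 1e-7)
      return(list(x = NULL, value = NA_real_, status = "infeasible"))
    # pivot any (degenerate) artificial out of the basis where possible,
    # on the largest-magnitude eligible entry
    for (i in which(env$basis %in% art_cols)) {
      row <- env$Tm[i, ]
      row[art_cols] <- 0
      piv <- which(abs(row) > piv_tol)
      if (length(piv) == 0L) piv <- which(abs(row) > tol)
      if (length(piv) > 0L) {
        ent <- piv[which.max(abs(row[piv]))]
        pv <- env$Tm[i, ent]
        env$Tm[i, ] <- env$Tm[i, ] / pv
        env$rhs[i] <- env$rhs[i] / pv
        f <- env$Tm[, ent]
        f[i] <- 0
        env$Tm <- env$Tm - outer(f, env$Tm[i, ])
        env$rhs <- pmax(env$rhs - f * env$rhs[i], 0)
        env$basis[i] <- ent
      }
    }
    # an artificial still basic marks a (numerically) redundant row: drop it,
    # otherwise later pivots could silently push the artificial off zero
    still <- which(env$basis %in% art_cols)
    if (length(still) > 0L) {
      env$Tm <- env$Tm[-still, , drop = FALSE]
      env$rhs <- env$rhs[-still]
      env$basis <- env$basis[-still]
      A_cols <- A_cols[-still, , drop = FALSE]
      b0 <- b0[-still]
    }
    blocked[art_cols] <- TRUE
  }

  cost2 <- c(cmin, rep(0, nv - n))
  st <- run(cost2, blocked)
  if (st != "optimal") return(list(x = NULL, value = NA_real_, status = st))

  # the tableau accumulates rounding error over pivots (small pivot elements
  # amplify it); re-solve the final basic system against the original
  # columns so the returned vertex is accurate to machine precision
  x <- rep(0, nv)
  xb <- tryCatch(qr.solve(A_cols[, env$basis, drop = FALSE], b0),
                 error = function(e) NULL)
  if (!is.null(xb) && all(xb > -1e-7)) x[env$basis] <- pmax(xb, 0)
  else x[env$basis] <- env$rhs
  # guard against silent corruption: the returned point must satisfy the
  # standard-form system (artificials at zero) to working precision
  if (max(abs(as.vector(A_cols %*% x) - b0)) > 1e-6 ||
      (n_art > 0L && any(x[art_cols] > 1e-6)))
    return(list(x = NULL, value = NA_real_, status = "numerical_failure"))
  x <- x[seq_len(n)]
  list(x = x, value = sum(obj * x), status = "optimal")
}
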