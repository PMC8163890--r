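# Internal linear-programming solver.
#
# Solves  max/min  obj' v
#         s.t.     Aeq v  = beq
#                  Aub v <= bub      (optional; slack variables added)
#                  lb <= v <= ub     (lb finite; ub may be +Inf)
#
# via a bounded-variable two-phase primal simplex with Bland's rule
# (anti-cycling). Dense and unoptimized on purpose: consortium-design
# models are small (tens to a few hundred reactions), and correctness is
# cross-checked against an exhaustive vertex-enumeration oracle in the
# test suite. Written in-package because no installed LP routine handles
# the degenerate zero-RHS equality systems of flux balance analysis.
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                     lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) abort("LP lower bounds must be finite")
  if (any(lb > ub)) abort("LP lower bound exceeds upper bound")

  A <- NULL
  b <- numeric(0)
  if (!is.null(Aeq)) {
    A <- Aeq
    b <- beq
  }
  n_slack <- 0L
  if (!is.null(Aub) && nrow(Aub) > 0) {
    n_slack <- nrow(Aub)
    slack <- diag(n_slack)
    if (is.null(A)) {
      A <- cbind(Aub, slack)
      b <- bub
    } else {
      A <- rbind(
        cbind(A, matrix(0, nrow(A), n_slack)),
        cbind(Aub, slack)
      )
      b <- c(b, bub)
    }
    lb <- c(lb, rep(0, n_slack))
    ub <- c(ub, rep(Inf, n_slack))
    obj <- c(obj, rep(0, n_slack))
  }
  if (is.null(A)) {
    # pure box problem
    v <- ifelse(if (maximize) obj > 0 else obj < 0, ub, lb)
    v[!is.finite(v)] <- 0
    return(list(status = "optimal", objective = sum(obj * v), solution = v[seq_len(n)]))
  }
  if (!maximize) obj <- -obj
  res <- simplex_bounded(obj, A, b, lb, ub)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_,
      solution = rep(NA_real_, n)))
  }
  v <- res$x[seq_len(n)]
  objective <- sum((if (maximize) obj else -obj)[seq_len(n)] * v)
  list(status = "optimal", objective = objective, solution = v)
}

# Maximize c'x s.t. A x = b, lb <= x <= ub (lb finite), two-phase.
simplex_bounded <- function(cc, A, b, lb, ub, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  # phase 1: artificials with columns sign(r) * e_i
  x <- lb
  r <- b - as.numeric(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  A1 <- cbind(A, diag(sgn, m))
  lb1 <- c(lb, rep(0, m))
  ub1 <- c(ub, rep(Inf, m))
  x1 <- c(x, abs(r))
  basis <- n + seq_len(m)
  at_ub <- rep(FALSE, n + m)
  c1 <- c(rep(0, n), rep(-1, m))

  ph1 <- simplex_iterate(c1, A1, lb1, ub1, x1, basis, at_ub, tol, max_iter)
  if (ph1$status != "optimal") return(list(status = ph1$status))
  if (sum(ph1$x[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible"))
  }
  # phase 2: freeze artificials at 0
  ub1[n + seq_len(m)] <- 0
  x1 <- ph1$x
  x1[n + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  ph2 <- simplex_iterate(c2, A1, lb1, ub1, x1, ph1$basis, ph1$at_ub, tol, max_iter)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  list(status = "optimal", x = ph2$x[seq_len(n)])
}

# One run of the bounded-variable primal simplex (maximization), Bland's
# rule for entering and leaving choices.
simplex_iterate <- function(cc, A, lb, ub, x, basis, at_ub, tol, max_iter) {
  m <- nrow(A)
  N <- ncol(A)
  for (iter in seq_len(max_iter)) {
    Bmat <- A[, basis, drop = FALSE]
    y <- tryCatch(solve(t(Bmat), cc[basis]), error = function(e) NULL)
    if (is.null(y)) return(list(status = "singular_basis"))
    in_basis <- logical(N)
    in_basis[basis] <- TRUE
    d <- cc - as.numeric(crossprod(A, y))
    eligible <- which(!in_basis &
      ((!at_ub & d > tol & lb < ub) | (at_ub & d < -tol)))
    if (length(eligible) == 0) {
      return(list(status = "optimal", x = x, basis = basis, at_ub = at_ub))
    }
    j <- min(eligible) # Bland
    w <- solve(Bmat, A[, j])
    dir <- if (at_ub[j]) -1 else 1
    delta_B <- -dir * w
    xB <- x[basis]
    ratio <- rep(Inf, m)
    dec <- delta_B < -tol
    inc <- delta_B > tol
    ratio[dec] <- (xB[dec] - lb[basis[dec]]) / (-delta_B[dec])
    ratio[inc] <- (ub[basis[inc]] - xB[inc]) / delta_B[inc]
    t_own <- ub[j] - lb[j]
    t_basic <- if (any(is.finite(ratio))) min(ratio) else Inf
    t_star <- min(t_basic, t_own)
    if (!is.finite(t_star)) return(list(status = "unbounded"))
    t_star <- max(t_star, 0)
    x[j] <- x[j] + dir * t_star
    x[basis] <- xB + t_star * delta_B
    if (t_own <= t_basic) {
      # entering variable crossed its whole span: bound flip, basis kept
      at_ub[j] <- !at_ub[j]
    } else {
      # basis change; Bland tie-break on the leaving variable's index
      cand <- which(ratio <= t_basic + tol)
      leave_pos <- cand[which.min(basis[cand])]
      leave_var <- basis[leave_pos]
      x[leave_var] <- if (delta_B[leave_pos] < 0) lb[leave_var] else ub[leave_var]
      at_ub[leave_var] <- delta_B[leave_pos] >= 0
      basis[leave_pos] <- j
      at_ub[j] <- FALSE
    }
  }
  list(status = "iteration_limit")
}

# Stoichiometric matrix (metabolites x reactions) of a strain or community
# model in its stated metabolite/reaction order.
stoich_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
    dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(rxn_ids)) {
    s <- model$reactions$stoichiometry[[j]]
    S[names(s), j] <- s
  }
  S
}
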