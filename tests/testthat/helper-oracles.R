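# Independent oracles used across the suite. These deliberately share no
# code with the package's solvers.

# Exhaustive vertex-enumeration LP oracle for max c'v s.t. S v = 0,
# l <= v <= u: every vertex has n - rank(S) variables at a bound; enumerate
# all such fixings, solve the square system for the rest, keep feasible
# points, return the best objective. Exponential, for tiny networks only.
oracle_lp_max <- function(cc, S, l, u) {
  n <- length(cc)
  r <- qr(S)$rank
  k <- n - r
  best <- -Inf
  fixsets <- if (k == 0) list(integer(0)) else combn(n, k, simplify = FALSE)
  for (fix in fixsets) {
    free <- setdiff(seq_len(n), fix)
    Sf <- S[, free, drop = FALSE]
    if (length(free) > 0 && qr(Sf)$rank < length(free)) next
    grid <- if (k == 0) matrix(0, 1, 0) else
      as.matrix(expand.grid(rep(list(c(1, 2)), k)))
    for (g in seq_len(nrow(grid))) {
      vfix <- if (k == 0) numeric(0) else ifelse(grid[g, ] == 1, l[fix], u[fix])
      rhs <- if (k == 0) rep(0, nrow(S)) else -as.numeric(S[, fix, drop = FALSE] %*% vfix)
      vfree <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
      if (is.null(vfree)) next
      v <- numeric(n)
      if (k > 0) v[fix] <- vfix
      v[free] <- vfree
      if (all(v >= l - 1e-8) && all(v <= u + 1e-8) &&
          max(abs(S %*% v)) < 1e-7) {
        best <- max(best, sum(cc * v))
      }
    }
  }
  best
}

# FBA oracle: vertex enumeration on a strain model + medium.
oracle_fba <- function(model, med) {
  model <- apply_medium(model, med)
  S <- consortia:::stoich_matrix(model)
  cc <- as.numeric(model$reactions$id == model$biomass_reaction_id)
  oracle_lp_max(cc, S, model$reactions$lb, model$reactions$ub)
}

# Positional mismatch fraction between two equal-length sequences — the
# exact divergence oracle for substitution-only mutated pairs.
oracle_mismatch_fraction <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca != cb)
}
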