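# Independent oracles: brute-force or closed-form implementations kept
# deliberately separate from the package's own algorithms.

# --- LP oracle: enumerate candidate vertices (n - m variables at a bound,
# solve the equality system for the rest); exact for full-row-rank A -------
lp_enum <- function(cc, A, b, lb, ub, maximize = TRUE) {
  m <- nrow(A); n <- ncol(A)
  if (m > 0 && qr(A)$rank < m) {
    keep <- qr(t(A))$pivot[seq_len(qr(A)$rank)]
    A <- A[keep, , drop = FALSE]; b <- b[keep]; m <- nrow(A)
  }
  best <- NA_real_
  combs <- combn(n, n - m)
  for (k in seq_len(ncol(combs))) {
    nb <- combs[, k]; bas <- setdiff(seq_len(n), nb)
    B <- A[, bas, drop = FALSE]
    if (m > 0 && abs(det(B)) < 1e-9) next
    grid <- as.matrix(expand.grid(rep(list(c(1L, 2L)), length(nb))))
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      x[nb] <- ifelse(grid[g, ] == 1L, lb[nb], ub[nb])
      rhs <- b - A[, nb, drop = FALSE] %*% x[nb]
      if (m > 0) x[bas] <- solve(B, rhs)
      if (all(x >= lb - 1e-7) && all(x <= ub + 1e-7)) {
        z <- sum(cc * x)
        if (is.na(best) || (maximize && z > best) ||
            (!maximize && z < best)) best <- z
      }
    }
  }
  best
}

# biomass-maximization oracle: rebuilds the flux problem from the stated
# bound rules (independently of build_problem) and solves by enumeration
fba_oracle_Z <- function(u, g, env, U = 1000) {
  S <- as.matrix(u$S)
  n <- length(u$rxn_ids)
  lb <- numeric(n); ub <- numeric(n)
  ub[g$bits] <- U
  lb[g$bits & u$reversible] <- -U
  for (k in which(u$role == "exchange")) {
    if (!g$bits[k]) next
    met <- u$met_ids[which(S[, k] != 0)]
    lb[k] <- if (met %in% env$importable) -U else 0
  }
  cc <- as.numeric(u$role == "biomass")
  cols <- which(g$bits)
  Ssub <- S[, cols, drop = FALSE]
  Ssub <- Ssub[rowSums(Ssub != 0) > 0, , drop = FALSE]
  z <- lp_enum(cc[cols], Ssub, numeric(nrow(Ssub)), lb[cols], ub[cols],
               maximize = TRUE)
  if (is.na(z)) 0 else z
}

# --- coupling oracles over the analysis network ---------------------------
null_basis <- function(S, tol = 1e-9) {
  sv <- svd(S, nu = 0, nv = ncol(S))
  d <- c(sv$d, rep(0, ncol(S) - length(sv$d)))
  sv$v[, d < tol * max(1, max(d)), drop = FALSE]
}

# classes of mutually fully coupled reactions from proportional (up to
# sign) nonzero rows of a null-space basis, restricted to `idx`
nullspace_classes <- function(S, idx, tol = 1e-6) {
  N <- null_basis(S)
  rows <- N[idx, , drop = FALSE]
  nrm <- sqrt(rowSums(rows^2))
  alive <- nrm > 1e-8
  unit <- rows
  unit[alive, ] <- rows[alive, , drop = FALSE] / nrm[alive]
  for (i in which(alive)) {
    piv <- which(abs(unit[i, ]) > 1e-8)[1]
    if (unit[i, piv] < 0) unit[i, ] <- -unit[i, ]
  }
  cls <- rep(NA_integer_, length(idx)); nxt <- 0L
  for (i in seq_along(idx)) {
    if (!alive[i] || !is.na(cls[i])) next
    nxt <- nxt + 1L; cls[i] <- nxt
    for (j in seq_along(idx)) {
      if (j <= i || !alive[j] || !is.na(cls[j])) next
      if (max(abs(unit[i, ] - unit[j, ])) < tol ||
          max(abs(unit[i, ] + unit[j, ])) < tol) cls[j] <- nxt
    }
  }
  cls
}

# Monte-Carlo ratio oracle: random flux vectors in the null space; two
# reactions are coupled when their ratio has (numerically) zero variance
# and is nonzero
mc_ratio_classes <- function(S, idx, n_samples = 1e4, tol = 1e-6) {
  N <- null_basis(S)
  if (ncol(N) == 0) return(rep(NA_integer_, length(idx)))
  V <- N %*% matrix(rnorm(ncol(N) * n_samples), ncol(N))
  V <- V[idx, , drop = FALSE]
  alive <- apply(abs(V), 1, max) > 1e-7
  coupled <- function(i, j) {
    ok <- abs(V[j, ]) > 1e-8
    if (sum(ok) < n_samples / 2) return(FALSE)
    r <- V[i, ok] / V[j, ok]
    md <- stats::median(r)
    abs(md) > tol && max(abs(r - md)) < tol * max(1, abs(md))
  }
  cls <- rep(NA_integer_, length(idx)); nxt <- 0L
  for (i in seq_along(idx)) {
    if (!alive[i] || !is.na(cls[i])) next
    nxt <- nxt + 1L; cls[i] <- nxt
    for (j in seq_along(idx))
      if (j > i && alive[j] && is.na(cls[j]) && coupled(i, j))
        cls[j] <- nxt
  }
  cls
}

# turn class labels into a partition (sets of ids, size >= 2, sorted)
classes_to_sets <- function(ids, cls) {
  out <- list()
  for (g in split(ids, cls)) if (length(g) >= 2) out <- c(out, list(sort(g)))
  out[order(vapply(out, `[`, character(1), 1))]
}

partition_sets <- function(p) p$sets

# --- h-index oracle: dense grid scan of sup{x : frac(Q >= x) >= x} --------
h_grid <- function(q, w = rep(1, length(q)), step = 1e-4) {
  xs <- seq(0, 1, by = step)
  ok <- vapply(xs, function(x) sum(w[q >= x]) / sum(w) >= x, logical(1))
  max(xs[ok])
}

# --- scope oracle: dependency-depth DP on acyclic irreversible networks ---
scope_depth_oracle <- function(u, seed_mets) {
  rx <- which(u$role == "metabolic")
  subs <- lapply(rx, function(k) u$met_ids[u$S[, k] < 0])
  prods <- lapply(rx, function(k) u$met_ids[u$S[, k] > 0])
  met_depth <- setNames(rep(Inf, length(u$met_ids)), u$met_ids)
  met_depth[seed_mets] <- 0
  fire <- setNames(rep(NA_real_, length(rx)), u$rxn_ids[rx])
  repeat {
    changed <- FALSE
    for (i in seq_along(rx)) {
      d <- if (length(subs[[i]])) max(met_depth[subs[[i]]]) else 0
      if (is.finite(d)) {
        f <- d + 1
        if (is.na(fire[i]) || f < fire[i]) { fire[i] <- f; changed <- TRUE }
        for (p in prods[[i]])
          if (f < met_depth[p]) { met_depth[p] <- f; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  fire
}
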