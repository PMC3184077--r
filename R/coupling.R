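# ---------------------------------------------------------------------------
# Flux coupling analysis: pairwise full-coupling detection and the partition
# of a genotype's unblocked metabolic reactions into fully coupled sets.
# ---------------------------------------------------------------------------

FM_EPS_COUPLE <- 1e-9

#' Build the analysis network for coupling and variability
#'
#' Returns the dense stoichiometric matrix and bounds actually optimized
#' over: columns are the genotype's present reactions, optionally with the
#' biomass reaction removed and replaced by one independent, irreversible
#' sink per biomass precursor (couplings are computed without assuming a
#' fixed biomass composition), and optionally with every exchange opened in
#' both directions.  Exposed so that independent oracles can inspect the
#' exact polytope used.
#'
#' @inheritParams build_problem
#' @param open_exchanges open all exchange reactions for import + secretion.
#' @param decouple_biomass drop the biomass column, add per-precursor sinks.
#' @return list with dense `S`, `lb`, `ub`, column `ids` and `kind`
#'   (`"metabolic"`, `"exchange"`, `"sink"`).
#' @export
analysis_network <- function(universe, g, open_exchanges = TRUE,
                             decouple_biomass = TRUE, U = FM_U) {
  pb <- build_problem(universe, g,
                      environment = if (open_exchanges) NULL else
                        growth_environment("closed", character(0)),
                      objective = list(reaction = universe$rxn_ids[1],
                                       sense = 1),
                      U = U)
  keep <- g$bits
  if (decouple_biomass) keep <- keep & universe$role != "biomass"
  cols <- which(keep)
  Sd <- dense_S(universe)[, cols, drop = FALSE]
  ids <- universe$rxn_ids[cols]
  kind <- ifelse(universe$role[cols] == "exchange", "exchange", "metabolic")
  lb <- pb$lb[cols]; ub <- pb$ub[cols]
  if (decouple_biomass && length(universe$biomass_precursors)) {
    prec <- names(universe$biomass_precursors)
    sinks <- matrix(0, nrow(Sd), length(prec))
    sinks[cbind(match(prec, universe$met_ids), seq_along(prec))] <- -1
    Sd <- cbind(Sd, sinks)
    ids <- c(ids, paste0(".sink_", prec))
    kind <- c(kind, rep("sink", length(prec)))
    lb <- c(lb, numeric(length(prec)))
    ub <- c(ub, rep(U, length(prec)))
  }
  nz <- rowSums(Sd != 0) > 0
  list(S = Sd[nz, , drop = FALSE], lb = lb, ub = ub, ids = ids, kind = kind)
}

# flux-ratio extremes for columns i1, i2 of an analysis network:
# fix v2 = 1 (falling back to v2 = -1 for reversible r2) and min/max v1
coupling_bounds_net <- function(net, i1, i2) {
  solve_dir <- function(val) {
    lb <- net$lb; ub <- net$ub
    lb[i2] <- val; ub[i2] <- val
    cc <- numeric(length(lb)); cc[i1] <- 1
    hi <- .simplex_solve(cc, net$S, numeric(nrow(net$S)), lb, ub, TRUE)
    if (hi$status != 0L) return(NULL)
    lo <- .simplex_solve(cc, net$S, numeric(nrow(net$S)), lb, ub, FALSE)
    if (lo$status != 0L) return(NULL)
    list(Rmin = lo$z / val, Rmax = hi$z / val)
  }
  r <- solve_dir(1)
  if (is.null(r) && net$lb[i2] < 0) {
    r <- solve_dir(-1)
    if (!is.null(r)) r <- list(Rmin = min(r$Rmin, r$Rmax),
                               Rmax = max(r$Rmin, r$Rmax))
  }
  if (is.null(r))
    return(structure(list(Rmin = NA_real_, Rmax = NA_real_,
                          feasible = FALSE), class = "coupling_bounds"))
  structure(list(Rmin = r$Rmin, Rmax = r$Rmax, feasible = TRUE),
            class = "coupling_bounds")
}

#' Flux-ratio bounds for a reaction pair
#'
#' Computes the extreme values of the flux ratio `v1/v2` over all steady
#' states of the analysis network, by fixing `v2 = 1` and minimizing /
#' maximizing `v1` (two LPs).  If `v2 = 1` is infeasible and r2 is
#' reversible the pair is re-solved with `v2 = -1` and the ratios negated.
#'
#' @inheritParams build_problem
#' @param r1,r2 distinct reaction ids, both present.
#' @param eps tolerance (see [fully_coupled()]).
#' @return list of class `coupling_bounds` with `Rmin`, `Rmax`, `feasible`.
#' @export
coupling_bounds <- function(universe, g, r1, r2, U = FM_U,
                            eps = FM_EPS_COUPLE) {
  if (identical(r1, r2))
    fm_error("fm_parse_error", "r1 and r2 must differ")
  net <- analysis_network(universe, g, TRUE, TRUE, U)
  i1 <- match(r1, net$ids); i2 <- match(r2, net$ids)
  if (is.na(i1) || is.na(i2))
    fm_error("fm_unknown_reaction", "r1/r2 not present in the network")
  coupling_bounds_net(net, i1, i2)
}

#' Decide full coupling from ratio bounds
#'
#' Two fluxes are fully coupled when their ratio is fixed and nonzero over
#' all steady states: the pair is feasible, `Rmax == Rmin` up to a relative
#' tolerance, and the common ratio is nonzero (a ratio locked at zero means
#' r1 is off whenever r2 runs, which is not mutual coupling).
#'
#' @param bounds a `coupling_bounds` object.
#' @param eps relative tolerance.
#' @return logical scalar.
#' @export
fully_coupled <- function(bounds, eps = FM_EPS_COUPLE) {
  isTRUE(bounds$feasible) &&
    abs(bounds$Rmax - bounds$Rmin) <= eps * max(1, abs(bounds$Rmax)) &&
    abs(bounds$Rmax) > eps
}

#' Partition a genotype's reactions into fully coupled sets
#'
#' Excludes blocked reactions, then treats full coupling as the equivalence
#' relation it is (reflexive, symmetric, transitive) on the genotype's
#' unblocked metabolic reactions: each reaction is tested by LP against one
#' representative per existing class, so the LP count grows with the number
#' of classes rather than quadratically.  Sets of size one are not modules
#' and are dropped.  Analysis conditions: all exchanges open in both
#' directions and biomass replaced by per-precursor sinks (sinks and
#' exchanges never appear in the reported sets).
#'
#' @inheritParams build_problem
#' @param eps relative coupling tolerance.
#' @param exhaustive verification mode: test all O(n^2) pairs and derive
#'   the partition from the full coupling graph, asserting that it is a
#'   disjoint union of cliques.
#' @return object of class `fcs_partition`: list with `sets` (list of
#'   character vectors, each of size >= 2), `M` (reactions in sets), `s`
#'   (number of sets), and `blocked` (excluded reaction ids).
#' @export
fcs_partition <- function(universe, g, U = FM_U, eps = FM_EPS_COUPLE,
                          exhaustive = FALSE) {
  net <- analysis_network(universe, g, TRUE, TRUE, U)
  cand <- net$ids[net$kind == "metabolic"]
  idx <- match(cand, net$ids)

  # flux variability over the candidates; the optimal vertices double as
  # witness flux vectors that later prove most pairs uncoupled without LPs
  nn <- length(net$ids)
  zero_rhs <- numeric(nrow(net$S))
  lo <- hi <- numeric(length(cand))
  W <- matrix(0, nn, 0)
  for (k in seq_along(cand)) {
    cc <- numeric(nn); cc[idx[k]] <- 1
    smin <- .simplex_solve(cc, net$S, zero_rhs, net$lb, net$ub, FALSE)
    smax <- .simplex_solve(cc, net$S, zero_rhs, net$lb, net$ub, TRUE)
    lo[k] <- if (smin$status == 0L) smin$z else NA_real_
    hi[k] <- if (smax$status == 0L) smax$z else NA_real_
    if (smin$status == 0L) W <- cbind(W, smin$x)
    if (smax$status == 0L) W <- cbind(W, smax$x)
  }
  is_blocked <- !is.na(lo) & !is.na(hi) &
    hi <= FM_EPS_BLOCKED & lo >= -FM_EPS_BLOCKED
  blocked <- cand[is_blocked]
  cand <- cand[!is_blocked]
  idx <- idx[!is_blocked]

  # witness-based disproof of full coupling: a steady state where one flux
  # runs and the other does not, or two states with different ratios
  witness_uncoupled <- function(a, b) {
    va <- W[a, ]; vb <- W[b, ]
    tol <- 1e-6
    on_a <- abs(va) > tol; on_b <- abs(vb) > tol
    if (any(on_a != on_b)) return(TRUE)
    both <- on_a & on_b
    if (!any(both)) return(FALSE)
    r <- va[both] / vb[both]
    (max(r) - min(r)) > 1e-6 * max(1, abs(max(r)))
  }

  sets <- list()
  if (length(cand) >= 2L) {
    if (exhaustive) {
      adj <- matrix(FALSE, length(cand), length(cand))
      for (a in seq_along(cand)) for (b in seq_len(a - 1L)) {
        cb <- coupling_bounds_net(net, idx[a], idx[b])
        adj[a, b] <- adj[b, a] <- fully_coupled(cb, eps)
      }
      comp <- integer(length(cand)); cur <- 0L
      for (a in seq_along(cand)) if (comp[a] == 0L) {
        cur <- cur + 1L
        queue <- a
        while (length(queue)) {
          x <- queue[1]; queue <- queue[-1]
          if (comp[x]) next
          comp[x] <- cur
          queue <- c(queue, which(adj[x, ] & comp == 0L))
        }
      }
      for (cl in split(seq_along(cand), comp)) {
        if (length(cl) < 2L) next
        for (a in cl) for (b in cl) if (a < b && !adj[a, b])
          fm_error("fm_coupling_inconsistent",
                   "full-coupling graph component is not a clique")
        sets <- c(sets, list(cand[cl]))
      }
    } else {
      class_rep <- integer(0)          # index into cand of each class rep
      class_of <- integer(length(cand))
      for (a in seq_along(cand)) {
        assigned <- FALSE
        for (ci in seq_along(class_rep)) {
          if (witness_uncoupled(idx[a], idx[class_rep[ci]])) next
          cb <- coupling_bounds_net(net, idx[a], idx[class_rep[ci]])
          if (fully_coupled(cb, eps)) {
            class_of[a] <- ci; assigned <- TRUE; break
          }
        }
        if (!assigned) {
          class_rep <- c(class_rep, a)
          class_of[a] <- length(class_rep)
        }
      }
      for (cl in split(seq_along(cand), class_of))
        if (length(cl) >= 2L) sets <- c(sets, list(cand[cl]))
    }
  }
  sets <- lapply(sets, sort)
  sets <- sets[order(vapply(sets, `[`, character(1), 1))]
  part <- structure(list(sets = sets,
                         M = sum(lengths(sets)),
                         s = length(sets),
                         blocked = sort(blocked)),
                    class = "fcs_partition")
  stopifnot(!anyDuplicated(unlist(part$sets)),
            all(lengths(part$sets) >= 2L))
  part
}

#' Modularity indices of a partition
#'
#' `M` is the number of reactions contained in fully coupled sets, `s` the
#' number of sets; an empty partition has `M = s = 0`.
#'
#' @param partition an `fcs_partition`.
#' @return named numeric vector `c(M =, s =)`.
#' @export
modularity_indices <- function(partition) {
  c(M = partition$M, s = partition$s)
}

#' @export
print.fcs_partition <- function(x, ...) {
  cat("<fcs_partition> s =", x$s, "sets, M =", x$M, "reactions",
      sprintf("(%d blocked excluded)\n", length(x$blocked)))
  invisible(x)
}
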