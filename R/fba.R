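# ---------------------------------------------------------------------------
# Flux balance analysis on the built-in bounded-variable simplex.
#
# All fluxes live in [-U, U] with U = 1000 ("unlimited" nutrient supply is
# represented by an uptake bound of -U), so every LP is bounded and v = 0 is
# always feasible for a biomass maximization.
# ---------------------------------------------------------------------------

FM_U <- 1000          # generic flux bound
FM_EPS_VIAB <- 1e-6   # biomass flux above this counts as viable
FM_EPS_BLOCKED <- 1e-6

# exchange reaction -> its (single) external metabolite, cached
exchange_metabolites <- function(u) {
  em <- u$cache$ex_met
  if (is.null(em)) {
    ex <- which(u$role == "exchange")
    em <- vapply(ex, function(k) u$met_ids[which(u$S[, k] != 0)[1]],
                 character(1))
    names(em) <- u$rxn_ids[ex]
    u$cache$ex_met <- em
  }
  em
}

# dense copy of S, cached inside the universe (the simplex is dense)
dense_S <- function(u) {
  d <- u$cache$S_dense
  if (is.null(d)) {
    d <- as.matrix(u$S)
    u$cache$S_dense <- d
  }
  d
}

#' Assemble the flux problem for a genotype in an environment
#'
#' Builds objective and flux bounds over the universe's reactions: absent
#' reactions are pinned to zero; present irreversible reactions get
#' `[0, U]`, reversible ones `[-U, U]`; exchange reactions may always
#' secrete (`[0, U]`) and may import (lower bound `-U`) only the
#' metabolites listed as importable in the environment.
#'
#' @param universe a [reaction_universe()].
#' @param g an [genotype()].
#' @param environment a [growth_environment()], or `NULL` to open every
#'   exchange in both directions (the convention used for coupling and
#'   blocked-reaction analysis).
#' @param objective `"biomass"`, or a list `list(reaction =, sense = 1|-1)`
#'   to optimize a single flux.
#' @param U generic flux bound.
#' @return list with `c`, `lb`, `ub` (per-reaction vectors) of class
#'   `flux_problem`.
#' @export
build_problem <- function(universe, g, environment = NULL,
                          objective = "biomass", U = FM_U) {
  n <- length(universe$rxn_ids)
  lb <- numeric(n); ub <- numeric(n)
  pres <- g$bits
  ub[pres] <- U
  lb[pres & universe$reversible] <- -U
  ex <- universe$role == "exchange"
  lb[pres & ex] <- 0                      # secretion only by default
  if (!is.null(environment)) {
    em <- exchange_metabolites(universe)  # exchange id -> metabolite id
    open <- ex & pres &
      (universe$rxn_ids %in% names(em)[em %in% environment$importable])
    lb[open] <- -U
  } else {
    lb[pres & ex] <- -U                   # all exchanges open
  }
  cc <- numeric(n)
  if (identical(objective, "biomass")) {
    bio <- which(universe$role == "biomass")
    if (length(bio) != 1L)
      fm_error("fm_no_biomass", "universe has no biomass reaction")
    cc[bio] <- 1
  } else {
    idx <- match(objective$reaction, universe$rxn_ids)
    if (is.na(idx))
      fm_error("fm_unknown_reaction",
               sprintf("unknown reaction '%s'", objective$reaction))
    cc[idx] <- objective$sense %||% 1
  }
  structure(list(c = cc, lb = lb, ub = ub), class = "flux_problem")
}

# core LP call on a column subset of S; drops untouched metabolite rows
solve_subset <- function(u, cols, cc, lb, ub, maximize = TRUE,
                         extra = NULL) {
  Sd <- dense_S(u)[, cols, drop = FALSE]
  if (!is.null(extra)) Sd <- cbind(Sd, extra$S)
  keep <- rowSums(Sd != 0) > 0
  Sd <- Sd[keep, , drop = FALSE]
  r <- .simplex_solve(cc, Sd, numeric(nrow(Sd)), lb, ub, maximize)
  r
}

#' Maximize biomass flux
#'
#' Solves the FBA problem `max Z = c'v` subject to `S v = 0` and the bounds
#' of [build_problem()].  Since `v = 0` is feasible, the optimum always
#' exists and `Z >= 0`.
#'
#' @inheritParams build_problem
#' @return list of class `flux_solution` with `status` (`"optimal"`,
#'   `"infeasible"`, `"iteration_limit"`), `Z`, and the flux vector `v`
#'   named by reaction id.
#' @export
max_biomass <- function(universe, g, environment, U = FM_U) {
  pb <- build_problem(universe, g, environment, "biomass", U)
  cols <- which(g$bits)
  r <- solve_subset(universe, cols, pb$c[cols], pb$lb[cols], pb$ub[cols])
  v <- numeric(length(universe$rxn_ids))
  status <- c("optimal", "infeasible", "iteration_limit")[r$status + 1L]
  if (r$status == 0L) v[cols] <- r$x
  structure(list(status = status,
                 Z = if (r$status == 0L) r$z else NA_real_,
                 v = setNames(v, universe$rxn_ids)),
            class = "flux_solution")
}

#' Viability of a genotype across environments
#'
#' A genotype is viable if its maximal biomass flux exceeds `eps` in every
#' listed environment (viability means a nonzero optimum; a strict
#' tolerance is mandatory with floating-point LP).
#'
#' @inheritParams build_problem
#' @param environments non-empty list of [growth_environment()] objects.
#' @param eps viability threshold on the biomass flux.
#' @return logical scalar.
#' @export
is_viable <- function(universe, g, environments, eps = FM_EPS_VIAB,
                      U = FM_U) {
  if (inherits(environments, "growth_environment"))
    environments <- list(environments)
  if (!length(environments))
    fm_error("fm_parse_error", "at least one environment is required")
  for (e in environments) {
    sol <- max_biomass(universe, g, e, U)
    if (sol$status != "optimal")
      fm_error("fm_solver_failure",
               sprintf("solver returned '%s' in environment '%s'",
                       sol$status, e$label))
    if (sol$Z <= eps) return(FALSE)
  }
  TRUE
}

#' Flux variability analysis
#'
#' For each requested present reaction, minimizes and maximizes its flux
#' over the steady-state polytope.  With `open_exchanges = TRUE` every
#' exchange reaction may import and secrete regardless of environment; with
#' `decouple_biomass = TRUE` the biomass reaction is replaced by one
#' independent sink per biomass precursor (so precursor synthesis is not
#' tied to a fixed biomass composition).
#'
#' @inheritParams build_problem
#' @param open_exchanges open all exchanges in both directions.
#' @param decouple_biomass replace biomass by per-precursor sinks.
#' @param reactions reaction ids to scan (default: all present reactions,
#'   excluding biomass when decoupled).
#' @return data.frame with columns `reaction_id`, `min`, `max`.
#' @export
flux_variability <- function(universe, g, open_exchanges = TRUE,
                             decouple_biomass = FALSE, reactions = NULL,
                             U = FM_U) {
  net <- analysis_network(universe, g, open_exchanges, decouple_biomass, U)
  ids <- reactions %||% net$ids[net$kind != "sink"]
  idx <- match(ids, net$ids)
  if (anyNA(idx))
    fm_error("fm_unknown_reaction", "requested reactions not in the network")
  res <- matrix(NA_real_, length(ids), 2,
                dimnames = list(ids, c("min", "max")))
  nn <- length(net$ids)
  for (k in seq_along(idx)) {
    cc <- numeric(nn); cc[idx[k]] <- 1
    lo <- .simplex_solve(cc, net$S, numeric(nrow(net$S)), net$lb, net$ub, FALSE)
    hi <- .simplex_solve(cc, net$S, numeric(nrow(net$S)), net$lb, net$ub, TRUE)
    if (lo$status == 0L) res[k, 1] <- lo$z
    if (hi$status == 0L) res[k, 2] <- hi$z
  }
  data.frame(reaction_id = ids, min = res[, 1], max = res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Blocked reactions of a universe
#'
#' A reaction is blocked when it cannot carry nonzero steady-state flux
#' under any condition: its flux-variability interval is `{0}` with every
#' exchange open and biomass decoupled.  Blocked reactions are excluded
#' from coupling analysis downstream.
#'
#' @inheritParams build_problem
#' @param g genotype to analyze (default: the full universe).
#' @param eps zero-flux tolerance applied to both interval ends.
#' @return character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(universe, g = full_genotype(universe),
                              eps = FM_EPS_BLOCKED, U = FM_U) {
  ids <- present_reactions(universe, g, role = "metabolic")
  if (!length(ids)) return(character(0))
  fv <- flux_variability(universe, g, open_exchanges = TRUE,
                         decouple_biomass = TRUE, reactions = ids, U = U)
  fv$reaction_id[!is.na(fv$min) & !is.na(fv$max) &
                   fv$max <= eps & fv$min >= -eps]
}
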