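# ---------------------------------------------------------------------------
# Synthetic reaction universes with known ground truth: nutrient-specific
# catabolic chains feeding a shared core, redundant entry routes, blocked
# distractors, optional cofactor cycle and a 2:1 stoichiometric step.
# ---------------------------------------------------------------------------

#' Configuration of a synthetic reaction universe
#'
#' The generated universe has, per nutrient, an exchange reaction and a
#' linear catabolic chain (annotated as its own pathway) from the nutrient
#' to a shared hub metabolite; `n_redundant_routes` parallel two-reaction
#' routes lead from the hub into the core, so that many genotypes realize
#' the same phenotype; a linear core produces the biomass precursors;
#' distractor reactions consume metabolites nothing can produce and are
#' therefore blocked.  Optional features: a 2:1 stoichiometric step at the
#' core entry (exercising non-unit coupling ratios) and a cofactor cycle
#' (exercising the scope algorithm's seed sensitivity).
#'
#' @param n_nutrients number of alternative sole carbon sources.
#' @param pathway_length reactions per catabolic chain (>= 1).
#' @param n_redundant_routes parallel hub-to-core routes (>= 1).
#' @param core_length reactions in the shared core chain (>= 1).
#' @param n_distractors blocked distractor reactions.
#' @param two_to_one_step give the core entry a 2:1 stoichiometry.
#' @param cofactors add a cofactor cycle through the core (0 or 1).
#' @param seed stored for provenance (generation is deterministic).
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_nutrients = 8, pathway_length = 3,
                         n_redundant_routes = 3, core_length = 12,
                         n_distractors = 20, two_to_one_step = TRUE,
                         cofactors = 1, seed = 1L) {
  if (n_nutrients < 1 || pathway_length < 1 || n_redundant_routes < 1 ||
      core_length < 1 || n_distractors < 0 || !cofactors %in% c(0, 1))
    fm_error("fm_bad_config", "contradictory synthetic-universe configuration")
  structure(list(n_nutrients = n_nutrients,
                 pathway_length = pathway_length,
                 n_redundant_routes = n_redundant_routes,
                 core_length = core_length,
                 n_distractors = n_distractors,
                 two_to_one_step = isTRUE(two_to_one_step),
                 cofactors = cofactors, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic universe with ground truth
#'
#' Builds the universe described by [synth_config()] together with its
#' pathway annotations, the per-nutrient minimal environments (shared base
#' importable metabolite `h2o_ext` plus one carbon source each), and a
#' ground-truth object derived from the construction: the expected FCS
#' partition of the full-universe genotype, designed scope distances, the
#' cofactor seed, and the identity of the blocked distractors.
#'
#' @param config a [synth_config()].
#' @return list with `universe`, `annotations`, `environments`,
#'   `ground_truth` (class `synth_ground_truth`).
#' @export
synth_universe <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  L <- config$pathway_length
  R <- config$n_redundant_routes
  K <- config$core_length
  mets <- data.frame(id = character(0), external = logical(0),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = character(0), equation = character(0),
                     role = character(0), swappable = logical(0),
                     stringsAsFactors = FALSE)
  ann <- list()
  add_met <- function(id, external = FALSE)
    mets <<- rbind(mets, data.frame(id = id, external = external,
                                    stringsAsFactors = FALSE))
  add_rxn <- function(id, eq, role = "metabolic", swappable = TRUE,
                      pathway = NULL) {
    rxns <<- rbind(rxns, data.frame(id = id, equation = eq, role = role,
                                    swappable = swappable,
                                    stringsAsFactors = FALSE))
    if (!is.null(pathway)) ann[[id]] <<- pathway
  }

  add_met("h2o_ext", external = TRUE)
  add_rxn("EX_h2o", "h2o_ext =>", role = "exchange", swappable = FALSE)
  add_met("hub")

  chains <- list()
  for (i in seq_len(config$n_nutrients)) {
    nut <- sprintf("nut%d_ext", i)
    add_met(nut, external = TRUE)
    add_rxn(sprintf("EX_nut%d", i), paste(nut, "=>"),
            role = "exchange", swappable = FALSE)
    pw <- sprintf("nutrient%d catabolism", i)
    ids <- character(L)
    prev <- nut
    for (j in seq_len(L)) {
      prod <- if (j == L) "hub" else sprintf("c%d_%d", i, j)
      if (j < L) add_met(prod)
      ids[j] <- sprintf("CAT%d_%d", i, j)
      add_rxn(ids[j], paste(prev, "=>", prod), pathway = pw)
      prev <- prod
    }
    chains[[i]] <- ids
  }

  add_met("pre_core")
  routes <- list()
  for (j in seq_len(R)) {
    rm <- sprintf("route%d_m", j)
    add_met(rm)
    ids <- c(sprintf("ROUTE%d_1", j), sprintf("ROUTE%d_2", j))
    add_rxn(ids[1], paste("hub =>", rm), pathway = "core entry")
    add_rxn(ids[2], paste(rm, "=> pre_core"), pathway = "core entry")
    routes[[j]] <- ids
  }

  core_ids <- character(K)
  prev <- "pre_core"
  use_cof <- config$cofactors > 0
  if (use_cof) { add_met("cofA"); add_met("cofB") }
  for (t in seq_len(K)) {
    prod <- if (t == K) "bm1" else sprintf("k%d", t)
    add_met(prod)
    core_ids[t] <- sprintf("CORE%d", t)
    lhs <- if (t == 1 && config$two_to_one_step) paste("2", prev) else prev
    if (use_cof && t == min(2, K)) {
      add_rxn(core_ids[t], paste(lhs, "+ cofA =>", prod, "+ cofB"),
              pathway = "core biosynthesis")
    } else {
      add_rxn(core_ids[t], paste(lhs, "=>", prod),
              pathway = "core biosynthesis")
    }
    prev <- prod
  }
  if (use_cof)
    add_rxn("REGEN", "cofB => cofA", pathway = "core biosynthesis")

  for (d in seq_len(config$n_distractors)) {
    add_met(sprintf("dead%d_a", d)); add_met(sprintf("dead%d_b", d))
    add_rxn(sprintf("DIST%d", d),
            sprintf("dead%d_a => dead%d_b", d, d), pathway = "distractor")
  }

  add_rxn("BIOMASS", "bm1 =>", role = "biomass", swappable = FALSE)

  u <- reaction_universe(mets, rxns)
  environments <- lapply(seq_len(config$n_nutrients), function(i)
    growth_environment(sprintf("nut%d", i),
                       c(sprintf("nut%d_ext", i), "h2o_ext")))

  # --- ground truth, by construction ---
  # coupling collapses every unbranched segment: a single route merges into
  # the core, and with a single nutrient AND a single route the whole
  # nutrient-to-biomass path is one fully coupled set
  core_set <- c(core_ids, if (use_cof) "REGEN")
  if (R == 1) {
    core_set <- c(routes[[1]], core_set)
    if (config$n_nutrients == 1 && L >= 1) {
      core_set <- c(chains[[1]], core_set)
      chains <- list()
    }
    routes <- list()
  }
  expected_sets <- c(
    Filter(function(s) length(s) >= 2, chains),
    Filter(function(s) length(s) >= 2, routes),
    if (length(core_set) >= 2) list(core_set)
  )
  expected_sets <- lapply(expected_sets, sort)
  expected_sets <- expected_sets[order(vapply(expected_sets, `[`,
                                              character(1), 1))]

  # designed scope distances (seed: one nutrient + h2o + cofA if present)
  dist <- setNames(rep(NA_integer_, length(u$rxn_ids)), u$rxn_ids)
  for (i in seq_len(config$n_nutrients))
    for (j in seq_len(L)) dist[sprintf("CAT%d_%d", i, j)] <- j
  for (j in seq_len(R)) {
    dist[sprintf("ROUTE%d_1", j)] <- L + 1L
    dist[sprintf("ROUTE%d_2", j)] <- L + 2L
  }
  for (t in seq_len(K)) dist[sprintf("CORE%d", t)] <- L + 2L + t
  if (use_cof) dist["REGEN"] <- L + 2L + min(2, K) + 1L
  dist <- dist[u$role == "metabolic"]

  # viability requirement per environment: that nutrient's chain, the full
  # core (incl. cofactor regeneration), and at least one complete route
  chain_sets <- lapply(seq_len(config$n_nutrients), function(i)
    sprintf("CAT%d_%d", i, seq_len(L)))
  route_sets <- lapply(seq_len(R), function(j)
    c(sprintf("ROUTE%d_1", j), sprintf("ROUTE%d_2", j)))
  gt <- structure(list(
    expected_fcs = expected_sets,
    expected_M = sum(lengths(expected_sets)),
    expected_s = length(expected_sets),
    scope_distance = dist,
    cofactor_seed = if (use_cof) "cofA" else character(0),
    blocked = if (config$n_distractors)
      sort(sprintf("DIST%d", seq_len(config$n_distractors)))
      else character(0),
    chains = chain_sets,
    routes = route_sets,
    core = c(core_ids, if (use_cof) "REGEN"),
    config = config
  ), class = "synth_ground_truth")

  list(universe = u, annotations = ann, environments = environments,
       ground_truth = gt)
}

#' Enumerate all viable genotypes of a small universe
#'
#' Exhaustively tests every genotype with `n` reactions (all combinations
#' of the swappable reactions on top of the fixed pattern) for viability in
#' the given environments.  Used as the uniformity oracle for the MCMC
#' sampler; refuses combinatorially infeasible inputs.
#'
#' @param universe a [reaction_universe()] with at most `max_swappable`
#'   swappable reactions.
#' @param n genotype size (total set bits).
#' @param environments list of [growth_environment()] objects.
#' @param max_swappable safety bound (default 25).
#' @param U generic flux bound.
#' @return list of viable `fm_genotype` objects.
#' @export
enumerate_viable_genotypes <- function(universe, n, environments,
                                       max_swappable = 25L, U = FM_U) {
  sw <- which(universe$swappable)
  n_fixed <- sum(!universe$swappable)
  k <- n - n_fixed
  if (length(sw) > max_swappable)
    fm_error("fm_enumeration_bound",
             sprintf("%d swappable reactions exceed the bound of %d",
                     length(sw), max_swappable))
  if (k < 0 || k > length(sw))
    fm_error("fm_enumeration_bound", "n incompatible with the universe")
  combs <- combn(sw, k)
  out <- list()
  for (c_ in seq_len(ncol(combs))) {
    bits <- !universe$swappable
    bits[combs[, c_]] <- TRUE
    g <- structure(list(bits = bits, n = n), class = "fm_genotype")
    if (is_viable(universe, g, environments, U = U))
      out[[length(out) + 1L]] <- g
  }
  out
}
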