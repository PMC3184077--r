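# ---------------------------------------------------------------------------
# Network expansion (scope) and per-reaction distances from nutrients.
# ---------------------------------------------------------------------------

#' Expand the scope of a seed metabolite set
#'
#' Iteratively grows the set `A` of producible metabolites, starting from
#' the seed: at iteration `i` every metabolic reaction whose substrates are
#' all contained in `A(i-1)` fires and contributes its products to `A(i)`.
#' Reversible reactions are evaluated as two directed half-reactions and
#' fire in either direction.  The procedure stops when no metabolite is
#' added and no reaction newly fires; a reaction's firing iteration is the
#' first iteration at which it fired (in any direction), or `NA` if it
#' never can ("unreached").  Exchange and biomass reactions are boundary
#' bookkeeping and take no part in the expansion.
#'
#' @param universe a [reaction_universe()].
#' @param seed_metabolites character vector of metabolite ids.
#' @return list of class `scope_result` with `producible` (the scope),
#'   `firing_iteration` (named integer, `NA` = unreached) and `iterations`.
#' @export
scope_expand <- function(universe, seed_metabolites) {
  bad <- setdiff(seed_metabolites, universe$met_ids)
  if (length(bad))
    fm_error("fm_unknown_metabolite",
             sprintf("seed metabolites not in universe: %s",
                     paste(bad, collapse = ", ")))
  rx <- which(universe$role == "metabolic")
  # directed half-reactions: list of (substrates, products, reaction index)
  dirs <- list()
  for (k in rx) {
    col <- universe$S[, k]
    subs <- universe$met_ids[col < 0]
    prods <- universe$met_ids[col > 0]
    dirs[[length(dirs) + 1L]] <- list(s = subs, p = prods, k = k)
    if (universe$reversible[k])
      dirs[[length(dirs) + 1L]] <- list(s = prods, p = subs, k = k)
  }
  A <- unique(seed_metabolites)
  fired <- rep(FALSE, length(dirs))
  firing <- setNames(rep(NA_integer_, length(universe$rxn_ids)),
                     universe$rxn_ids)
  i <- 0L
  repeat {
    i <- i + 1L
    new_mets <- character(0)
    new_fire <- FALSE
    for (d in seq_along(dirs)) {
      if (fired[d]) next
      if (all(dirs[[d]]$s %in% A)) {
        fired[d] <- TRUE
        new_fire <- TRUE
        k <- dirs[[d]]$k
        if (is.na(firing[k])) firing[k] <- i
        new_mets <- c(new_mets, dirs[[d]]$p)
      }
    }
    grew <- length(setdiff(new_mets, A)) > 0
    A <- union(A, new_mets)
    if (!grew && !new_fire) { i <- i - 1L; break }
  }
  structure(list(producible = sort(A),
                 firing_iteration = firing[universe$role == "metabolic"],
                 iterations = i),
            class = "scope_result")
}

#' Scope distances of reactions from nutrients
#'
#' For each environment the seed is its importable metabolites plus the
#' configured cofactor seed (network expansion cannot bootstrap
#' autocatalytic cofactor cycles, so cofactors are seeded explicitly); the
#' scope distance of a reaction is the minimum firing iteration over all
#' environments, or `NA` ("unreached") if it fires in none.
#'
#' @param universe a [reaction_universe()].
#' @param environments non-empty list of [growth_environment()] objects.
#' @param cofactor_seed metabolite ids always added to the seed.
#' @return data.frame with columns `reaction_id`, `distance` (integer, `NA`
#'   = unreached); the number of unreached reactions is attached as
#'   attribute `n_unreached`.
#' @export
scope_distances <- function(universe, environments,
                            cofactor_seed = character(0)) {
  if (inherits(environments, "growth_environment"))
    environments <- list(environments)
  if (!length(environments))
    fm_error("fm_parse_error", "at least one environment is required")
  dist <- NULL
  for (e in environments) {
    sc <- scope_expand(universe, union(e$importable, cofactor_seed))
    d <- sc$firing_iteration
    dist <- if (is.null(dist)) d else pmin(dist, d, na.rm = TRUE)
  }
  out <- data.frame(reaction_id = names(dist),
                    distance = as.integer(dist),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_unreached") <- sum(is.na(dist))
  out
}
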