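# ---------------------------------------------------------------------------
# MCMC sampling of viable genotypes at fixed reaction number n.
# ---------------------------------------------------------------------------

#' Specification of one MCMC sampling run
#'
#' Bundles the environments defining the phenotype (their number is the
#' environmental versatility index `V_env`), the genotype size `n`, and the
#' chain parameters.  The defaults are sized for genome-scale universes
#' (burn-in 1e5 attempted swaps, 1e6 further attempts, every 1000th state
#' saved); desk-scale runs pass smaller values explicitly.
#'
#' @param environments non-empty list of [growth_environment()] objects.
#' @param n total number of reactions in each genotype (set bits).
#' @param burn_in attempted swaps before sampling starts.
#' @param chain_length attempted swaps after burn-in.
#' @param thinning save interval (must divide `chain_length`).
#' @param seed integer RNG seed for the chain.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(environments, n, burn_in = 1e5,
                          chain_length = 1e6, thinning = 1e3, seed = 1L) {
  if (inherits(environments, "growth_environment"))
    environments <- list(environments)
  if (!length(environments))
    fm_error("fm_parse_error", "V_env must be at least 1")
  if (chain_length %% thinning != 0)
    fm_error("fm_parse_error", "thinning must divide chain_length")
  structure(list(environments = environments, n = as.integer(n),
                 burn_in = as.integer(burn_in),
                 chain_length = as.integer(chain_length),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Propose a reaction swap
#'
#' Removes one uniformly chosen present swappable reaction and adds one
#' uniformly chosen absent swappable reaction, preserving the reaction
#' count `n`.  The proposal distribution is symmetric, which together with
#' accept-iff-viable makes the chain's stationary distribution uniform on
#' the reachable viable set.
#'
#' @param g an [genotype()].
#' @param universe a [reaction_universe()].
#' @return the proposed `fm_genotype`.
#' @export
propose_swap <- function(g, universe) {
  sw <- universe$swappable
  pres <- which(sw & g$bits)
  abs_ <- which(sw & !g$bits)
  if (!length(pres) || !length(abs_))
    fm_error("fm_no_swappable_moves",
             "need at least one swappable present and one absent reaction")
  bits <- g$bits
  bits[pres[sample.int(length(pres), 1L)]] <- FALSE
  bits[abs_[sample.int(length(abs_), 1L)]] <- TRUE
  structure(list(bits = bits, n = g$n), class = "fm_genotype")
}

#' Run one MCMC chain over viable genotypes
#'
#' Metropolis-with-rejection random walk in the space of genotypes with
#' exactly `n` reactions: at each step a reaction swap is proposed and
#' accepted iff the modified genotype is viable in every environment of the
#' spec; otherwise the current genotype is retained.  States are saved
#' every `thinning` attempts after the burn-in.  Viability calls are
#' memoized by genotype hash within the chain (rejected proposals repeat,
#' and the LP dominates runtime).  Given the same seed the chain is exactly
#' reproducible.
#'
#' @param spec an [ensemble_spec()].
#' @param universe a [reaction_universe()].
#' @param start a viable `fm_genotype` with `n` reactions (see
#'   [build_start_genotype()]).
#' @param U generic flux bound.
#' @return object of class `ensemble_sample`: list with `spec`, `genotypes`
#'   (saved states), `acceptance_count`, `attempts`, and `provenance`.
#' @export
mcmc_chain <- function(spec, universe, start, U = FM_U) {
  if (start$n != spec$n)
    fm_error("fm_nonviable_start",
             sprintf("start genotype has %d reactions, spec demands %d",
                     start$n, spec$n))
  memo <- new.env(hash = TRUE, parent = emptyenv())
  viable_memo <- function(g) {
    key <- genotype_key(universe, g)
    v <- memo[[key]]
    if (is.null(v)) {
      v <- is_viable(universe, g, spec$environments, U = U)
      memo[[key]] <- v
    }
    v
  }
  if (!viable_memo(start))
    fm_error("fm_nonviable_start",
             "start genotype is not viable in all spec environments")

  set.seed(spec$seed)
  sw <- which(universe$swappable)
  bits <- start$bits
  pres <- which(universe$swappable & bits)   # swappable & present, indices
  abs_ <- setdiff(sw, pres)
  n_keep <- spec$chain_length %/% spec$thinning
  saved <- vector("list", n_keep)
  accept <- 0L
  total <- spec$burn_in + spec$chain_length
  for (t in seq_len(total)) {
    i <- sample.int(length(pres), 1L)
    j <- sample.int(length(abs_), 1L)
    bits2 <- bits
    bits2[pres[i]] <- FALSE
    bits2[abs_[j]] <- TRUE
    cand <- structure(list(bits = bits2, n = start$n), class = "fm_genotype")
    if (viable_memo(cand)) {
      tmp <- pres[i]; pres[i] <- abs_[j]; abs_[j] <- tmp
      bits <- bits2
      accept <- accept + 1L
    }
    if (t > spec$burn_in && (t - spec$burn_in) %% spec$thinning == 0L) {
      saved[[(t - spec$burn_in) %/% spec$thinning]] <-
        structure(list(bits = bits, n = start$n), class = "fm_genotype")
    }
  }
  structure(list(spec = spec, genotypes = saved,
                 acceptance_count = accept, attempts = total,
                 provenance = list(seed = spec$seed, U = U,
                                   eps_viab = FM_EPS_VIAB,
                                   package = "fluxmodules",
                                   version = as.character(
                                     utils::packageVersion("fluxmodules")))),
            class = "ensemble_sample")
}

#' Build a viable starting genotype
#'
#' Takes the union over the required
#' environments of the reactions carrying nonzero flux in one
#' biomass-maximizing flux distribution of the full universe, then pad with
#' uniformly random absent swappable reactions until the genotype has
#' exactly `n` reactions.  If the result is not viable (degenerate
#' alternate optimum) the padding is redrawn up to `retry_cap` times.
#'
#' @param universe a [reaction_universe()].
#' @param environments list of [growth_environment()] objects.
#' @param n target reaction count (set bits), at least the union size.
#' @param retry_cap number of padding redraws before giving up.
#' @param U generic flux bound.
#' @return a viable `fm_genotype` with `n` reactions.
#' @export
build_start_genotype <- function(universe, environments, n, retry_cap = 10L,
                                 U = FM_U) {
  if (inherits(environments, "growth_environment"))
    environments <- list(environments)
  fullg <- full_genotype(universe)
  core <- logical(length(universe$rxn_ids))
  for (e in environments) {
    sol <- max_biomass(universe, fullg, e, U)
    if (sol$status != "optimal" || sol$Z <= FM_EPS_VIAB)
      fm_error("fm_start_failed",
               sprintf("full universe is not viable in environment '%s'",
                       e$label))
    core <- core | (abs(sol$v) > 1e-6 & universe$swappable)
  }
  fixed <- !universe$swappable
  base_n <- sum(fixed | core)
  if (n < base_n)
    fm_error("fm_start_failed",
             sprintf("n = %d below the nonzero-flux union size %d", n, base_n))
  pool <- which(universe$swappable & !core)
  if (n - base_n > length(pool))
    fm_error("fm_start_failed", "not enough swappable reactions to pad to n")
  for (try in seq_len(retry_cap)) {
    bits <- fixed | core
    if (n > base_n)
      bits[sample(pool, n - base_n)] <- TRUE
    g <- structure(list(bits = bits, n = sum(bits)), class = "fm_genotype")
    if (is_viable(universe, g, environments, U = U)) return(g)
  }
  fm_error("fm_start_failed",
           sprintf("no viable start genotype found in %d tries", retry_cap))
}

#' Nested families of environment sets
#'
#' Draws decreasing nested subsets of the available environments: above
#' `pivot_size` a single nested chain is shared
#' by all replicates; at `pivot_size`, `replicates` independent subsets are
#' drawn from the smallest shared set; below it each replicate continues as
#' its own nested chain.  Every smaller set is contained in its parent.
#'
#' @param all_environments list of [growth_environment()] objects.
#' @param sizes strictly decreasing vector of set sizes (the `V_env`
#'   values), maximum at most `length(all_environments)`.
#' @param replicates number of independent families.
#' @param pivot_size element of `sizes` at which replication starts
#'   (default: the largest size, i.e. fully independent families below a
#'   shared top set).
#' @return list of `replicates` families; each family is a list mapping
#'   `V_env` (as character) to the list of environments of that size.
#' @export
build_nested_environment_sets <- function(all_environments, sizes,
                                          replicates = 1L,
                                          pivot_size = max(sizes)) {
  sizes <- as.integer(sizes)
  if (any(diff(sizes) >= 0))
    fm_error("fm_invalid_sizes", "sizes must be strictly decreasing")
  if (sizes[1] > length(all_environments))
    fm_error("fm_invalid_sizes", "largest size exceeds available environments")
  if (!pivot_size %in% sizes)
    fm_error("fm_invalid_sizes", "pivot_size must be one of sizes")

  draw <- function(pool, k)
    if (k == length(pool)) pool else pool[sort(sample.int(length(pool), k))]
  above <- sizes[sizes > pivot_size]
  shared <- list()
  parent <- all_environments
  for (k in above) {
    parent <- draw(parent, k)
    shared[[as.character(k)]] <- parent
  }
  below <- sizes[sizes < pivot_size]
  families <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    fam <- shared
    cur_r <- draw(parent, pivot_size)
    fam[[as.character(pivot_size)]] <- cur_r
    for (k in below) {
      cur_r <- draw(cur_r, k)
      fam[[as.character(k)]] <- cur_r
    }
    families[[r]] <- fam
  }
  families
}
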