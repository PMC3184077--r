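# ---------------------------------------------------------------------------
# Orchestration: versatility-vs-modularity curves, ensemble percentile
# tests, consensus reaction sets, and scope-distance comparisons.
# ---------------------------------------------------------------------------

#' Run the versatility experiment
#'
#' For every replicate family and every environment-set size `V_env`, runs
#' one MCMC chain, computes the FCS partition of every saved genotype, and
#' keeps the samples and partitions for downstream aggregation.  Chain
#' seeds are derived deterministically from `seed`, the replicate and the
#' set size.  A failing cell is recorded with its error message and skipped
#' rather than aborting the run.
#'
#' @param universe a [reaction_universe()].
#' @param families replicate families from [build_nested_environment_sets()].
#' @param n genotype size passed to [ensemble_spec()].
#' @param burn_in,chain_length,thinning chain parameters.
#' @param seed base seed; cell seeds are `seed + 1009 * replicate + V_env`.
#' @param U generic flux bound.
#' @return object of class `versatility_experiment`: list of cells, each
#'   with `replicate`, `V_env`, `sample`, `partitions` (or `error`).
#' @export
run_versatility_experiment <- function(universe, families, n,
                                       burn_in = 1000, chain_length = 10000,
                                       thinning = 100, seed = 1L, U = FM_U) {
  cells <- list()
  for (r in seq_along(families)) {
    fam <- families[[r]]
    for (nm in names(fam)) {
      envs <- fam[[nm]]
      v_env <- length(envs)
      cell_seed <- as.integer(seed + 1009L * r + v_env)
      cell <- tryCatch({
        set.seed(cell_seed)
        start <- build_start_genotype(universe, envs, n, U = U)
        spec <- ensemble_spec(envs, n, burn_in, chain_length, thinning,
                              seed = cell_seed)
        sample_ <- mcmc_chain(spec, universe, start, U = U)
        parts <- lapply(sample_$genotypes, function(g)
          fcs_partition(universe, g, U = U))
        list(replicate = r, V_env = v_env, sample = sample_,
             partitions = parts)
      }, fluxmodules_error = function(e)
        list(replicate = r, V_env = v_env, error = conditionMessage(e)))
      cells[[length(cells) + 1L]] <- cell
    }
  }
  structure(list(cells = cells, n = n, seed = seed),
            class = "versatility_experiment")
}

#' Aggregate an experiment into the versatility curve
#'
#' One row per (replicate, V_env): the ensemble means of the modularity
#' indices `M` (reactions in fully coupled sets) and `s` (number of sets)
#' with their standard deviations and standard errors, plus ensemble size
#' and the chain's acceptance rate.  Pure function of the stored samples:
#' re-aggregating the same experiment is bit-identical.
#'
#' @param experiment a [run_versatility_experiment()] result.
#' @return data.frame sorted by replicate then `V_env`.
#' @export
versatility_curve <- function(experiment) {
  rows <- lapply(experiment$cells, function(cell) {
    if (!is.null(cell$error))
      return(data.frame(replicate = cell$replicate, V_env = cell$V_env,
                        mean_M = NA_real_, mean_s = NA_real_,
                        sd_M = NA_real_, sd_s = NA_real_,
                        se_M = NA_real_, se_s = NA_real_,
                        n_genotypes = 0L, acceptance_rate = NA_real_,
                        stringsAsFactors = FALSE))
    Ms <- vapply(cell$partitions, function(p) p$M, numeric(1))
    ss <- vapply(cell$partitions, function(p) p$s, numeric(1))
    k <- length(Ms)
    data.frame(replicate = cell$replicate, V_env = cell$V_env,
               mean_M = mean(Ms), mean_s = mean(ss),
               sd_M = sd(Ms), sd_s = sd(ss),
               se_M = sd(Ms) / sqrt(k), se_s = sd(ss) / sqrt(k),
               n_genotypes = k,
               acceptance_rate = cell$sample$acceptance_count /
                 cell$sample$attempts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$replicate, out$V_env), , drop = FALSE]
}

#' Empirical percentile test of an observed value against an ensemble
#'
#' Rank-based comparison of one observed network statistic (e.g. its `M`)
#' with an ensemble of sampled values:
#' `p = (1 + #\{ensemble >= observed\}) / (1 + ensemble size)` and the
#' percentile of the observed value within the ensemble.
#'
#' @param ensemble_values numeric vector (non-empty).
#' @param observed numeric scalar.
#' @return list with `percentile` and `p`.
#' @export
empirical_percentile_test <- function(ensemble_values, observed) {
  if (!length(ensemble_values))
    fm_error("fm_empty_ensemble", "empty ensemble")
  n <- length(ensemble_values)
  p <- (1 + sum(ensemble_values >= observed)) / (1 + n)
  list(percentile = 100 * sum(ensemble_values < observed) / n, p = p)
}

#' Consensus set of FCS reactions
#'
#' A reaction belongs to the consensus set of an ensemble when it appears
#' inside the FCS partition of at least `threshold_fraction` of the
#' genotypes (default: half, e.g. at least 500 of 1000 genotypes).
#'
#' @param partitions list of [fcs_partition()] objects, one per genotype.
#' @param threshold_fraction required fraction of genotypes.
#' @return object of class `consensus_set`: list with `reactions` (sorted
#'   character vector), `threshold` (genotype count) and `counts`.
#' @export
consensus_reactions <- function(partitions, threshold_fraction = 0.5) {
  ngen <- length(partitions)
  threshold <- threshold_fraction * ngen
  counts <- table(unlist(lapply(partitions, function(p) unlist(p$sets)),
                         use.names = FALSE))
  reactions <- sort(names(counts)[counts >= threshold])
  structure(list(reactions = reactions, threshold = threshold,
                 counts = counts, n_genotypes = ngen,
                 threshold_fraction = threshold_fraction),
            class = "consensus_set")
}

#' Compare two scope-distance samples
#'
#' Two-sided two-sample Kolmogorov-Smirnov test plus Welch's t test on the
#' scope distances of two reaction groups (e.g. consensus-difference
#' reactions versus the whole universe).  Unreached reactions (`NA`) are
#' dropped with their counts reported.
#'
#' @param distances_a,distances_b numeric vectors, `NA` = unreached.
#' @return list with `ks_statistic`, `ks_p`, `welch_t`, `welch_p`,
#'   `summary` (a data.frame), and the dropped-NA counts.
#' @export
compare_scope_distributions <- function(distances_a, distances_b) {
  na_a <- sum(is.na(distances_a)); na_b <- sum(is.na(distances_b))
  a <- distances_a[!is.na(distances_a)]
  b <- distances_b[!is.na(distances_b)]
  if (!length(a) || !length(b))
    fm_error("fm_empty_sample",
             "a sample is empty after dropping unreached reactions")
  ks <- suppressWarnings(ks.test(a, b))     # ties expected: integer ranks
  tt <- t.test(a, b)                        # Welch by default
  list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       welch_t = unname(tt$statistic), welch_p = tt$p.value,
       n_a = length(a), n_b = length(b),
       unreached_a = na_a, unreached_b = na_b,
       summary = data.frame(
         sample = c("a", "b"),
         n = c(length(a), length(b)),
         unreached = c(na_a, na_b),
         mean = c(mean(a), mean(b)),
         median = c(stats::median(a), stats::median(b)),
         stringsAsFactors = FALSE))
}
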