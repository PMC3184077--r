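# Fixtures are built in code; nothing is read from disk.

# linear pathway: EX_A0 imports A0, k metabolic steps A0 -> ... -> Ak,
# biomass consumes Ak
chain_universe <- function(k) {
  mets <- data.frame(id = paste0("A", 0:k),
                     external = c(TRUE, rep(FALSE, k)),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A0", paste0("R", seq_len(k)), "BIOMASS"),
    equation = c("A0 =>",
                 paste(paste0("A", 0:(k - 1)), "=>", paste0("A", 1:k)),
                 paste0("A", k, " =>")),
    role = c("exchange", rep("metabolic", k), "biomass"),
    swappable = c(FALSE, rep(TRUE, k), FALSE),
    stringsAsFactors = FALSE)
  reaction_universe(mets, rxns)
}

chain_env <- function() growth_environment("A0", "A0")

# random small universe with exchanges and a biomass reaction, for FBA
# oracle comparisons; reactions drawn with 1-2 substrates/products and
# coefficients in {1, 2}
random_fba_universe <- function(seed, n_int = 4, n_ext = 2, n_rxn = 6,
                                reversible_frac = 0.4) {
  set.seed(seed)
  int <- paste0("m", seq_len(n_int))
  ext <- paste0("x", seq_len(n_ext))
  mets <- data.frame(id = c(int, ext),
                     external = c(rep(FALSE, n_int), rep(TRUE, n_ext)),
                     stringsAsFactors = FALSE)
  term <- function(ms) paste(ifelse(runif(length(ms)) < 0.3, "2 ", ""), ms,
                             sep = "", collapse = " + ")
  eqs <- character(n_rxn)
  for (r in seq_len(n_rxn)) {
    pool <- c(int, ext)
    subs <- sample(pool, sample(1:2, 1))
    prods <- sample(setdiff(pool, subs), sample(1:2, 1))
    arrow <- if (runif(1) < reversible_frac) "<=>" else "=>"
    eqs[r] <- paste(term(subs), arrow, term(prods))
  }
  rxns <- data.frame(
    id = c(paste0("EX_", ext), paste0("R", seq_len(n_rxn)), "BIOMASS"),
    equation = c(paste(ext, "=>"), eqs, paste(sample(int, 1), "=>")),
    role = c(rep("exchange", n_ext), rep("metabolic", n_rxn), "biomass"),
    swappable = c(rep(FALSE, n_ext), rep(TRUE, n_rxn), FALSE),
    stringsAsFactors = FALSE)
  reaction_universe(mets, rxns)
}

random_fba_env <- function(u) {
  ext <- u$met_ids[u$external]
  growth_environment("all", ext)
}

# random fully reversible network without biomass, for coupling oracles
random_reversible_universe <- function(seed, n_int = 5, n_ext = 2,
                                       n_rxn = 9) {
  set.seed(seed)
  int <- paste0("m", seq_len(n_int))
  ext <- paste0("x", seq_len(n_ext))
  mets <- data.frame(id = c(int, ext),
                     external = c(rep(FALSE, n_int), rep(TRUE, n_ext)),
                     stringsAsFactors = FALSE)
  eqs <- character(n_rxn)
  for (r in seq_len(n_rxn)) {
    pool <- c(int, ext)
    subs <- sample(pool, sample(1:2, 1))
    prods <- sample(setdiff(pool, subs), sample(1:2, 1))
    coef <- function(ms) paste(ifelse(runif(length(ms)) < 0.3, "2 ", ""),
                               ms, sep = "", collapse = " + ")
    eqs[r] <- paste(coef(subs), "<=>", coef(prods))
  }
  rxns <- data.frame(
    id = c(paste0("EX_", ext), paste0("R", seq_len(n_rxn))),
    equation = c(paste(ext, "=>"), eqs),
    role = c(rep("exchange", n_ext), rep("metabolic", n_rxn)),
    swappable = c(rep(FALSE, n_ext), rep(TRUE, n_rxn)),
    stringsAsFactors = FALSE)
  reaction_universe(mets, rxns)
}

# uniformity fixture: 12 swappable reactions, 21 viable genotypes at n_extra = 2
uniformity_fixture <- function() {
  cfg <- synth_config(n_nutrients = 1, pathway_length = 2,
                      n_redundant_routes = 1, core_length = 1,
                      n_distractors = 7, cofactors = 0,
                      two_to_one_step = FALSE)
  sy <- synth_universe(cfg)
  sy$n <- sum(!sy$universe$swappable) + 7L  # forced 5 swappable + 2 spares
  sy
}

# the scaled end-to-end experiment (study conditions); computed once and
# shared between the tests that inspect it
.experiment_cache <- new.env(parent = emptyenv())
get_scaled_experiment <- function() {
  if (is.null(.experiment_cache$exp)) {
    sy <- synth_universe(synth_config())
    u <- sy$universe
    n <- sum(!u$swappable) + 43L
    set.seed(20260925)
    fams <- build_nested_environment_sets(sy$environments, c(8, 4, 2, 1),
                                          replicates = 3, pivot_size = 8)
    exp_ <- run_versatility_experiment(u, fams, n, burn_in = 1000,
                                       chain_length = 10000, thinning = 100,
                                       seed = 42L)
    .experiment_cache$exp <- list(synth = sy, experiment = exp_, n = n)
  }
  .experiment_cache$exp
}
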