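#' Construct a metabolic genotype
#'
#' A genotype is a bit vector over the universe's reactions saying which
#' reactions the network contains.  Non-swappable reactions (exchanges, the
#' biomass reaction, and any metabolic reaction marked non-swappable) follow
#' the universe-wide fixed pattern and are always present; only the
#' swappable bits vary between genotypes.
#'
#' @param universe a [reaction_universe()].
#' @param present which swappable reactions are present: a character vector
#'   of reaction ids, or a logical vector over the universe's swappable
#'   reactions (in universe order).
#' @return an object of class `fm_genotype` with elements `bits` (logical,
#'   length N over all reactions) and `n` (number of set bits).
#' @export
genotype <- function(universe, present) {
  bits <- !universe$swappable          # fixed pattern: non-swappable present
  sw <- which(universe$swappable)
  if (is.character(present)) {
    idx <- match(present, universe$rxn_ids)
    if (anyNA(idx))
      fm_error("fm_unknown_reaction",
               sprintf("unknown reaction(s): %s",
                       paste(present[is.na(idx)], collapse = ", ")))
    if (any(!universe$swappable[idx]))
      fm_error("fm_parse_error", "listed reactions include non-swappable ones")
    bits[idx] <- TRUE
  } else {
    if (length(present) != length(sw))
      fm_error("fm_parse_error",
               "logical 'present' must have one entry per swappable reaction")
    bits[sw] <- as.logical(present)
  }
  structure(list(bits = bits, n = sum(bits)), class = "fm_genotype")
}

#' Genotype containing every reaction of the universe
#' @param universe a [reaction_universe()].
#' @return an `fm_genotype` with all bits set.
#' @export
full_genotype <- function(universe) {
  structure(list(bits = rep(TRUE, length(universe$rxn_ids)),
                 n = length(universe$rxn_ids)),
            class = "fm_genotype")
}

#' Reaction ids present in a genotype
#' @param universe a [reaction_universe()].
#' @param g an `fm_genotype`.
#' @param role optional filter on reaction role.
#' @return character vector of reaction ids.
#' @export
present_reactions <- function(universe, g, role = NULL) {
  keep <- g$bits
  if (!is.null(role)) keep <- keep & universe$role %in% role
  universe$rxn_ids[keep]
}

# canonical hash key over the swappable bits (used by the MCMC memoizer)
genotype_key <- function(universe, g) {
  paste(which(g$bits[universe$swappable]), collapse = " ")
}

#' @export
print.fm_genotype <- function(x, ...) {
  cat("<fm_genotype> ", x$n, " of ", length(x$bits), " reactions present\n",
      sep = "")
  invisible(x)
}
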