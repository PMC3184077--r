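# ---------------------------------------------------------------------------
# Pathway coherence of fully coupled sets: Q statistic, h-index, and the
# annotation-swap randomization test over a merged FCS list.
# ---------------------------------------------------------------------------

#' Merge FCS partitions of an ensemble
#'
#' Combines the fully coupled sets of many sampled genotypes into one
#' merged list.  Because FCSs within one genotype are disjoint, a repeated
#' set signals its presence in several genotypes; the merged list stores
#' each distinct set once together with its multiplicity (the number of
#' genotypes containing it).
#'
#' @param partitions list of [fcs_partition()] objects, one per genotype.
#' @return object of class `merged_fcs_list`: list with `sets` (distinct
#'   FCSs, character vectors), `multiplicity` (integer) and `n_genotypes`.
#' @export
merge_fcs_partitions <- function(partitions) {
  keys <- character(0); sets <- list(); mult <- integer(0)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (p in partitions) {
    for (s in p$sets) {
      key <- paste(s, collapse = "|")
      at <- lookup[[key]]
      if (is.null(at)) {
        sets[[length(sets) + 1L]] <- s
        mult <- c(mult, 1L)
        lookup[[key]] <- length(sets)
      } else {
        mult[at] <- mult[at] + 1L
      }
    }
  }
  structure(list(sets = sets, multiplicity = mult,
                 n_genotypes = length(partitions)),
            class = "merged_fcs_list")
}

#' Pathway coherence Q of one fully coupled set
#'
#' For each pathway, counts the member reactions whose annotation set
#' contains it; the dominant pathway is the one with the largest count
#' (ties broken lexicographically) and `Q` is that count divided by the
#' FCS size.  Unannotated members count in the denominator but match no
#' pathway.
#'
#' @param fcs character vector of reaction ids (non-empty).
#' @param annotations named list: reaction id -> character vector of
#'   pathway labels.
#' @return list with `Q` (fraction) and `dominant` (pathway label, or `NA`
#'   if no member is annotated).
#' @export
q_statistic <- function(fcs, annotations) {
  if (!length(fcs))
    fm_error("fm_empty_fcs", "cannot compute Q of an empty FCS")
  labels <- unlist(lapply(fcs, function(r) unique(annotations[[r]])),
                   use.names = FALSE)
  if (!length(labels))
    return(list(Q = 0, dominant = NA_character_))
  counts <- table(labels)
  top <- max(counts)
  dominant <- sort(names(counts)[counts == top])[1]
  list(Q = as.numeric(top) / length(fcs), dominant = dominant)
}

#' h-index of a list of Q values
#'
#' The largest `h` such that a fraction `h` of the FCSs have `Q >= h`:
#' `h = sup{x in [0,1] : fraction(Q >= x) >= x}`, the intersection of the
#' cumulative Q distribution with the bisecting line.  Computed exactly as
#' the maximum over distinct Q values of `min(q, fraction(Q >= q))`.
#' Weights (e.g. FCS multiplicities in a merged list) turn the fraction
#' into a weighted fraction.
#'
#' @param q_values numeric vector of Q values in (0, 1].
#' @param weights optional non-negative weights, same length.
#' @return the h-index, a number in `[0, 1]`.
#' @export
h_index <- function(q_values, weights = NULL) {
  if (!length(q_values))
    fm_error("fm_empty_fcs", "h-index of an empty list")
  w <- weights %||% rep(1, length(q_values))
  tot <- sum(w)
  max(vapply(unique(q_values), function(q)
    min(q, sum(w[q_values >= q]) / tot), numeric(1)))
}

# flattened slot representation of a merged list used by the swap chain
flatten_merged <- function(merged, annotations) {
  sizes <- lengths(merged$sets)
  slot_rxn <- unlist(merged$sets, use.names = FALSE)
  ann <- lapply(slot_rxn, function(r) {
    a <- annotations[[r]]
    if (is.null(a)) character(0) else sort(unique(a))
  })
  keys <- vapply(ann, paste, character(1), collapse = "\r")
  dict_keys <- unique(keys)
  dict <- ann[match(dict_keys, keys)]
  list(slot_offset = c(0L, cumsum(sizes)),
       assign = match(keys, dict_keys),       # 1-based into dict
       dict = dict, sizes = sizes)
}

# Q values of all FCSs for a given slot->annotation-set assignment
q_of_assignment <- function(fl, assign) {
  vapply(seq_along(fl$sizes), function(f) {
    lo <- fl$slot_offset[f] + 1L; hi <- fl$slot_offset[f + 1L]
    labels <- unlist(fl$dict[assign[lo:hi]], use.names = FALSE)
    if (!length(labels)) return(0)
    max(table(labels)) / fl$sizes[f]
  }, numeric(1))
}

# weighted pathway frequency of an assignment (for conservation checks)
annotation_frequencies <- function(fl, assign, multiplicity) {
  lab <- character(0); wt <- numeric(0)
  for (f in seq_along(fl$sizes)) {
    lo <- fl$slot_offset[f] + 1L; hi <- fl$slot_offset[f + 1L]
    l <- unlist(fl$dict[assign[lo:hi]], use.names = FALSE)
    if (length(l)) { lab <- c(lab, l); wt <- c(wt, rep(multiplicity[f], length(l))) }
  }
  tapply(wt, lab, sum)
}

#' Annotation-swap randomization test for pathway coherence
#'
#' Tests whether the observed h-index of a merged FCS list could arise if
#' annotations were unrelated to FCS membership.  Each of `n_random_lists`
#' random lists is produced by `n_swaps` moves starting from the observed
#' list; a move picks two distinct FCSs with the same multiplicity, one
#' member reaction in each, and exchanges their entire annotation sets —
#' preserving every pathway's total frequency in the merged list (checked
#' after every list) as well as all FCS sizes and multiplicities.  The
#' p-value uses the add-one correction
#' `p = (1 + #random h >= observed h) / (1 + n_random_lists)` and is never
#' zero.
#'
#' @param merged a [merge_fcs_partitions()] result.
#' @param annotations named list: reaction id -> pathway labels.
#' @param n_random_lists number of randomized lists (full-scale default
#'   1000).
#' @param n_swaps swap moves per list (full-scale default 1e7; desk-scale
#'   analyses pass smaller values).
#' @return object of class `coherence_result`: `q_values` and
#'   `multiplicity` per distinct FCS, observed `h`, `p_value`, `h_random`,
#'   and the test parameters.
#' @export
annotation_swap_randomization <- function(merged, annotations,
                                          n_random_lists = 1000,
                                          n_swaps = 1e7) {
  fl <- flatten_merged(merged, annotations)
  q_obs <- q_of_assignment(fl, fl$assign)
  h_obs <- h_index(q_obs, merged$multiplicity)

  classes <- split(seq_along(merged$sets), merged$multiplicity)
  classes <- classes[lengths(classes) >= 2L]
  if (!length(classes))
    fm_error("fm_no_swap_partners",
             "no two FCSs share a multiplicity; randomization impossible")
  elig_fcs <- unlist(classes, use.names = FALSE)
  class_offset <- c(0L, cumsum(lengths(classes)))
  elig_class <- rep(seq_along(classes) - 1L, lengths(classes))

  freq_obs <- annotation_frequencies(fl, fl$assign, merged$multiplicity)
  h_rand <- numeric(n_random_lists)
  for (l in seq_len(n_random_lists)) {
    assign2 <- .swap_chain(fl$assign - 1L, fl$slot_offset,
                           elig_fcs - 1L, class_offset, elig_class,
                           n_swaps) + 1L
    freq2 <- annotation_frequencies(fl, assign2, merged$multiplicity)
    stopifnot(identical(freq_obs[order(names(freq_obs))],
                        freq2[order(names(freq2))]))
    h_rand[l] <- h_index(q_of_assignment(fl, assign2), merged$multiplicity)
  }
  p <- (1 + sum(h_rand >= h_obs)) / (1 + n_random_lists)
  structure(list(q_values = q_obs, multiplicity = merged$multiplicity,
                 h = h_obs, p_value = p, h_random = h_rand,
                 n_random_lists = n_random_lists, n_swaps = n_swaps),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat("<coherence_result> h =", format(x$h, digits = 4),
      " p =", format(x$p_value, digits = 4),
      sprintf(" (%d lists, %g swaps each)\n",
              x$n_random_lists, x$n_swaps))
  invisible(x)
}
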