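#include <Rcpp.h>
using namespace Rcpp;

// Annotation-swap chain for the coherence randomization test.
//
// `assign` holds, per member slot of each distinct FCS, an index into a
// dictionary of annotation sets.  One move picks two distinct FCSs of the
// same multiplicity (uniform first pick over all eligible FCSs, second
// uniform among the rest of its multiplicity class), one member slot in
// each, and exchanges their annotation-set indices.  Uses R's RNG, so runs
// are reproducible under set.seed().
//
// slot_offset: per-FCS start into `assign` (0-based, length F+1)
// elig_fcs:    0-based FCS indices grouped by multiplicity class
// class_offset: per-class start into elig_fcs (0-based, length C+1)
// elig_class:  per entry of elig_fcs, its class id (0-based)

// [[Rcpp::export(name = ".swap_chain")]]
IntegerVector swap_chain(IntegerVector assign, IntegerVector slot_offset,
                         IntegerVector elig_fcs, IntegerVector class_offset,
                         IntegerVector elig_class, double n_swaps) {
  IntegerVector out = clone(assign);
  int n_elig = elig_fcs.size();
  if (n_elig < 2) return out;
  for (double t = 0; t < n_swaps; ++t) {
    int pos1 = (int)(unif_rand() * n_elig);
    if (pos1 >= n_elig) pos1 = n_elig - 1;
    int c = elig_class[pos1];
    int lo = class_offset[c], hi = class_offset[c + 1];
    int span = hi - lo;
    int pos2 = lo + (int)(unif_rand() * (span - 1));
    if (pos2 >= pos1) pos2 += 1;            // exclude pos1 itself
    if (pos2 >= hi) pos2 = hi - 1;
    int f1 = elig_fcs[pos1], f2 = elig_fcs[pos2];
    int s1 = slot_offset[f1] +
             (int)(unif_rand() * (slot_offset[f1 + 1] - slot_offset[f1]));
    int s2 = slot_offset[f2] +
             (int)(unif_rand() * (slot_offset[f2 + 1] - slot_offset[f2]));
    int tmp = out[s1];
    out[s1] = out[s2];
    out[s2] = tmp;
  }
  return out;
}
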