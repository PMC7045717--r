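#include <Rcpp.h>
using namespace Rcpp;

// Ancestry tracts for one linkage group are stored as three flat arrays:
//   bp  : tract end positions (Morgans), ascending within each chromosome
//         copy, the last entry of a copy equalling the group length L
//   lab : founder-copy label of each tract (1-based)
//   off : offsets (0-based) into bp/lab, length n_copies + 1
// Copy k (0-based) owns entries [off[k], off[k+1]).  Tracts tile [0, L]
// without gaps; adjacent tracts always differ in label.

// Append one tract, merging with the previous one when labels agree.
static inline void push_tract(std::vector<double> &bp, std::vector<int> &lab,
                              double end, int label, size_t copy_start) {
  if (bp.size() > copy_start && lab.back() == label) {
    bp.back() = end;
  } else {
    bp.push_back(end);
    lab.push_back(label);
  }
}

// Copy the part of parental copy [c0, c1) overlapping (seg_start, seg_end]
// into the output gamete.
static inline void copy_segment(const double *bp, const int *lab,
                                int c0, int c1, double seg_start,
                                double seg_end, size_t copy_start,
                                std::vector<double> &obp,
                                std::vector<int> &olab) {
  int i = c0;
  while (i < c1 - 1 && bp[i] <= seg_start) ++i; // first tract ending beyond start
  for (; i < c1; ++i) {
    double e = bp[i] < seg_end ? bp[i] : seg_end;
    push_tract(obp, olab, e, lab[i], copy_start);
    if (bp[i] >= seg_end) break;
  }
}

// Form one gamete from the two parental copies (a, b) of one group.
// Crossover count ~ Poisson(L); breakpoint positions Uniform(0, L); no
// interference (Haldane model).  Uses R's RNG, so results are reproducible
// under set.seed().
static void make_gamete(const double *bp, const int *lab,
                        int a0, int a1, int b0, int b1, double L,
                        std::vector<double> &obp, std::vector<int> &olab) {
  const size_t copy_start = obp.size();
  int nxo = (int) R::rpois(L);
  bool use_a = unif_rand() < 0.5;
  if (nxo == 0) {
    int s = use_a ? a0 : b0, e = use_a ? a1 : b1;
    for (int i = s; i < e; ++i) push_tract(obp, olab, bp[i], lab[i], copy_start);
    return;
  }
  std::vector<double> xo(nxo);
  for (int i = 0; i < nxo; ++i) xo[i] = unif_rand() * L;
  std::sort(xo.begin(), xo.end());
  double seg_start = 0.0;
  for (int s = 0; s <= nxo; ++s) {
    double seg_end = (s < nxo) ? xo[s] : L;
    if (seg_end > seg_start) {
      if (use_a) copy_segment(bp, lab, a0, a1, seg_start, seg_end,
                              copy_start, obp, olab);
      else       copy_segment(bp, lab, b0, b1, seg_start, seg_end,
                              copy_start, obp, olab);
      seg_start = seg_end;
    }
    use_a = !use_a;
  }
}

// One generation of random union of gametes for one linkage group.
// mother/father are 1-based individual indices (length = offspring count);
// offspring j receives copy 1 from mother[j] and copy 2 from father[j].
// [[Rcpp::export]]
List next_gen_group(NumericVector bp, IntegerVector lab, IntegerVector off,
                    double L, IntegerVector mother, IntegerVector father) {
  int n_off = mother.size();
  std::vector<double> obp;
  std::vector<int> olab;
  std::vector<int> ooff(2 * n_off + 1);
  obp.reserve(bp.size());
  olab.reserve(lab.size());
  ooff[0] = 0;
  const double *pbp = REAL(bp);
  const int *plab = INTEGER(lab);
  for (int j = 0; j < n_off; ++j) {
    int m = mother[j] - 1, f = father[j] - 1;
    make_gamete(pbp, plab, off[2 * m], off[2 * m + 1], off[2 * m + 1],
                off[2 * m + 2], L, obp, olab);
    ooff[2 * j + 1] = (int) obp.size();
    make_gamete(pbp, plab, off[2 * f], off[2 * f + 1], off[2 * f + 1],
                off[2 * f + 2], L, obp, olab);
    ooff[2 * j + 2] = (int) obp.size();
  }
  return List::create(_["bp"] = NumericVector(obp.begin(), obp.end()),
                      _["lab"] = IntegerVector(olab.begin(), olab.end()),
                      _["off"] = IntegerVector(ooff.begin(), ooff.end()));
}

// Founder-copy label at given positions for every chromosome copy.
// Returns an n_copies x n_pos integer matrix.
// [[Rcpp::export]]
IntegerMatrix labels_at(NumericVector bp, IntegerVector lab, IntegerVector off,
                        NumericVector pos) {
  int n_copies = off.size() - 1;
  int n_pos = pos.size();
  IntegerMatrix out(n_copies, n_pos);
  for (int k = 0; k < n_copies; ++k) {
    for (int p = 0; p < n_pos; ++p) {
      int i = off[k];
      // first tract whose end exceeds pos (last tract takes pos == L)
      while (i < off[k + 1] - 1 && bp[i] <= pos[p]) ++i;
      out(k, p) = lab[i];
    }
  }
  return out;
}
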