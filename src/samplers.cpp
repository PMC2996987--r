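#include <Rcpp.h>
using namespace Rcpp;

// Sample an index in [0, k) from an unnormalised weight row; returns -1 if the
// row has no mass. Uses R's RNG so set.seed() on the R side governs output.
static int sample_row(const double *w, int k) {
  double tot = 0.0;
  for (int i = 0; i < k; ++i) tot += w[i];
  if (tot <= 0.0) return -1;
  double u = unif_rand() * tot, acc = 0.0;
  for (int i = 0; i < k; ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return k - 1;
}

// Generate concatenated genes from a three-periodic nucleotide Markov chain.
//
// probs: 3 matrices (phase of the emitted base, 0..2), each 4^m x 4,
//   row-stochastic after back-off; flattened column-major as an R matrix list.
// init_ctx: one sampled initial context index per gene (0-based, in [0, 4^m)).
// len_nt: per-gene lengths in nucleotides (multiples of 3).
// stop_codons: integer codes b1*16 + b2*4 + b3 of the genetic code's stops.
//
// Emissions at phase 2 that would complete an in-frame stop are masked and the
// row renormalised, so generated genes are stop-free even through back-off.
// [[Rcpp::export]]
IntegerVector periodic_sample_cpp(int m,
                                  List probs,
                                  IntegerVector init_ctx,
                                  IntegerVector len_nt,
                                  IntegerVector stop_codons) {
  const int n_ctx = 1 << (2 * m);      // 4^m
  NumericMatrix P0 = probs[0], P1 = probs[1], P2 = probs[2];
  const NumericMatrix *P[3] = {&P0, &P1, &P2};
  int total = 0;
  for (int g = 0; g < len_nt.size(); ++g) total += len_nt[g];
  IntegerVector out(total);

  // stop lookup: for phase-2 masking we need, per (prev2 nt pair), which
  // third bases are forbidden
  std::vector<bool> forbidden(64, false);
  for (int s = 0; s < stop_codons.size(); ++s) forbidden[stop_codons[s]] = true;

  int pos = 0;
  for (int g = 0; g < len_nt.size(); ++g) {
    int L = len_nt[g];
    int ctx = init_ctx[g];
    // unpack the initial m-mer into the first m bases
    for (int i = m - 1; i >= 0; --i) out[pos + i] = (ctx >> (2 * (m - 1 - i))) & 3;
    for (int i = m; i < L; ++i) {
      int phase = i % 3;
      const NumericMatrix &pm = *P[phase];
      double w[4];
      for (int b = 0; b < 4; ++b) w[b] = pm(ctx, b);
      if (phase == 2) {
        int p2 = out[pos + i - 2] * 16 + out[pos + i - 1] * 4;
        for (int b = 0; b < 4; ++b) if (forbidden[p2 + b]) w[b] = 0.0;
      }
      int b = sample_row(w, 4);
      if (b < 0) stop("periodic sampler reached a context with no admissible emission");
      out[pos + i] = b;
      ctx = ((ctx << 2) | b) & (n_ctx - 1);
    }
    pos += L;
  }
  return out;
}

// First-order categorical chain over K states (codon or amino-acid chains).
// trans: K x K row-stochastic matrix; rows with zero mass must be repaired on
// the R side before the call. init: K-vector of initial-state weights.
// Returns 0-based state indices, genes concatenated.
// [[Rcpp::export]]
IntegerVector chain_sample_cpp(NumericMatrix trans,
                               NumericVector init,
                               IntegerVector len_states) {
  const int K = trans.nrow();
  int total = 0;
  for (int g = 0; g < len_states.size(); ++g) total += len_states[g];
  IntegerVector out(total);
  std::vector<double> row(K);
  int pos = 0;
  for (int g = 0; g < len_states.size(); ++g) {
    int L = len_states[g];
    int s = sample_row(REAL(init), K);
    if (s < 0) stop("initial state distribution has no mass");
    out[pos] = s;
    for (int i = 1; i < L; ++i) {
      for (int k = 0; k < K; ++k) row[k] = trans(s, k);
      int nxt = sample_row(row.data(), K);
      if (nxt < 0) stop("transition row with no mass (repair rows before sampling)");
      out[pos + i] = nxt;
      s = nxt;
    }
    pos += L;
  }
  return out;
}

// Count off-frame stop triplets in an integer-coded nucleotide vector.
// offset 1 scans frame +2 (0-based start 1), offset 2 scans frame +3.
// gene_start: 0-based start of each gene in seq; gene_len_nt: lengths.
// Returns one count per gene; windows never span gene boundaries.
// [[Rcpp::export]]
IntegerVector count_osc_int_cpp(IntegerVector seq,
                                IntegerVector gene_start,
                                IntegerVector gene_len_nt,
                                int offset,
                                IntegerVector stop_codons) {
  std::vector<bool> is_stop(64, false);
  for (int s = 0; s < stop_codons.size(); ++s) is_stop[stop_codons[s]] = true;
  int nG = gene_start.size();
  IntegerVector out(nG);
  for (int g = 0; g < nG; ++g) {
    int a = gene_start[g] + offset, end = gene_start[g] + gene_len_nt[g];
    int cnt = 0;
    for (int i = a; i + 2 <= end - 1; i += 3) {
      int code = seq[i] * 16 + seq[i + 1] * 4 + seq[i + 2];
      if (is_stop[code]) ++cnt;
    }
    out[g] = cnt;
  }
  return out;
}
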