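#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// DNA codes: A=0 C=1 G=2 T=3, anything else 4 (treated as N).
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// reverse complement of an encoded sequence; N stays N
static std::vector<int> revcomp_codes(const std::vector<int>& s) {
  std::vector<int> r(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int b = s[s.size() - 1 - i];
    r[i] = (b > 3) ? 4 : 3 - b;
  }
  return r;
}

// Accumulate occupancy sum_i 1/(1 + e^{E_i - mu}) into acc (one slot per mu),
// using the precomputed-exponent identity: e^{E_i - mu} = e^{-mu} * prod_j e^{w_{j,b}}.
// expw holds e^{w_{j,a}}; emu holds e^{-mu}.  Windows containing N contribute 0.
static void add_occupancy(const std::vector<int>& s, const NumericMatrix& expw,
                          const std::vector<double>& emu, double* acc) {
  const int N = (int)s.size(), M = expw.nrow(), nmu = (int)emu.size();
  for (int i = 0; i + M <= N; ++i) {
    double p = 1.0;
    bool ok = true;
    for (int j = 0; j < M; ++j) {
      int b = s[i + j];
      if (b > 3) { ok = false; break; }
      p *= expw(j, b);
    }
    if (!ok) continue;
    for (int m = 0; m < nmu; ++m) acc[m] += 1.0 / (1.0 + p * emu[m]);
  }
}

// [[Rcpp::export]]
NumericVector cpp_occupancy(std::string seq, NumericMatrix expw,
                            NumericVector mus, bool both_strands) {
  const int nmu = mus.size();
  if (expw.ncol() != 4) stop("PSAM exponent matrix must have 4 columns");
  if ((int)seq.size() < expw.nrow()) stop("sequence shorter than the motif");
  std::vector<double> emu(nmu);
  for (int m = 0; m < nmu; ++m) emu[m] = std::exp(-mus[m]);
  std::vector<int> s = encode_seq(seq);
  NumericVector out(nmu);
  add_occupancy(s, expw, emu, REAL(out));
  if (both_strands) {
    std::vector<int> rc = revcomp_codes(s);
    add_occupancy(rc, expw, emu, REAL(out));
  }
  return out;
}

// Fisher-Yates shuffle driven by a private mt19937 stream, so results are
// reproducible for a given seed independently of R's RNG state.
static void shuffle_codes(std::vector<int>& s, std::mt19937& rng) {
  for (size_t i = s.size() - 1; i > 0; --i) {
    size_t j = (size_t)(rng() % (uint32_t)(i + 1));
    std::swap(s[i], s[j]);
  }
}

// dbA for one sequence against n_shuffles mononucleotide-composition-preserving
// shuffles, for a list of PSAMs and a ladder of chemical potentials in one pass.
// Shuffled sequences are shared across PSAMs and mus.  Returns n_tf x n_mu.
// [[Rcpp::export]]
NumericMatrix cpp_dba_multi(std::string seq, List expw_list, NumericVector mus,
                            int n_shuffles, int seed, bool both_strands) {
  const int ntf = expw_list.size(), nmu = mus.size();
  if (n_shuffles < 1) stop("n_shuffles must be >= 1");
  std::vector<double> emu(nmu);
  for (int m = 0; m < nmu; ++m) emu[m] = std::exp(-mus[m]);
  std::vector<NumericMatrix> expws;
  expws.reserve(ntf);
  for (int t = 0; t < ntf; ++t) {
    NumericMatrix w = expw_list[t];
    if (w.ncol() != 4) stop("PSAM exponent matrix must have 4 columns");
    if ((int)seq.size() < w.nrow()) stop("sequence shorter than the motif");
    expws.push_back(w);
  }
  std::vector<int> s = encode_seq(seq);

  std::vector<double> p0(ntf * nmu, 0.0), bg(ntf * nmu, 0.0);
  {
    std::vector<int> rc = revcomp_codes(s);
    for (int t = 0; t < ntf; ++t) {
      add_occupancy(s, expws[t], emu, &p0[t * nmu]);
      if (both_strands) add_occupancy(rc, expws[t], emu, &p0[t * nmu]);
    }
  }

  std::mt19937 rng((uint32_t)seed);
  std::vector<int> sh = s;
  for (int k = 0; k < n_shuffles; ++k) {
    shuffle_codes(sh, rng);
    std::vector<int> rc = revcomp_codes(sh);
    for (int t = 0; t < ntf; ++t) {
      add_occupancy(sh, expws[t], emu, &bg[t * nmu]);
      if (both_strands) add_occupancy(rc, expws[t], emu, &bg[t * nmu]);
    }
  }

  NumericMatrix out(ntf, nmu);
  for (int t = 0; t < ntf; ++t)
    for (int m = 0; m < nmu; ++m) {
      double d = p0[t * nmu + m] - bg[t * nmu + m] / n_shuffles;
      out(t, m) = d > 0 ? d : 0.0;
    }
  return out;
}
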