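// Smith-Waterman local alignment with affine gaps (Gotoh), plus an
// independent brute-force reference scorer used by the test suite.
//
// Gap convention: a gap of length L costs open + L * extend (the
// convention shared by EMBOSS water and Biostrings::pairwiseAlignment).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG = -1e30;

static double enum_best(int i, int j,
                        const std::vector<int>& a, const std::vector<int>& b,
                        const NumericMatrix& S, double open, double ext,
                        std::vector<std::vector<double>>& memo);

// Gotoh local alignment; fills DP matrices and optionally tracebacks.
// a, b: 0-based integer encodings into the substitution matrix.
static double gotoh_score(const std::vector<int>& a, const std::vector<int>& b,
                          const NumericMatrix& S, double open, double ext,
                          std::vector<std::string>* aln,
                          const StringVector* alphabet) {
  const int n = a.size(), m = b.size();
  // H: best ending with match/mismatch or anything; E: gap in a (deletion
  // from b ... gap run in sequence A consuming b); F: gap run consuming a.
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double>> E(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> F(n + 1, std::vector<double>(m + 1, NEG));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(H[i][j - 1] - (open + ext), E[i][j - 1] - ext);
      F[i][j] = std::max(H[i - 1][j] - (open + ext), F[i - 1][j] - ext);
      double diag = H[i - 1][j - 1] + S(a[i - 1], b[j - 1]);
      double h = std::max(std::max(diag, 0.0), std::max(E[i][j], F[i][j]));
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (aln != nullptr && best > 0) {
    // traceback from (bi, bj) until H hits 0
    std::string ra, rb;
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E, 2 = F
    const double tol = 1e-9;
    while (i > 0 && j > 0) {
      if (state == 0) {
        if (H[i][j] <= tol) break;
        double diag = H[i - 1][j - 1] + S(a[i - 1], b[j - 1]);
        if (std::abs(H[i][j] - diag) < tol) {
          ra += as<std::string>((*alphabet)[a[i - 1]]);
          rb += as<std::string>((*alphabet)[b[j - 1]]);
          --i; --j;
        } else if (std::abs(H[i][j] - E[i][j]) < tol) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        ra += '-';
        rb += as<std::string>((*alphabet)[b[j - 1]]);
        if (std::abs(E[i][j] - (H[i][j - 1] - (open + ext))) < tol) state = 0;
        --j;
      } else {
        ra += as<std::string>((*alphabet)[a[i - 1]]);
        rb += '-';
        if (std::abs(F[i][j] - (H[i - 1][j] - (open + ext))) < tol) state = 0;
        --i;
      }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    aln->push_back(ra);
    aln->push_back(rb);
  } else if (aln != nullptr) {
    aln->push_back("");
    aln->push_back("");
  }
  return best;
}

static std::vector<int> encode(const std::string& s,
                               const std::string& letters) {
  std::vector<int> v;
  v.reserve(s.size());
  for (char c : s) {
    size_t p = letters.find(c);
    if (p == std::string::npos)
      stop("sequence letter '%s' not present in the substitution matrix",
           std::string(1, c).c_str());
    v.push_back((int)p);
  }
  return v;
}

static std::string matrix_letters(const NumericMatrix& S) {
  CharacterVector rn = rownames(S);
  std::string letters;
  for (int i = 0; i < rn.size(); ++i) {
    std::string l = as<std::string>(rn[i]);
    if (l.size() != 1) stop("substitution matrix row names must be single letters");
    letters += l;
  }
  return letters;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, NumericMatrix S,
                  double open, double ext) {
  std::string letters = matrix_letters(S);
  StringVector alphabet(letters.size());
  for (size_t i = 0; i < letters.size(); ++i)
    alphabet[i] = std::string(1, letters[i]);
  std::vector<int> ia = encode(a, letters), ib = encode(b, letters);
  std::vector<std::string> aln;
  double score = gotoh_score(ia, ib, S, open, ext, &aln, &alphabet);
  return List::create(_["score"] = score,
                      _["aligned_a"] = aln[0],
                      _["aligned_b"] = aln[1]);
}

// [[Rcpp::export]]
NumericVector sw_scores_pairs_cpp(CharacterVector seq_a, CharacterVector seq_b,
                                  NumericMatrix S, double open, double ext) {
  std::string letters = matrix_letters(S);
  int n = seq_a.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    std::vector<int> ia = encode(as<std::string>(seq_a[k]), letters);
    std::vector<int> ib = encode(as<std::string>(seq_b[k]), letters);
    out[k] = gotoh_score(ia, ib, S, open, ext, nullptr, nullptr);
  }
  return out;
}

// Brute-force reference: a local alignment is a non-empty increasing set
// of matched column pairs; unmatched residues between consecutive matches
// form one gap run per sequence. best(i, j) = best score of an alignment
// whose first matched pair is (i, j). Memoized over (i, j).
static double enum_best(int i, int j,
                        const std::vector<int>& a, const std::vector<int>& b,
                        const NumericMatrix& S, double open, double ext,
                        std::vector<std::vector<double>>& memo) {
  if (memo[i][j] > NEG / 2) return memo[i][j];
  const int n = a.size(), m = b.size();
  double best = S(a[i], b[j]); // alignment consisting of this single column
  for (int i2 = i + 1; i2 < n; ++i2) {
    for (int j2 = j + 1; j2 < m; ++j2) {
      double gap = 0.0;
      int da = i2 - i - 1, db = j2 - j - 1;
      if (da > 0) gap += open + ext * da;
      if (db > 0) gap += open + ext * db;
      double tail = enum_best(i2, j2, a, b, S, open, ext, memo);
      double cand = S(a[i], b[j]) - gap + tail;
      if (cand > best) best = cand;
    }
  }
  memo[i][j] = best;
  return best;
}

// Compare the Gotoh implementation against the enumeration reference for
// every (unordered) pair of the given sequences; returns the largest
// absolute score difference and the number of pairs checked.
// [[Rcpp::export]]
List sw_compare_all_pairs_cpp(CharacterVector seqs, NumericMatrix S,
                              double open, double ext) {
  std::string letters = matrix_letters(S);
  const int n = seqs.size();
  std::vector<std::vector<int>> enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode(as<std::string>(seqs[i]), letters);
  double max_diff = 0.0;
  long long n_pairs = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double g = gotoh_score(enc[i], enc[j], S, open, ext, nullptr, nullptr);
      const int la = enc[i].size(), lb = enc[j].size();
      std::vector<std::vector<double>> memo(la, std::vector<double>(lb, NEG));
      double e = 0.0;
      for (int a = 0; a < la; ++a)
        for (int b = 0; b < lb; ++b)
          e = std::max(e, enum_best(a, b, enc[i], enc[j], S, open, ext, memo));
      max_diff = std::max(max_diff, std::abs(g - e));
      ++n_pairs;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["max_abs_diff"] = max_diff,
                      _["n_pairs"] = (double)n_pairs);
}

// [[Rcpp::export]]
double sw_score_enum_cpp(std::string a, std::string b, NumericMatrix S,
                         double open, double ext) {
  std::string letters = matrix_letters(S);
  std::vector<int> ia = encode(a, letters), ib = encode(b, letters);
  const int n = ia.size(), m = ib.size();
  std::vector<std::vector<double>> memo(n, std::vector<double>(m, NEG));
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      best = std::max(best, enum_best(i, j, ia, ib, S, open, ext, memo));
  return best;
}
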