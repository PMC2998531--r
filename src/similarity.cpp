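#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Maximum number of identical residues over all ungapped (non-gap) relative
// offsets of p1 against p2, requiring overlap >= 1 residue.
static int max_identities(const std::string& a, const std::string& b) {
  const int la = (int)a.size(), lb = (int)b.size();
  int best = 0;
  // offset d: a[i] aligned with b[i + d], d in [-(la-1), lb-1]
  for (int d = -(la - 1); d <= lb - 1; ++d) {
    int i0 = std::max(0, -d);
    int i1 = std::min(la, lb - d);
    int m = 0;
    for (int i = i0; i < i1; ++i)
      if (a[i] == b[i + d]) ++m;
    if (m > best) best = m;
  }
  return best;
}

static bool shares_kmer(const std::string& a, const std::string& b, int k) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la < k || lb < k) return false;
  for (int i = 0; i + k <= la; ++i)
    for (int j = 0; j + k <= lb; ++j) {
      int m = 0;
      while (m < k && a[i + m] == b[j + m]) ++m;
      if (m == k) return true;
    }
  return false;
}

static bool pair_similar(const std::string& a, const std::string& b,
                         double threshold) {
  if (shares_kmer(a, b, 9)) return true;
  double denom = (double)std::min(a.size(), b.size());
  return max_identities(a, b) / denom > threshold;
}

// [[Rcpp::export]]
double cpp_ungapped_identity(std::string p1, std::string p2) {
  if (p1.empty() || p2.empty()) stop("peptides must be non-empty");
  return max_identities(p1, p2) /
         (double)std::min(p1.size(), p2.size());
}

// [[Rcpp::export]]
bool cpp_shares_9mer(std::string p1, std::string p2) {
  return shares_kmer(p1, p2, 9);
}

// [[Rcpp::export]]
bool cpp_is_similar(std::string p1, std::string p2, double threshold) {
  return pair_similar(p1, p2, threshold);
}

// All unordered pairs (i < j, 1-based) that are similar.
// [[Rcpp::export]]
IntegerMatrix cpp_similar_pairs(CharacterVector peptides, double threshold) {
  const int n = peptides.size();
  std::vector<std::string> pep(n);
  for (int i = 0; i < n; ++i) pep[i] = as<std::string>(peptides[i]);
  std::vector<int> ii, jj;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (pair_similar(pep[i], pep[j], threshold)) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
  IntegerMatrix out((int)ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}
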