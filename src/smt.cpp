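#include <Rcpp.h>
#include <map>
#include <vector>
#include <string>
using namespace Rcpp;

// 2-bit base encoding: A=0, C=1, G=2, T=3; anything else (N) = -1.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Build the sparse motif trie over all k-windows of `seqs`.
// Node table layout (1-based node ids, root = 1): columns 1..4 child
// pointers for A,C,G,T; column 5 terminal count; column 6 numeric 2-bit
// code of the spelled k-mer (exact for k <= 26, NA otherwise).
// Windows containing a symbol outside ACGT are skipped.
// [[Rcpp::export]]
List smt_build(CharacterVector seqs, int k) {
  std::vector<int> child;            // flat, 4 cells per node
  std::vector<int> count;
  std::vector<double> code;
  child.reserve(4096); count.reserve(1024); code.reserve(1024);

  // returns new node id
  auto add_node = [&]() -> int {
    child.insert(child.end(), 4, 0);
    count.push_back(0);
    code.push_back(NA_REAL);
    return (int)count.size();
  };
  add_node(); // root, id 1

  std::map<int, std::vector<std::pair<int, int> > > addr; // terminal -> (seq 1-based, offset 0-based)
  double n_windows = 0;

  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int t = (int)s.size();
    if (t < k) continue;
    std::vector<int> bc(t);
    for (int j = 0; j < t; ++j) bc[j] = base_code(s[j]);
    // rightmost invalid position at or before j, for O(1) window checks
    std::vector<int> last_bad(t, -1);
    for (int j = 0; j < t; ++j)
      last_bad[j] = (bc[j] < 0) ? j : (j > 0 ? last_bad[j - 1] : -1);

    for (int u = 0; u + k <= t; ++u) {
      if (last_bad[u + k - 1] >= u) continue; // window touches an N
      n_windows += 1;
      int node = 1;
      double c = 0.0;
      for (int j = u; j < u + k; ++j) {
        int b = bc[j];
        c = c * 4.0 + b;
        int cell = child[(size_t)(node - 1) * 4 + b];
        if (cell == 0) {
          cell = add_node();
          child[(size_t)(node - 1) * 4 + b] = cell;
        }
        node = cell;
      }
      count[node - 1] += 1;
      if (k <= 26) code[node - 1] = c;
      addr[node].push_back(std::make_pair(i + 1, u));
    }
  }

  int nu = (int)count.size();
  NumericMatrix M(nu, 6);
  for (int r = 0; r < nu; ++r) {
    for (int b = 0; b < 4; ++b) M(r, b) = child[(size_t)r * 4 + b];
    M(r, 4) = count[r];
    M(r, 5) = code[r];
  }

  int nterm = (int)addr.size();
  IntegerVector term_ids(nterm);
  List addresses(nterm);
  int idx = 0;
  for (std::map<int, std::vector<std::pair<int, int> > >::const_iterator it = addr.begin();
       it != addr.end(); ++it, ++idx) {
    term_ids[idx] = it->first;
    const std::vector<std::pair<int, int> > &v = it->second;
    IntegerMatrix A((int)v.size(), 2);
    for (int r = 0; r < (int)v.size(); ++r) {
      A(r, 0) = v[r].first;
      A(r, 1) = v[r].second;
    }
    addresses[idx] = A;
  }

  return List::create(_["M"] = M, _["nu"] = nu, _["k"] = k,
                      _["n_windows"] = n_windows,
                      _["terminals"] = term_ids,
                      _["addresses"] = addresses);
}

// Exact trie walk. Returns terminal node id, or 0 when the path is absent.
// [[Rcpp::export]]
int smt_walk(NumericMatrix M, std::string query) {
  int node = 1;
  for (size_t i = 0; i < query.size(); ++i) {
    int b = base_code(query[i]);
    if (b < 0) return 0;
    int ch = (int)M(node - 1, b);
    if (ch == 0) return 0;
    node = ch;
  }
  return node;
}

struct KdiveAcc {
  std::vector<int> nodes;
  std::vector<int> dists;
  std::vector<std::string> kmers;
  bool resp;
  bool collect;
};

// Depth-first bounded-mismatch search. Base case 1 prunes once the
// mismatch budget is exceeded; base case 2 (depth == k) records a match.
static void kdive_rec(const NumericMatrix &M, const std::vector<int> &q,
                      int d_max, int d, int i, int k, int node,
                      std::string &path, KdiveAcc &acc) {
  if (d > d_max) return;
  if (i >= k) {
    acc.resp = true;
    if (acc.collect) {
      acc.nodes.push_back(node);
      acc.dists.push_back(d);
      acc.kmers.push_back(path);
    }
    return;
  }
  if (!acc.collect && acc.resp) return; // decision already made
  for (int b = 0; b < 4; ++b) {
    int ch = (int)M(node - 1, b);
    if (ch == 0) continue;
    path.push_back(BASES[b]);
    kdive_rec(M, q, d_max, d + (q[(size_t)i] == b ? 0 : 1), i + 1, k, ch, path, acc);
    path.pop_back();
  }
}

// [[Rcpp::export]]
List smt_kdive(NumericMatrix M, int k, std::string query, int d_max, bool collect) {
  std::vector<int> q(k);
  for (int i = 0; i < k; ++i) q[i] = base_code(query[(size_t)i]);
  KdiveAcc acc; acc.resp = false; acc.collect = collect;
  std::string path; path.reserve(k);
  kdive_rec(M, q, d_max, 0, 0, k, 1, path, acc);
  return List::create(_["found"] = acc.resp,
                      _["node"] = wrap(acc.nodes),
                      _["distance"] = wrap(acc.dists),
                      _["kmer"] = wrap(acc.kmers));
}

static void kmers_rec(const NumericMatrix &M, int k, int node, int depth,
                      std::string &path, std::vector<int> &nodes,
                      std::vector<double> &counts, std::vector<std::string> &kmers) {
  if (depth == k) {
    nodes.push_back(node);
    counts.push_back(M(node - 1, 4));
    kmers.push_back(path);
    return;
  }
  for (int b = 0; b < 4; ++b) {
    int ch = (int)M(node - 1, b);
    if (ch == 0) continue;
    path.push_back(BASES[b]);
    kmers_rec(M, k, ch, depth + 1, path, nodes, counts, kmers);
    path.pop_back();
  }
}

// Enumerate every stored k-mer (depth-k terminal) with its node id and count.
// [[Rcpp::export]]
List smt_kmers(NumericMatrix M, int k) {
  std::vector<int> nodes;
  std::vector<double> counts;
  std::vector<std::string> kmers;
  std::string path; path.reserve(k);
  kmers_rec(M, k, 1, 0, path, nodes, counts, kmers);
  return List::create(_["node"] = wrap(nodes), _["count"] = wrap(counts),
                      _["kmer"] = wrap(kmers));
}
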