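#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Per-observation accumulation for the quality-aware de Bruijn graph.
// Each vertex tracks: total observation count, number of distinct supporting
// reads, and the per-position sum of Phred qualities over all observations.
// Edges are observed (k+1)-mers with their observation frequency.

namespace {

struct VertexAcc {
  int count = 0;
  int distinct_reads = 0;
  int last_read = -1;
  std::vector<int> qual_sums;
};

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

inline bool valid_window(const std::string &s, size_t start, size_t len) {
  for (size_t i = start; i < start + len; ++i) {
    char c = s[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  }
  return true;
}

void add_strand(const std::string &seq, const std::string &qual, int k, int rid,
                std::unordered_map<std::string, VertexAcc> &vertices,
                std::unordered_map<std::string, int> &edges) {
  const int n = seq.size();
  for (int p = 0; p + k <= n; ++p) {
    if (!valid_window(seq, p, k)) continue;
    std::string km = seq.substr(p, k);
    VertexAcc &v = vertices[km];
    if (v.qual_sums.empty()) v.qual_sums.assign(k, 0);
    v.count += 1;
    if (v.last_read != rid) {
      v.distinct_reads += 1;
      v.last_read = rid;
    }
    for (int i = 0; i < k; ++i) v.qual_sums[i] += (int)qual[p + i] - 33;
  }
  for (int p = 0; p + k + 1 <= n; ++p) {
    if (!valid_window(seq, p, k + 1)) continue;
    edges[seq.substr(p, k + 1)] += 1;
  }
}

} // namespace

// [[Rcpp::export(name = ".dbg_count_kmers")]]
List dbg_count_kmers(CharacterVector reads, CharacterVector quals, int k,
                     bool both_strands = true) {
  if (reads.size() != quals.size())
    stop("reads and quals must have equal length");
  std::unordered_map<std::string, VertexAcc> vertices;
  std::unordered_map<std::string, int> edges;
  int n_short = 0;

  for (int r = 0; r < reads.size(); ++r) {
    std::string seq = as<std::string>(reads[r]);
    std::string qual = as<std::string>(quals[r]);
    if ((int)seq.size() < k) { ++n_short; continue; }
    if (seq.size() != qual.size()) stop("sequence/quality length mismatch at read %d", r + 1);
    add_strand(seq, qual, k, r, vertices, edges);
    if (both_strands) {
      std::string rc(seq.rbegin(), seq.rend());
      for (auto &c : rc) c = comp_base(c);
      std::string rq(qual.rbegin(), qual.rend());
      add_strand(rc, rq, k, r, vertices, edges);
    }
  }

  const int nv = vertices.size();
  CharacterVector kmer(nv);
  IntegerVector count(nv), distinct_reads(nv);
  IntegerMatrix qual_sums(nv, k);
  int i = 0;
  for (auto &kv : vertices) {
    kmer[i] = kv.first;
    count[i] = kv.second.count;
    distinct_reads[i] = kv.second.distinct_reads;
    for (int j = 0; j < k; ++j) qual_sums(i, j) = kv.second.qual_sums[j];
    ++i;
  }
  const int ne = edges.size();
  CharacterVector ekmer(ne);
  IntegerVector efreq(ne);
  i = 0;
  for (auto &kv : edges) {
    ekmer[i] = kv.first;
    efreq[i] = kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count,
                      _["distinct_reads"] = distinct_reads,
                      _["qual_sums"] = qual_sums, _["edge_kmer"] = ekmer,
                      _["edge_freq"] = efreq, _["n_short_reads"] = n_short);
}

// Count perfect ungapped matches of a 16-mer anchor at every offset of a
// contig; returns the Hamming distance at each start position.
// [[Rcpp::export(name = ".hamming_scan")]]
IntegerVector hamming_scan(std::string contig, std::string pattern) {
  const int n = contig.size(), m = pattern.size();
  if (n < m) return IntegerVector(0);
  IntegerVector out(n - m + 1);
  for (int p = 0; p + m <= n; ++p) {
    int mm = 0;
    for (int i = 0; i < m; ++i)
      if (contig[p + i] != pattern[i]) ++mm;
    out[p] = mm;
  }
  return out;
}

// Best (minimum) Hamming distance of `pattern` over all windows of each
// subject sequence; used for isotype tail matching and truth evaluation.
// Returns a list with per-subject best mismatch count and its offset (0-based,
// -1 when the subject is shorter than the pattern).
// [[Rcpp::export(name = ".best_window_mismatch")]]
List best_window_mismatch(CharacterVector subjects, std::string pattern,
                          int stop_at = -1) {
  const int m = pattern.size();
  IntegerVector best(subjects.size()), offset(subjects.size());
  for (int s = 0; s < subjects.size(); ++s) {
    std::string subj = as<std::string>(subjects[s]);
    const int n = subj.size();
    if (n < m) { best[s] = NA_INTEGER; offset[s] = -1; continue; }
    int bmm = m + 1, boff = -1;
    for (int p = 0; p + m <= n; ++p) {
      int mm = 0;
      for (int i = 0; i < m && mm < bmm; ++i)
        if (subj[p + i] != pattern[i]) ++mm;
      if (mm < bmm) { bmm = mm; boff = p; }
      if (stop_at >= 0 && bmm <= stop_at) break;
    }
    best[s] = bmm;
    offset[s] = boff;
  }
  return List::create(_["mismatches"] = best, _["offset"] = offset);
}
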