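// k-mer machinery shared by the assembler, the read assigner and the
// assembly evaluator.  k is limited to 31 so a k-mer packs into 62 bits.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <array>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_code(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

static inline std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = CODE2BASE[x & 3ULL];
    x >>= 2;
  }
  return s;
}

// Call fn(offset0, fwd_code) for every k-mer free of non-ACGT bases.
template <typename F>
static void for_each_kmer(const std::string& s, int k, F fn) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t val = 0;
  int run = 0;
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint64_t)c) & mask;
    if (++run >= k) fn(i - k + 1, val);
  }
}

typedef std::unordered_map<uint64_t, uint32_t> KmerCounts;

static KmerCounts count_canonical(const std::vector<std::string>& seqs, int k) {
  KmerCounts counts;
  for (const auto& s : seqs) {
    for_each_kmer(s, k, [&](int, uint64_t fwd) {
      uint64_t rc = revcomp_code(fwd, k);
      uint64_t canon = std::min(fwd, rc);
      ++counts[canon];
    });
  }
  return counts;
}

// ---------------------------------------------------------------------------
// de Bruijn unitig assembly on a filtered canonical k-mer set
// ---------------------------------------------------------------------------

struct Oriented {
  uint64_t canon;
  bool flipped;  // true: the oriented k-mer is revcomp(canon)
};

struct DbgSet {
  int k;
  uint64_t mask;
  const KmerCounts* kmers;
  bool has(uint64_t canon) const { return kmers->find(canon) != kmers->end(); }
  uint64_t seq_of(const Oriented& o) const {
    return o.flipped ? revcomp_code(o.canon, k) : o.canon;
  }
  // forward extensions of the oriented k-mer that exist in the set
  int successors(const Oriented& o, std::array<Oriented, 4>& out) const {
    uint64_t seq = seq_of(o);
    int n = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t nxt = ((seq << 2) | b) & mask;
      uint64_t rc = revcomp_code(nxt, k);
      uint64_t canon = std::min(nxt, rc);
      if (has(canon)) out[n++] = Oriented{canon, canon != nxt};
    }
    return n;
  }
  int predecessor_count(const Oriented& o) const {
    uint64_t seq = seq_of(o);
    int n = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t prv = (b << (2 * (k - 1))) | (seq >> 2);
      uint64_t rc = revcomp_code(prv, k);
      if (has(std::min(prv, rc))) ++n;
    }
    return n;
  }
};

struct Unitig {
  std::string seq;
  std::vector<uint64_t> path;  // canonical k-mers along the unitig
  bool left_dead, right_dead;
};

static std::vector<Unitig> build_unitigs(const DbgSet& dbg) {
  std::vector<uint64_t> keys;
  keys.reserve(dbg.kmers->size());
  for (const auto& kv : *dbg.kmers) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());  // deterministic traversal order

  std::unordered_set<uint64_t> visited;
  std::vector<Unitig> out;
  std::array<Oriented, 4> succ;

  for (uint64_t key : keys) {
    if (visited.count(key)) continue;
    std::vector<Oriented> path;
    path.push_back(Oriented{key, false});
    visited.insert(key);
    // extend forward
    bool right_dead = false;
    for (;;) {
      int ns = dbg.successors(path.back(), succ);
      if (ns == 0) { right_dead = true; break; }
      if (ns > 1) break;
      Oriented nxt = succ[0];
      if (visited.count(nxt.canon)) break;
      if (dbg.predecessor_count(nxt) != 1) break;
      path.push_back(nxt);
      visited.insert(nxt.canon);
    }
    // extend backward: walk forward from the flipped seed, then reverse
    std::vector<Oriented> back;
    Oriented cur{key, true};
    bool left_dead = false;
    for (;;) {
      int ns = dbg.successors(cur, succ);
      if (ns == 0) { left_dead = true; break; }
      if (ns > 1) break;
      Oriented nxt = succ[0];
      if (visited.count(nxt.canon)) break;
      if (dbg.predecessor_count(nxt) != 1) break;
      back.push_back(nxt);
      visited.insert(nxt.canon);
      cur = nxt;
    }
    // stitch: reverse(back, flipped) + path
    std::vector<Oriented> full;
    full.reserve(back.size() + path.size());
    for (auto it = back.rbegin(); it != back.rend(); ++it)
      full.push_back(Oriented{it->canon, !it->flipped});
    for (const auto& o : path) full.push_back(o);

    Unitig u;
    u.seq = decode_kmer(dbg.seq_of(full[0]), dbg.k);
    u.path.reserve(full.size());
    for (size_t i = 0; i < full.size(); ++i) {
      u.path.push_back(full[i].canon);
      if (i > 0) u.seq.push_back(CODE2BASE[dbg.seq_of(full[i]) & 3ULL]);
    }
    u.left_dead = left_dead;
    u.right_dead = right_dead;
    out.push_back(std::move(u));
  }
  return out;
}

// Abundance-threshold auto-selection: with substitution errors, k-mers seen
// once or twice are overwhelmingly error k-mers whose frequency grows with
// depth; the histogram of k-mer multiplicities is bimodal (error peak at 1,
// coverage peak near the sequencing depth).  The valley between the two is
// the classical coverage cutoff.  Only applied when a clear coverage peak
// exists (>= 8), so low-coverage/error-free desk-scale uses are unaffected.
static int auto_cutoff(const KmerCounts& counts, int min_count) {
  const int CAP = 255;
  std::vector<double> hist(CAP + 1, 0.0);
  for (const auto& kv : counts) {
    int c = (int)std::min<uint32_t>(kv.second, CAP);
    hist[c] += 1.0;
  }
  // walk past the initial error decay, then locate the coverage peak
  int fmin = 2;
  while (fmin < CAP && hist[fmin + 1] < hist[fmin]) ++fmin;
  int peak = fmin;
  for (int c = fmin; c <= CAP; ++c) if (hist[c] > hist[peak]) peak = c;
  if (peak < 8) return min_count;
  int valley = min_count < 1 ? 1 : min_count;
  for (int c = valley + 1; c <= peak; ++c) {
    if (hist[c] < hist[valley]) valley = c;
  }
  return std::max(min_count, valley);
}

// [[Rcpp::export]]
List cpp_assemble(CharacterVector seqs, int k, int min_count, int tip_max_len,
                  bool auto_min_count) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  std::vector<std::string> ss(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) ss[i] = as<std::string>(seqs[i]);

  KmerCounts counts = count_canonical(ss, k);
  if (auto_min_count) min_count = auto_cutoff(counts, min_count);
  for (auto it = counts.begin(); it != counts.end();) {
    if ((int)it->second < min_count) it = counts.erase(it);
    else ++it;
  }

  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  DbgSet dbg{k, mask, &counts};

  // iterative tip clipping: drop short unitigs hanging off a junction
  for (int round = 0; round < 5; ++round) {
    std::vector<Unitig> unis = build_unitigs(dbg);
    bool removed = false;
    for (const auto& u : unis) {
      bool tip = ((int)u.seq.size() < tip_max_len) &&
                 ((u.left_dead && !u.right_dead) ||
                  (!u.left_dead && u.right_dead));
      if (tip) {
        for (uint64_t km : u.path) counts.erase(km);
        removed = true;
      }
    }
    if (!removed) break;
  }

  std::vector<Unitig> unis = build_unitigs(dbg);
  // keep unitigs of length >= 2k; sort by (length desc, canonical sequence)
  std::vector<std::pair<std::string, double>> keep;
  KmerCounts full = count_canonical(ss, k);
  for (const auto& u : unis) {
    if ((int)u.seq.size() < 2 * k) continue;
    double cov = 0.0;
    for (uint64_t km : u.path) cov += full[km];
    cov /= (double)u.path.size();
    keep.push_back({u.seq, cov});
  }
  auto canon_seq = [](const std::string& s) {
    std::string rc(s.rbegin(), s.rend());
    for (auto& c : rc) {
      switch (c) { case 'A': c = 'T'; break; case 'C': c = 'G'; break;
                   case 'G': c = 'C'; break; case 'T': c = 'A'; break; }
    }
    return std::min(s, rc);
  };
  std::sort(keep.begin(), keep.end(),
            [&](const std::pair<std::string, double>& a,
                const std::pair<std::string, double>& b) {
              if (a.first.size() != b.first.size())
                return a.first.size() > b.first.size();
              return canon_seq(a.first) < canon_seq(b.first);
            });

  CharacterVector cseq(keep.size());
  NumericVector ccov(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) {
    cseq[i] = canon_seq(keep[i].first);
    ccov[i] = keep[i].second;
  }
  return List::create(_["sequence"] = cseq, _["coverage"] = ccov,
                      _["min_count_used"] = min_count);
}

// ---------------------------------------------------------------------------
// k-mer index over contigs + read assignment by k-mer voting
// ---------------------------------------------------------------------------

struct Hit { int32_t contig; int32_t pos; int8_t strand; };  // strand 0: canonical written forward

struct KIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<Hit>> map;
  int n_contigs;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector contig_seqs, int k) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  XPtr<KIndex> idx(new KIndex(), true);
  idx->k = k;
  idx->n_contigs = (int)contig_seqs.size();
  for (R_xlen_t ci = 0; ci < contig_seqs.size(); ++ci) {
    std::string s = as<std::string>(contig_seqs[ci]);
    for_each_kmer(s, k, [&](int off, uint64_t fwd) {
      uint64_t rc = revcomp_code(fwd, k);
      uint64_t canon = std::min(fwd, rc);
      idx->map[canon].push_back(
          Hit{(int32_t)ci, (int32_t)(off + 1), (int8_t)(canon == fwd ? 0 : 1)});
    });
  }
  return idx;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP index) { return XPtr<KIndex>(index)->k; }

// [[Rcpp::export]]
int cpp_index_size(SEXP index) { return (int)XPtr<KIndex>(index)->map.size(); }

// [[Rcpp::export]]
List cpp_index_lookup(SEXP index, std::string kmer) {
  XPtr<KIndex> idx(index);
  if ((int)kmer.size() != idx->k) stop("k-mer length must equal index k");
  uint64_t fwd = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b < 0) return List::create();
    fwd = (fwd << 2) | (uint64_t)b;
  }
  uint64_t canon = std::min(fwd, revcomp_code(fwd, idx->k));
  auto it = idx->map.find(canon);
  if (it == idx->map.end())
    return List::create(_["contig"] = IntegerVector(0),
                        _["pos"] = IntegerVector(0),
                        _["strand"] = CharacterVector(0));
  const auto& v = it->second;
  IntegerVector contig(v.size()), pos(v.size());
  CharacterVector strand(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    contig[i] = v[i].contig + 1;
    pos[i] = v[i].pos;
    strand[i] = v[i].strand == 0 ? "+" : "-";
  }
  return List::create(_["contig"] = contig, _["pos"] = pos,
                      _["strand"] = strand);
}

// [[Rcpp::export]]
DataFrame cpp_assign_reads(SEXP index, CharacterVector read_seqs,
                           double min_frac) {
  XPtr<KIndex> idx(index);
  const int k = idx->k;
  const R_xlen_t n = read_seqs.size();
  IntegerVector contig(n, NA_INTEGER), start(n, NA_INTEGER);
  CharacterVector strand(n);
  NumericVector frac(n, NA_REAL);

  std::unordered_map<int64_t, int32_t> votes;
  std::unordered_map<int64_t, std::pair<int32_t, int32_t>> first_hit;

  for (R_xlen_t ri = 0; ri < n; ++ri) {
    strand[ri] = NA_STRING;
    std::string s = as<std::string>(read_seqs[ri]);
    const int L = (int)s.size();
    if (L < k) continue;
    votes.clear();
    first_hit.clear();
    int total = 0;
    for_each_kmer(s, k, [&](int off, uint64_t fwd) {
      ++total;
      uint64_t rc = revcomp_code(fwd, k);
      uint64_t canon = std::min(fwd, rc);
      bool read_flipped = (canon != fwd);
      auto it = idx->map.find(canon);
      if (it == idx->map.end()) return;
      // one vote per (contig, strand) per read k-mer position
      std::unordered_set<int64_t> seen;
      for (const Hit& h : it->second) {
        int eff = ((h.strand == 1) == read_flipped) ? 0 : 1;  // 0:+, 1:-
        int64_t key = ((int64_t)h.contig << 1) | eff;
        if (!seen.insert(key).second) continue;
        ++votes[key];
        if (!first_hit.count(key)) first_hit[key] = {off, h.pos};
      }
    });
    if (total == 0) continue;
    int32_t best = -1, second = -1;
    int64_t best_key = -1;
    for (const auto& kv : votes) {
      if (kv.second > best) {
        second = best; best = kv.second; best_key = kv.first;
      } else if (kv.second > second) {
        second = kv.second;
      }
    }
    if (best < 0) continue;
    double f = (double)best / (double)total;
    if (f < min_frac) continue;
    if (second == best) continue;  // tie -> unassigned
    int ci = (int)(best_key >> 1);
    int eff = (int)(best_key & 1);
    auto fh = first_hit[best_key];
    int st = (eff == 0) ? (fh.second - fh.first)
                        : (fh.second - (L - k - fh.first));
    contig[ri] = ci + 1;
    start[ri] = std::max(1, st);
    strand[ri] = (eff == 0) ? "+" : "-";
    frac[ri] = f;
  }
  return DataFrame::create(_["contig"] = contig, _["start"] = start,
                           _["strand"] = strand, _["frac"] = frac,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// exact k-mer set comparison: assembly completeness / contamination
// ---------------------------------------------------------------------------

static std::unordered_set<uint64_t> kmer_set(const std::vector<std::string>& ss,
                                             int k) {
  std::unordered_set<uint64_t> out;
  for (const auto& s : ss) {
    for_each_kmer(s, k, [&](int, uint64_t fwd) {
      out.insert(std::min(fwd, revcomp_code(fwd, k)));
    });
  }
  return out;
}

static std::vector<std::string> to_vec(CharacterVector x) {
  std::vector<std::string> v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v[i] = as<std::string>(x[i]);
  return v;
}

// [[Rcpp::export]]
List cpp_kmer_compare(CharacterVector contigs, CharacterVector target,
                      CharacterVector contaminant, int k) {
  auto cset = kmer_set(to_vec(contigs), k);
  auto tset = kmer_set(to_vec(target), k);
  auto xset = kmer_set(to_vec(contaminant), k);
  size_t t_in_c = 0;
  for (uint64_t km : tset) if (cset.count(km)) ++t_in_c;
  size_t contam = 0;
  for (uint64_t km : cset) if (xset.count(km) && !tset.count(km)) ++contam;
  double completeness = tset.empty() ? NA_REAL : (double)t_in_c / tset.size();
  double contam_frac = cset.empty() ? NA_REAL : (double)contam / cset.size();
  return List::create(_["target_completeness"] = completeness,
                      _["contaminant_kmer_fraction"] = contam_frac,
                      _["n_contig_kmers"] = (double)cset.size(),
                      _["n_target_kmers"] = (double)tset.size());
}

// ---------------------------------------------------------------------------
// sliding-window quality trimming bounds (qualities as Phred+33 strings)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_trim_bounds(CharacterVector quals, double q_threshold,
                              double window_frac) {
  const R_xlen_t n = quals.size();
  IntegerMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    const int L = (int)q.size();
    out(i, 0) = 0; out(i, 1) = 0;
    if (L == 0) continue;
    int w = (int)std::lround(window_frac * L);
    if (w < 1) w = 1;
    if (w > L) w = L;
    std::vector<double> pre(L + 1, 0.0);
    for (int j = 0; j < L; ++j) pre[j + 1] = pre[j] + (double)(q[j] - 33);
    const int nwin = L - w + 1;
    int good = -1;
    for (int s = 0; s < nwin; ++s) {
      double mean = (pre[s + w] - pre[s]) / w;
      if (mean >= q_threshold) { good = s; break; }
    }
    if (good < 0) continue;
    int bad = -1;
    for (int s = good + 1; s < nwin; ++s) {
      double mean = (pre[s + w] - pre[s]) / w;
      if (mean < q_threshold) { bad = s; break; }
    }
    out(i, 0) = good + 1;                      // 1-based keep start
    out(i, 1) = (bad < 0) ? L : bad;           // keep end = bad start - 1
  }
  return out;
}

// ---------------------------------------------------------------------------
// simulation helpers (use R's RNG -> deterministic under set.seed)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_add_substitutions(CharacterVector seqs, double rate) {
  RNGScope scope;
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (auto& c : s) {
      if (unif_rand() < rate) {
        int b = base_code(c);
        if (b < 0) continue;
        int nb = (b + 1 + (int)(unif_rand() * 3.0)) & 3;
        c = CODE2BASE[nb];
      }
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_phred_strings(IntegerVector lens, double q_mean,
                                  double q_decay, double q_sd) {
  RNGScope scope;
  CharacterVector out(lens.size());
  for (R_xlen_t i = 0; i < lens.size(); ++i) {
    int L = lens[i];
    std::string q(L, '!');
    for (int j = 0; j < L; ++j) {
      double v = q_mean - q_decay * j + norm_rand() * q_sd;
      int iv = (int)std::lround(v);
      if (iv < 2) iv = 2;
      if (iv > 40) iv = 40;
      q[j] = (char)(iv + 33);
    }
    out[i] = q;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_kmer_hist(CharacterVector seqs, int k, int cap = 255) {
  std::vector<std::string> ss = to_vec(seqs);
  KmerCounts counts = count_canonical(ss, k);
  NumericVector hist(cap + 1);
  for (const auto& kv : counts) {
    int c = (int)std::min<uint32_t>(kv.second, (uint32_t)cap);
    hist[c] += 1.0;
  }
  return hist;
}
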