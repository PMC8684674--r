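#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const int NEG_INF = INT32_MIN / 4;

static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) r[j] = comp(s[s.size() - 1 - j]);
    out[i] = r;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}

// Full affine-gap local alignment (Smith-Waterman) best score: exhaustive
// quadratic DP, no banding, no seeding, no traceback.  Used as the reference
// the seeded engine is checked against.  gap_open/gap_extend are <= 0; a gap
// of length L costs gap_open + L*gap_extend.
// [[Rcpp::export]]
int sw_score_cpp(std::string a, std::string b, int match, int mismatch,
                 int gap_open, int gap_extend) {
  int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> H(n + 1, 0);        // H[i-1][j] rolling
  std::vector<int> F(n + 1, NEG_INF);  // F[.][j] (gap consuming query)
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;        // H[i-1][j-1]
    int E = NEG_INF;      // E[i][j] (gap consuming subject)
    int Hprevcol = 0;     // H[i][j-1]
    for (int j = 1; j <= n; ++j) {
      E = std::max(Hprevcol + gap_open + gap_extend, E + gap_extend);
      F[j] = std::max(H[j] + gap_open + gap_extend, F[j] + gap_extend);
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int h = Hdiag + s;
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      Hprevcol = h;
      if (h > best) best = h;
    }
  }
  return best;
}

struct Seed { int qpos, spos; };

struct Cluster {
  int dmin, dmax, last_spos, min_spos, max_send, min_qpos, max_qend, n;
};

struct Hit {
  int qidx, sidx, orient;
  int q_start, q_end, s_start, s_end;
  int score, n_match, n_cols;
  bool band_edge;   // alignment path touched a restricted diagonal bound
};

// Banded local alignment with traceback inside a subject window [slo, shi).
// Diagonal d = (subject consumed) - (query consumed) restricted to [dlo, dhi].
// Out-of-band predecessors fall back to a fresh local start (score 0), so the
// banded score is always a lower bound on the full SW score and equals it
// when the band covers every diagonal of the window.
static bool banded_align(const std::string &q, const std::string &subj,
                         int slo, int shi, int dlo, int dhi,
                         int match, int mismatch, int gap_open, int gap_extend,
                         Hit &out) {
  int m = (int)q.size();
  if (m == 0 || shi - slo <= 0) return false;
  bool dlo_tight = dlo > slo - m;
  bool dhi_tight = dhi < shi;
  if (dlo < slo - m) dlo = slo - m;
  if (dhi > shi) dhi = shi;
  if (dhi < dlo) return false;
  long long W = (long long)dhi - dlo + 1;
  if ((long long)(m + 1) * W > (long long)4e8)
    stop("alignment band too large; reduce band or window");
  std::vector<int> Hp((size_t)W, 0), Fp((size_t)W, NEG_INF);
  std::vector<int> Hc((size_t)W), Ec((size_t)W), Fc((size_t)W);
  // traceback byte: bits 0-1 source of H (0 stop, 1 diag, 2 E, 3 F);
  // bit 2: E extended an existing gap; bit 3: F extended an existing gap
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);
  int best = 0, best_i = -1, best_off = -1;
  for (int i = 1; i <= m; ++i) {
    std::fill(Hc.begin(), Hc.end(), NEG_INF);
    std::fill(Ec.begin(), Ec.end(), NEG_INF);
    std::fill(Fc.begin(), Fc.end(), NEG_INF);
    int s_lo = std::max(slo + 1, i + dlo);  // subject consumed count
    int s_hi = std::min(shi, i + dhi);
    for (int s = s_lo; s <= s_hi; ++s) {
      int off = s - i - dlo;
      int e = NEG_INF; bool eext = false;
      if (off - 1 >= 0 && Hc[off - 1] != NEG_INF) {
        int eo = Hc[off - 1] + gap_open + gap_extend;
        int ee = (Ec[off - 1] != NEG_INF) ? Ec[off - 1] + gap_extend : NEG_INF;
        e = std::max(eo, ee); eext = (ee > eo);
      }
      int f = NEG_INF; bool fext = false;
      if (off + 1 < (int)W && Hp[off + 1] != NEG_INF) {
        int fo = Hp[off + 1] + gap_open + gap_extend;
        int fe = (Fp[off + 1] != NEG_INF) ? Fp[off + 1] + gap_extend : NEG_INF;
        f = std::max(fo, fe); fext = (fe > fo);
      } else if (off + 1 < (int)W && Fp[off + 1] != NEG_INF) {
        f = Fp[off + 1] + gap_extend; fext = true;
      }
      // diagonal predecessor (i-1, s-1) sits at the same offset in the
      // previous row; row 0 and window-edge cells behave as score 0
      int hprev = Hp[off];
      int hd = ((hprev == NEG_INF) ? 0 : hprev) +
               ((q[i - 1] == subj[s - 1]) ? match : mismatch);
      int h = 0; uint8_t src = 0;
      if (hd > h) { h = hd; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      uint8_t t = src;
      if (eext) t |= 4;
      if (fext) t |= 8;
      tb[(size_t)i * W + off] = t;
      Hc[off] = h; Ec[off] = e; Fc[off] = f;
      if (h > best) { best = h; best_i = i; best_off = off; }
    }
    std::swap(Hp, Hc);
    std::swap(Fp, Fc);
  }
  if (best <= 0) return false;

  int i = best_i, off = best_off;
  int n_match = 0, n_cols = 0;
  bool edge = false;
  auto note_edge = [&](int o) {
    if ((o <= 0 && dlo_tight) || (o >= (int)W - 1 && dhi_tight)) edge = true;
  };
  note_edge(off);
  while (i > 0) {
    uint8_t t = tb[(size_t)i * W + off];
    int src = t & 3;
    if (src == 0) break;
    if (src == 1) {
      int s = i + dlo + off;
      if (q[i - 1] == subj[s - 1]) ++n_match;
      ++n_cols;
      i -= 1;  // offset unchanged on the diagonal
    } else if (src == 2) {
      // gap run consuming subject bases, walk left within the row
      while (true) {
        bool ext = (tb[(size_t)i * W + off] & 4) != 0;
        ++n_cols;
        off -= 1;
        if (!ext) break;
      }
    } else {
      // gap run consuming query bases, walk up
      while (i > 0) {
        bool ext = (tb[(size_t)i * W + off] & 8) != 0;
        ++n_cols;
        i -= 1; off += 1;
        if (!ext) break;
      }
    }
    note_edge(off);
  }
  out.q_start = i;
  out.s_start = i + dlo + off;
  out.q_end = best_i;
  out.s_end = best_i + dlo + best_off;
  out.score = best; out.n_match = n_match; out.n_cols = n_cols;
  out.band_edge = edge;
  return true;
}

// Seed-and-extend local alignment of queries (both strands) against subjects.
// Exact k-mer seeds are grouped into diagonal clusters; each cluster is
// extended by banded affine-gap DP.  Coordinates in the result are 0-based
// half-open on the forward orientation of both query and subject.
// [[Rcpp::export]]
DataFrame seed_align_cpp(CharacterVector query_ids, CharacterVector query_seqs,
                         CharacterVector subj_ids, CharacterVector subj_seqs,
                         int k, int band,
                         int match, int mismatch, int gap_open, int gap_extend,
                         double karlin_lambda, double karlin_k,
                         double evalue_max, double search_space) {
  int nq = query_ids.size(), ns = subj_ids.size();
  std::vector<std::string> qf(nq), qr(nq);
  for (int i = 0; i < nq; ++i) {
    qf[i] = as<std::string>(query_seqs[i]);
    std::string r(qf[i].size(), 'N');
    for (size_t j = 0; j < qf[i].size(); ++j) r[j] = comp(qf[i][qf[i].size() - 1 - j]);
    qr[i] = r;
  }
  double total_subj_len = 0;
  for (int i = 0; i < ns; ++i)
    total_subj_len += (double)LENGTH(STRING_ELT(subj_seqs, i));

  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  struct QPos { int32_t key; int32_t qpos; };  // key = qidx*2 + orient
  std::unordered_map<uint64_t, std::vector<QPos>> idx;
  for (int qi = 0; qi < nq; ++qi) {
    for (int orient = 0; orient < 2; ++orient) {
      const std::string &s = orient ? qr[qi] : qf[qi];
      int len = (int)s.size();
      if (len < k) continue;
      uint64_t km = 0; int valid = 0;
      for (int p = 0; p < len; ++p) {
        int b = base2(s[p]);
        if (b < 0) { valid = 0; km = 0; continue; }
        km = ((km << 2) | (uint64_t)b) & mask;
        if (++valid >= k) idx[km].push_back({qi * 2 + orient, p - k + 1});
      }
    }
  }

  const int seed_gap = 1000;
  std::vector<Hit> hits;

  for (int si = 0; si < ns; ++si) {
    std::string ss = as<std::string>(subj_seqs[si]);
    int slen = (int)ss.size();
    if (slen < k) continue;
    std::unordered_map<int, std::vector<Seed>> seeds;
    uint64_t km = 0; int valid = 0;
    for (int p = 0; p < slen; ++p) {
      int b = base2(ss[p]);
      if (b < 0) { valid = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        auto it = idx.find(km);
        if (it != idx.end())
          for (const QPos &qp : it->second)
            seeds[qp.key].push_back({qp.qpos, p - k + 1});
      }
    }
    for (auto &kv : seeds) {
      int qi = kv.first / 2, orient = kv.first % 2;
      const std::string &q = orient ? qr[qi] : qf[qi];
      int m = (int)q.size();
      std::vector<Seed> &sv = kv.second;
      std::sort(sv.begin(), sv.end(), [](const Seed &a, const Seed &b) {
        return a.spos < b.spos || (a.spos == b.spos && a.qpos < b.qpos);
      });
      std::vector<Cluster> clusters;
      for (const Seed &sd : sv) {
        int d = sd.spos - sd.qpos;
        bool placed = false;
        // scan all open clusters: creation order does not track recency,
        // so a stale chance-seed cluster must not shadow an older cluster
        // that is still collecting seeds
        for (int ci = (int)clusters.size() - 1; ci >= 0; --ci) {
          Cluster &c = clusters[ci];
          if (sd.spos - c.last_spos > seed_gap) continue;
          if (d >= c.dmin - band && d <= c.dmax + band) {
            c.dmin = std::min(c.dmin, d); c.dmax = std::max(c.dmax, d);
            c.last_spos = std::max(c.last_spos, sd.spos);
            c.min_spos = std::min(c.min_spos, sd.spos);
            c.max_send = std::max(c.max_send, sd.spos + k);
            c.min_qpos = std::min(c.min_qpos, sd.qpos);
            c.max_qend = std::max(c.max_qend, sd.qpos + k);
            c.n += 1; placed = true; break;
          }
        }
        if (!placed)
          clusters.push_back({d, d, sd.spos, sd.spos, sd.spos + k,
                              sd.qpos, sd.qpos + k, 1});
      }
      for (const Cluster &c : clusters) {
        // restrict the DP to the seeded query range padded by the band
        // plus a margin, so chance single-seed clusters stay cheap; if the
        // optimal alignment runs into the restricted boundary, retry with
        // a larger pad until it ends strictly inside (the alignment can
        // legitimately extend far beyond the outermost seed when errors
        // leave a long seedless stretch)
        const int margin = 128;   // stop-short tolerance near a cap
        int qpad = std::max(2 * margin, band + 64);
        int bandw = band;
        Hit h;
        bool ok = false;
        int q_lo = 0, q_hi = m, wlo = 0, whi = slen;
        for (int attempt = 0; attempt < 8; ++attempt) {
          q_lo = std::max(0, c.min_qpos - qpad);
          q_hi = std::min(m, c.max_qend + qpad);
          std::string qsub = q.substr(q_lo, q_hi - q_lo);
          int pad_l = (c.min_qpos - q_lo) + bandw + 16;
          int pad_r = (q_hi - c.max_qend) + bandw + 16;
          wlo = std::max(0, c.min_spos - pad_l);
          whi = std::min(slen, c.max_send + pad_r);
          ok = banded_align(qsub, ss, wlo, whi,
                            c.dmin + q_lo - bandw, c.dmax + q_lo + bandw,
                            match, mismatch, gap_open, gap_extend, h);
          if (!ok) break;
          bool touch = h.band_edge ||
            (q_lo > 0 && h.q_start < margin) ||
            (q_hi < m && h.q_end > (q_hi - q_lo) - margin) ||
            (wlo > 0 && h.s_start < wlo + margin) ||
            (whi < slen && h.s_end > whi - margin);
          if (!touch) break;
          qpad *= 4;
          bandw *= 2;
        }
        if (!ok) continue;
        h.q_start += q_lo; h.q_end += q_lo;
        h.qidx = qi; h.sidx = si; h.orient = orient;
        if (orient) {  // report on the query's forward orientation
          int qs = m - h.q_end, qe = m - h.q_start;
          h.q_start = qs; h.q_end = qe;
        }
        hits.push_back(h);
      }
    }
  }

  // E-value threshold, then per (query, subject, strand) overlap dedup:
  // a cluster can be discovered twice (split seeds), keep the best-scoring
  // representative of any pile of mutually overlapping hits
  std::vector<int> keep;
  {
    std::vector<int> ord(hits.size());
    for (size_t i = 0; i < hits.size(); ++i) ord[i] = (int)i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (hits[a].score != hits[b].score) return hits[a].score > hits[b].score;
      if (hits[a].sidx != hits[b].sidx) return hits[a].sidx < hits[b].sidx;
      return hits[a].s_start < hits[b].s_start;
    });
    std::unordered_map<int64_t, std::vector<int>> kept_by_group;
    for (int id : ord) {
      const Hit &h = hits[id];
      double m = (double)(qf[h.qidx].size());
      double space = (search_space > 0) ? search_space : m * total_subj_len;
      double ev = karlin_k * space * std::exp(-karlin_lambda * (double)h.score);
      if (ev > evalue_max) continue;
      int64_t gk = ((int64_t)h.qidx * ns + h.sidx) * 2 + h.orient;
      auto &kept = kept_by_group[gk];
      bool overlap = false;
      for (int prev : kept) {
        const Hit &p = hits[prev];
        // subject overlap only: the same query region may genuinely hit
        // several subject loci (repeats), and those hits must all survive
        // so that downstream uniqueness filters can see them
        int ov_s = std::min(h.s_end, p.s_end) - std::max(h.s_start, p.s_start);
        int sh_s = std::min(h.s_end - h.s_start, p.s_end - p.s_start);
        if (ov_s > 0 && ov_s >= 0.3 * sh_s) { overlap = true; break; }
      }
      if (!overlap) { kept.push_back(id); keep.push_back(id); }
    }
  }

  int nh = (int)keep.size();
  CharacterVector o_qid(nh), o_sid(nh), o_strand(nh);
  IntegerVector o_qs(nh), o_qe(nh), o_ss(nh), o_se(nh), o_len(nh), o_score(nh);
  NumericVector o_ident(nh), o_bits(nh), o_ev(nh);
  double ln2 = std::log(2.0);
  for (int i = 0; i < nh; ++i) {
    const Hit &h = hits[keep[i]];
    o_qid[i] = query_ids[h.qidx];
    o_sid[i] = subj_ids[h.sidx];
    o_strand[i] = h.orient ? "-" : "+";
    o_qs[i] = h.q_start; o_qe[i] = h.q_end;
    o_ss[i] = h.s_start; o_se[i] = h.s_end;
    o_len[i] = h.n_cols;
    o_score[i] = h.score;
    o_ident[i] = 100.0 * (double)h.n_match / (double)h.n_cols;
    double m = (double)(qf[h.qidx].size());
    double space = (search_space > 0) ? search_space : m * total_subj_len;
    o_ev[i] = karlin_k * space * std::exp(-karlin_lambda * (double)h.score);
    o_bits[i] = (karlin_lambda * (double)h.score - std::log(karlin_k)) / ln2;
  }
  return DataFrame::create(
    _["query_id"] = o_qid, _["subject_id"] = o_sid,
    _["q_start"] = o_qs, _["q_end"] = o_qe,
    _["s_start"] = o_ss, _["s_end"] = o_se,
    _["strand"] = o_strand, _["identity_pct"] = o_ident,
    _["aligned_len"] = o_len, _["score"] = o_score,
    _["bitscore"] = o_bits, _["evalue"] = o_ev,
    _["stringsAsFactors"] = false);
}

// Random DNA of given length and GC fraction; draws from R's RNG so
// set.seed() makes it reproducible.
// [[Rcpp::export]]
std::string random_dna_cpp(int n, double gc) {
  std::string s(n, 'A');
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    if (u < gc / 2) s[i] = 'G';
    else if (u < gc) s[i] = 'C';
    else if (u < gc + (1 - gc) / 2) s[i] = 'A';
    else s[i] = 'T';
  }
  PutRNGstate();
  return s;
}

// i.i.d. per-base substitution / insertion / deletion errors (R's RNG).
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double p_sub,
                                double p_ins, double p_del) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  GetRNGstate();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r;
    r.reserve((size_t)(s.size() * (1.0 + p_ins + 0.01)) + 16);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < p_del) {
        // base dropped
      } else {
        char c = s[j];
        if (unif_rand() < p_sub) {
          char nc;
          do { nc = bases[(int)(unif_rand() * 4) & 3]; } while (nc == c);
          c = nc;
        }
        r.push_back(c);
      }
      if (unif_rand() < p_ins) r.push_back(bases[(int)(unif_rand() * 4) & 3]);
    }
    out[i] = r;
  }
  PutRNGstate();
  out.attr("names") = seqs.attr("names");
  return out;
}
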