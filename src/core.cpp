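#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cctype>
#include <cstdint>
#include <cstring>
#include <map>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

inline int baseCode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

inline char codeBase(int i) { return "ACGT"[i]; }

inline char complBase(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = complBase(r[i]);
  return r;
}

// Hamming distance with early exit once maxd is exceeded.
int hammingLeq(const char* a, const char* b, int n, int maxd) {
  int d = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i] && ++d > maxd) return maxd + 1;
  }
  return d;
}

// Ends-free (overlap) alignment of a vs b, restricted to diagonals
// j - i within [min(0, m-n) - band, max(0, m-n) + band].  Scoring is
// match +1, mismatch/gap -1; identity is matches / alignment columns with
// terminal (free) gap columns excluded and internal gap columns counted
// as mismatch columns.  Deterministic tie-breaking: diagonal > up > left,
// end cell scanned last-row-then-last-column.
double overlapIdentity(const std::string& a, const std::string& b, int band,
                       int* matches_out = 0, int* cols_out = 0) {
  const int n = (int)a.size(), m = (int)b.size();
  int lo, hi;
  if (band >= n + m) { lo = -n; hi = m; }
  else {
    lo = std::min(0, m - n) - band;
    hi = std::max(0, m - n) + band;
    if (lo < -n) lo = -n;
    if (hi > m) hi = m;
  }
  const int width = hi - lo + 1;
  const int NEG = -1000000000;
  std::vector<int> sc((size_t)(n + 1) * width, NEG);
  std::vector<int> mat((size_t)(n + 1) * width, 0);
  std::vector<int> col((size_t)(n + 1) * width, 0);
  // cell (i, j) lives at [i][j - i - lo]
  #define IDX(i, j) ((size_t)(i) * width + ((j) - (i) - lo))
  #define INBAND(i, j) ((j) >= 0 && (j) <= m && (j) - (i) >= lo && (j) - (i) <= hi)
  for (int j = 0; j <= m; ++j) if (INBAND(0, j)) sc[IDX(0, j)] = 0;
  for (int i = 0; i <= n; ++i) if (INBAND(i, 0)) sc[IDX(i, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    const int jstart = std::max(1, i + lo), jend = std::min(m, i + hi);
    for (int j = jstart; j <= jend; ++j) {
      int bs = NEG, bm = 0, bc = 0;
      if (INBAND(i - 1, j - 1) && sc[IDX(i - 1, j - 1)] > NEG) {
        const bool eq = a[i - 1] == b[j - 1];
        bs = sc[IDX(i - 1, j - 1)] + (eq ? 1 : -1);
        bm = mat[IDX(i - 1, j - 1)] + (eq ? 1 : 0);
        bc = col[IDX(i - 1, j - 1)] + 1;
      }
      if (INBAND(i - 1, j) && sc[IDX(i - 1, j)] > NEG) {
        const int v = sc[IDX(i - 1, j)] - 1;
        if (v > bs) { bs = v; bm = mat[IDX(i - 1, j)]; bc = col[IDX(i - 1, j)] + 1; }
      }
      if (INBAND(i, j - 1) && sc[IDX(i, j - 1)] > NEG) {
        const int v = sc[IDX(i, j - 1)] - 1;
        if (v > bs) { bs = v; bm = mat[IDX(i, j - 1)]; bc = col[IDX(i, j - 1)] + 1; }
      }
      sc[IDX(i, j)] = bs; mat[IDX(i, j)] = bm; col[IDX(i, j)] = bc;
    }
  }
  int bs = NEG, bm = 0, bc = 0;
  for (int j = 0; j <= m; ++j)
    if (INBAND(n, j) && sc[IDX(n, j)] > bs) { bs = sc[IDX(n, j)]; bm = mat[IDX(n, j)]; bc = col[IDX(n, j)]; }
  for (int i = 0; i <= n; ++i)
    if (INBAND(i, m) && sc[IDX(i, m)] > bs) { bs = sc[IDX(i, m)]; bm = mat[IDX(i, m)]; bc = col[IDX(i, m)]; }
  #undef IDX
  #undef INBAND
  if (matches_out) *matches_out = bm;
  if (cols_out) *cols_out = bc;
  return bc > 0 ? (double)bm / bc : 0.0;
}

} // namespace

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    out[i] = revcomp(as<std::string>(seqs[i]));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revstring(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    std::reverse(s.begin(), s.end());
    out[i] = s;
  }
  return out;
}

// Barcode assignment against the R1 prefix.  Barcodes are evaluated
// longest-length-first; within a length the unique barcode at minimal
// Hamming distance <= max_mismatch wins, provided the cut-site remnant
// follows it exactly.  A distance tie among equal-length barcodes is an
// ambiguous match and discards the read.  Returns 1-based index into
// `barcodes`, or 0 for no match.
// [[Rcpp::export]]
IntegerVector cpp_match_barcodes(CharacterVector r1, CharacterVector barcodes,
                                 std::string remnant, int max_mismatch) {
  const int nb = barcodes.size();
  std::vector<std::string> bc(nb);
  for (int i = 0; i < nb; ++i) bc[i] = as<std::string>(barcodes[i]);
  std::vector<int> lens;
  for (int i = 0; i < nb; ++i)
    if (std::find(lens.begin(), lens.end(), (int)bc[i].size()) == lens.end())
      lens.push_back((int)bc[i].size());
  std::sort(lens.rbegin(), lens.rend());
  const int rl = (int)remnant.size();
  const int n = r1.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(r1, i));
    const int sl = (int)LENGTH(STRING_ELT(r1, i));
    int hit = 0;
    for (size_t li = 0; li < lens.size(); ++li) {
      const int L = lens[li];
      if (sl < L + rl) continue;
      if (rl > 0 && std::strncmp(s + L, remnant.c_str(), rl) != 0) continue;
      int best = max_mismatch + 1, besti = -1;
      bool tie = false;
      for (int k = 0; k < nb; ++k) {
        if ((int)bc[k].size() != L) continue;
        const int d = hammingLeq(s, bc[k].c_str(), L, max_mismatch);
        if (d < best) { best = d; besti = k; tie = false; }
        else if (d == best && d <= max_mismatch) tie = true;
      }
      if (besti >= 0 && best <= max_mismatch) { hit = tie ? 0 : besti + 1; break; }
    }
    out[i] = hit;
  }
  return out;
}

// Quality trimming: leading, trailing, then 5'->3' sliding window; the read
// is cut at the start of the first window whose mean Phred falls below
// min_q.  Returns 1-based (start, end); (0, 0) when nothing survives.
// [[Rcpp::export]]
IntegerMatrix cpp_quality_trim(CharacterVector qual, int window, double min_q,
                               int lead_q, int trail_q) {
  const int n = qual.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(qual, i));
    const int len = (int)LENGTH(STRING_ELT(qual, i));
    int s = 0, e = len - 1;
    while (s < len && q[s] - 33 < lead_q) ++s;
    while (e >= s && q[e] - 33 < trail_q) --e;
    if (e >= s && window > 0) {
      for (int w = s; w + window - 1 <= e; ++w) {
        int sum = 0;
        for (int k = 0; k < window; ++k) sum += q[w + k] - 33;
        if ((double)sum / window < min_q) { e = w - 1; break; }
      }
    }
    if (e < s) { out(i, 0) = 0; out(i, 1) = 0; }
    else { out(i, 0) = s + 1; out(i, 1) = e + 1; }
  }
  return out;
}

// Overlap merging of mate pairs.  seq2rc/qual2rc are the R2 mate already
// reverse-complemented into R1 orientation.  The longest 3'(R1)-5'(rc R2)
// overlap of length >= min_overlap whose mismatch fraction is within
// max_mismatch_frac wins; at mismatching columns the higher-quality base is
// kept with its own quality.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2rc, CharacterVector qual2rc,
                     int min_overlap, double max_mismatch_frac) {
  const int n = seq1.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector merged(n);
  for (int i = 0; i < n; ++i) {
    const std::string s1 = as<std::string>(seq1[i]), q1 = as<std::string>(qual1[i]);
    const std::string s2 = as<std::string>(seq2rc[i]), q2 = as<std::string>(qual2rc[i]);
    const int l1 = (int)s1.size(), l2 = (int)s2.size();
    int best = -1;
    for (int o = std::min(l1, l2); o >= min_overlap; --o) {
      const int lim = (int)std::floor(max_mismatch_frac * o + 1e-9);
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < o; ++k) {
        if (s1[l1 - o + k] != s2[k] && ++mm > lim) { ok = false; break; }
      }
      if (ok) { best = o; break; }
    }
    if (best < 0) {
      merged[i] = false;
      mseq[i] = NA_STRING;
      mqual[i] = NA_STRING;
      continue;
    }
    const int o = best;
    std::string os(o, 'N'), oq(o, '!');
    for (int k = 0; k < o; ++k) {
      const char b1 = s1[l1 - o + k], c1 = q1[l1 - o + k];
      const char b2 = s2[k], c2 = q2[k];
      if (b1 == b2) { os[k] = b1; oq[k] = std::max(c1, c2); }
      else if (c2 > c1) { os[k] = b2; oq[k] = c2; }
      else { os[k] = b1; oq[k] = c1; }
    }
    mseq[i] = s1.substr(0, l1 - o) + os + s2.substr(o);
    mqual[i] = q1.substr(0, l1 - o) + oq + q2.substr(o);
    merged[i] = true;
  }
  return List::create(_["seq"] = mseq, _["qual"] = mqual, _["merged"] = merged);
}

// [[Rcpp::export]]
NumericVector cpp_identity(std::string a, std::string b) {
  int m = 0, c = 0;
  const double id = overlapIdentity(a, b, (int)(a.size() + b.size()), &m, &c);
  NumericVector out = NumericVector::create(id, (double)m, (double)c);
  out.names() = CharacterVector::create("identity", "matches", "columns");
  return out;
}

// Greedy first-fit clustering.  `seqs` must already be in processing order
// (length-descending, ties lexicographic).  A shared-8-mer count prefilter
// (lower bound derived from the identity threshold with a 1.5x gap-slack
// factor) restricts the exact banded alignment to plausible centroids;
// candidate centroids are tested in founding order.  Returns the 1-based
// centroid ordinal for every sequence.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold,
                                 int band, int kmer) {
  const int n = seqs.size();
  IntegerVector assign(n);
  std::unordered_map<uint64_t, std::vector<int> > index;
  std::vector<std::string> cent;
  std::vector<int> hitcount, stamp;
  std::vector<int> touched;
  const uint64_t mask = (kmer >= 32) ? ~0ULL : ((1ULL << (2 * kmer)) - 1);
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    const std::string q = as<std::string>(seqs[i]);
    const int ql = (int)q.size();
    ++cur;
    touched.clear();
    uint64_t code = 0;
    int run = 0;
    for (int p = 0; p < ql; ++p) {
      const int b = baseCode(q[p]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= kmer) {
        std::unordered_map<uint64_t, std::vector<int> >::iterator it = index.find(code);
        if (it != index.end()) {
          for (size_t t = 0; t < it->second.size(); ++t) {
            const int cid = it->second[t];
            if (stamp[cid] != cur) { stamp[cid] = cur; hitcount[cid] = 0; touched.push_back(cid); }
            ++hitcount[cid];
          }
        }
      }
    }
    std::sort(touched.begin(), touched.end());
    int hit = -1;
    for (size_t t = 0; t < touched.size(); ++t) {
      const int cid = touched[t];
      const int cl = (int)cent[cid].size();
      const int minL = std::min(ql, cl);
      int req = (int)std::floor((double)(minL - kmer + 1) -
                                (double)kmer * (1.0 - threshold) * minL * 1.5);
      if (req < 1) req = 1;
      if (hitcount[cid] < req) continue;
      const int b = band + std::abs(ql - cl);
      const double id = overlapIdentity(q, cent[cid], b);
      if (id + 1e-12 >= threshold) { hit = cid; break; }
    }
    if (hit < 0) {
      hit = (int)cent.size();
      cent.push_back(q);
      stamp.push_back(0);
      hitcount.push_back(0);
      std::unordered_map<uint64_t, bool> seen;
      uint64_t c2 = 0;
      int r2 = 0;
      for (int p = 0; p < ql; ++p) {
        const int bb = baseCode(q[p]);
        if (bb < 0) { r2 = 0; c2 = 0; continue; }
        c2 = ((c2 << 2) | (uint64_t)bb) & mask;
        if (++r2 >= kmer && !seen.count(c2)) { seen[c2] = true; index[c2].push_back(hit); }
      }
    }
    assign[i] = hit + 1;
  }
  return assign;
}

// Seed-and-extend read mapping against a set of reference sequences.
// Candidate (reference, diagonal, strand) loci come from exact seed_len-mer
// hits; each candidate is scored by full-length ungapped comparison with
// early exit.  Two or more distinct loci at the equal best score leave the
// read unmapped (n_best reports the multiplicity).  Alignments crossing a
// junction interval (stitched-read A-runs) are rejected outright.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector refs,
                        int seed_len, int seed_step, double max_edit_frac,
                        List junctions) {
  const int nr = refs.size();
  std::vector<std::string> R(nr);
  for (int i = 0; i < nr; ++i) R[i] = as<std::string>(refs[i]);
  std::vector<std::vector<std::pair<int, int> > > junc(nr);
  if (junctions.size() == nr) {
    for (int i = 0; i < nr; ++i) {
      if (Rf_isNull(junctions[i])) continue;
      IntegerMatrix jm = junctions[i];
      for (int k = 0; k < jm.nrow(); ++k)
        junc[i].push_back(std::make_pair(jm(k, 0), jm(k, 1)));
    }
  }
  if (seed_len < 4 || seed_len > 31) stop("seed_len must be in [4, 31]");
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
  for (int r = 0; r < nr; ++r) {
    const std::string& s = R[r];
    uint64_t code = 0;
    int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      const int b = baseCode(s[p]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= seed_len) index[code].push_back(std::make_pair(r, p - seed_len + 1));
    }
  }
  const int n = reads.size();
  IntegerVector oref(n), opos(n), oedit(n), onbest(n);
  CharacterVector ostrand(n);
  std::vector<std::pair<std::pair<int, int>, int> > cands; // ((ref, diag), strand)
  for (int i = 0; i < n; ++i) {
    oref[i] = 0; opos[i] = NA_INTEGER; oedit[i] = NA_INTEGER;
    onbest[i] = 0; ostrand[i] = NA_STRING;
    if (reads[i] == NA_STRING) continue;
    const std::string fwd = as<std::string>(reads[i]);
    const int rl = (int)fwd.size();
    if (rl < seed_len) continue;
    const std::string rev = revcomp(fwd);
    const int maxmm = (int)std::floor(max_edit_frac * rl + 1e-9);
    cands.clear();
    for (int st = 0; st < 2; ++st) {
      const std::string& q = (st == 0) ? fwd : rev;
      std::vector<int> starts;
      for (int p = 0; p + seed_len <= rl; p += seed_step) starts.push_back(p);
      if (starts.empty() || starts.back() != rl - seed_len) starts.push_back(rl - seed_len);
      for (size_t si = 0; si < starts.size(); ++si) {
        const int p = starts[si];
        uint64_t code = 0;
        bool ok = true;
        for (int k = 0; k < seed_len; ++k) {
          const int b = baseCode(q[p + k]);
          if (b < 0) { ok = false; break; }
          code = (code << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::iterator it = index.find(code);
        if (it == index.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h)
          cands.push_back(std::make_pair(
              std::make_pair(it->second[h].first, it->second[h].second - p), st));
      }
    }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
    int best = maxmm + 1, nbest = 0, bref = -1, bpos = -1, bst = 0;
    for (size_t c = 0; c < cands.size(); ++c) {
      const int r = cands[c].first.first, diag = cands[c].first.second, st = cands[c].second;
      if (diag < 0 || diag + rl > (int)R[r].size()) continue;
      bool cross = false;
      for (size_t J = 0; J < junc[r].size(); ++J)
        if (diag + 1 < junc[r][J].first && diag + rl > junc[r][J].second) { cross = true; break; }
      if (cross) continue;
      const std::string& q = (st == 0) ? fwd : rev;
      const std::string& s = R[r];
      int mm = 0;
      bool over = false;
      for (int k = 0; k < rl; ++k)
        if (q[k] != s[diag + k] && ++mm > best) { over = true; break; }
      if (over || mm > maxmm) continue;
      if (mm < best) { best = mm; nbest = 1; bref = r; bpos = diag; bst = st; }
      else ++nbest;
    }
    if (best <= maxmm) {
      onbest[i] = nbest;
      if (nbest == 1) {
        oref[i] = bref + 1;
        opos[i] = bpos + 1;
        oedit[i] = best;
        ostrand[i] = (bst == 0) ? "+" : "-";
      }
    }
  }
  return DataFrame::create(_["ref"] = oref, _["pos"] = opos, _["strand"] = ostrand,
                           _["edits"] = oedit, _["n_best"] = onbest,
                           _["stringsAsFactors"] = false);
}

namespace {

// Expand one alignment record into per-reference-position (base, qual),
// marking indel evidence as it goes.  Returns the 0-based reference index.
int walkCigar(int rec, const IntegerVector& refidx, const IntegerVector& pos,
              const CharacterVector& seq, const CharacterVector& qual,
              const CharacterVector& cigar,
              std::vector<std::vector<char> >& indel,
              std::map<std::pair<int, int>, std::pair<char, char> >& out) {
  const int r = refidx[rec] - 1;
  int rp = pos[rec] - 1;
  const char* s = CHAR(STRING_ELT(seq, rec));
  const char* q = CHAR(STRING_ELT(qual, rec));
  const std::string cg = as<std::string>(cigar[rec]);
  const int rlen = (int)indel[r].size();
  int qi = 0;
  size_t ci = 0;
  while (ci < cg.size()) {
    long num = 0;
    while (ci < cg.size() && std::isdigit((unsigned char)cg[ci]))
      num = num * 10 + (cg[ci++] - '0');
    if (ci >= cg.size() || num <= 0) stop("malformed CIGAR string");
    const char op = cg[ci++];
    if (op == 'M' || op == '=' || op == 'X') {
      for (long k = 0; k < num; ++k) {
        if (rp >= 0 && rp < rlen)
          out[std::make_pair(r, rp)] = std::make_pair(s[qi], q[qi]);
        ++rp; ++qi;
      }
    } else if (op == 'I') {
      if (rp - 1 >= 0 && rp - 1 < rlen) indel[r][rp - 1] = 1;
      if (rp >= 0 && rp < rlen) indel[r][rp] = 1;
      qi += (int)num;
    } else if (op == 'D' || op == 'N') {
      for (long k = 0; k < num; ++k) {
        if (rp >= 0 && rp < rlen) indel[r][rp] = 1;
        ++rp;
      }
    } else if (op == 'S') {
      qi += (int)num;
    } else if (op == 'H') {
      // no-op
    } else {
      stop("unsupported CIGAR operation");
    }
  }
  return r;
}

} // namespace

// Per-position A/C/G/T depth accumulation over alignment records.  Records
// sharing a pairid are mates of one template: bases in the mate-overlap
// region are counted once, the higher-quality base winning (ties keep the
// first mate).  Records must be sorted by pairid.
// [[Rcpp::export]]
DataFrame cpp_pileup(IntegerVector refidx, IntegerVector pos, CharacterVector seq,
                     CharacterVector qual, CharacterVector cigar,
                     IntegerVector pairid, IntegerVector reflen, int min_base_q) {
  const int nr = reflen.size();
  std::vector<std::vector<std::array<int, 4> > > cnt(nr);
  std::vector<std::vector<char> > indel(nr);
  for (int r = 0; r < nr; ++r) {
    std::array<int, 4> z = {{0, 0, 0, 0}};
    cnt[r].assign(reflen[r], z);
    indel[r].assign(reflen[r], 0);
  }
  const int n = refidx.size();
  int i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && pairid[j] == pairid[i]) ++j;
    std::map<std::pair<int, int>, std::pair<char, char> > acc;
    walkCigar(i, refidx, pos, seq, qual, cigar, indel, acc);
    for (int k = i + 1; k < j; ++k) {
      std::map<std::pair<int, int>, std::pair<char, char> > m2;
      walkCigar(k, refidx, pos, seq, qual, cigar, indel, m2);
      for (std::map<std::pair<int, int>, std::pair<char, char> >::iterator it = m2.begin();
           it != m2.end(); ++it) {
        std::map<std::pair<int, int>, std::pair<char, char> >::iterator prev = acc.find(it->first);
        if (prev == acc.end()) acc[it->first] = it->second;
        else if (it->second.second > prev->second.second) prev->second = it->second;
      }
    }
    for (std::map<std::pair<int, int>, std::pair<char, char> >::iterator it = acc.begin();
         it != acc.end(); ++it) {
      const int b = baseCode((char)std::toupper((unsigned char)it->second.first));
      if (b >= 0 && it->second.second - 33 >= min_base_q)
        ++cnt[it->first.first][it->first.second][b];
    }
    i = j;
  }
  std::vector<int> vr, vp, va, vc, vg, vt;
  std::vector<int> vi;
  for (int r = 0; r < nr; ++r) {
    for (int p = 0; p < reflen[r]; ++p) {
      const std::array<int, 4>& d = cnt[r][p];
      const int tot = d[0] + d[1] + d[2] + d[3];
      if (tot > 0 || indel[r][p]) {
        vr.push_back(r + 1); vp.push_back(p + 1);
        va.push_back(d[0]); vc.push_back(d[1]); vg.push_back(d[2]); vt.push_back(d[3]);
        vi.push_back(indel[r][p] ? 1 : 0);
      }
    }
  }
  return DataFrame::create(_["ref"] = vr, _["pos"] = vp, _["A"] = va, _["C"] = vc,
                           _["G"] = vg, _["T"] = vt, _["indel"] = vi);
}

// In-line 3' signature truncation.  Returns the kept read length for each
// sequence: leftmost full occurrence of `sig` within `max_mm` mismatches
// wins; otherwise the longest read suffix equal to a signature prefix
// (exact below `approx_min_len` bases, one mismatch allowed at or above
// it); -1 when nothing matches.
// [[Rcpp::export]]
IntegerVector cpp_trim_signature(CharacterVector seqs, std::string sig,
                                 int max_mm, int approx_min_len) {
  const int L = (int)sig.size();
  const int n = seqs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    const int sl = (int)LENGTH(STRING_ELT(seqs, i));
    int cut = -1;
    for (int p = 0; p + L <= sl; ++p) {
      if (hammingLeq(s + p, sig.c_str(), L, max_mm) <= max_mm) { cut = p; break; }
    }
    if (cut < 0) {
      const int top = std::min(L - 1, sl);
      for (int k = top; k >= 1; --k) {
        const int allow = (k >= approx_min_len) ? max_mm : 0;
        if (hammingLeq(s + sl - k, sig.c_str(), k, allow) <= allow) {
          cut = sl - k;
          break;
        }
      }
    }
    out[i] = cut;
  }
  return out;
}

// Hamming distance of each sequence's prefix against `pat` (prefix shorter
// than the pattern counts missing bases as mismatches).
// [[Rcpp::export]]
IntegerVector cpp_prefix_mismatches(CharacterVector seqs, std::string pat) {
  const int L = (int)pat.size();
  const int n = seqs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    const int sl = (int)LENGTH(STRING_ELT(seqs, i));
    int d = 0;
    for (int k = 0; k < L; ++k) {
      if (k >= sl || s[k] != pat[k]) ++d;
    }
    out[i] = d;
  }
  return out;
}

// Parse one samtools-mpileup read-bases string.  Returns c(A, C, G, T,
// indel_evidence, depth_units) where depth_units counts the base-level
// symbols ('.', ',', letters, '*', '<', '>') for cross-checking against the
// depth column.
// [[Rcpp::export]]
IntegerVector cpp_parse_mpileup_bases(std::string ref_base, std::string bases) {
  int d[4] = {0, 0, 0, 0};
  int indel = 0, units = 0;
  const char rb = ref_base.empty() ? 'N' : (char)std::toupper((unsigned char)ref_base[0]);
  size_t i = 0;
  while (i < bases.size()) {
    const char c = bases[i];
    if (c == '^') {
      if (i + 1 >= bases.size()) stop("dangling '^' without mapping-quality character");
      i += 2;
    } else if (c == '$') {
      ++i;
    } else if (c == '+' || c == '-') {
      ++i;
      size_t j = i;
      long num = 0;
      while (j < bases.size() && std::isdigit((unsigned char)bases[j])) {
        num = num * 10 + (bases[j] - '0');
        ++j;
      }
      if (j == i) stop("indel marker without a length");
      if (j + (size_t)num > bases.size()) stop("dangling indel sequence");
      i = j + (size_t)num;
      indel = 1;
    } else if (c == '*') {
      indel = 1; ++units; ++i;
    } else if (c == '.' || c == ',') {
      const int b = baseCode(rb);
      if (b >= 0) ++d[b];
      ++units; ++i;
    } else if (c == '>' || c == '<') {
      ++units; ++i;
    } else {
      const int b = baseCode((char)std::toupper((unsigned char)c));
      if (b >= 0) { ++d[b]; ++units; ++i; }
      else if (std::toupper((unsigned char)c) == 'N') { ++units; ++i; }
      else stop(std::string("unexpected character '") + c + "' in read-bases string");
    }
  }
  return IntegerVector::create(d[0], d[1], d[2], d[3], indel, units);
}

// Uniform per-base substitution errors drawn from R's RNG (deterministic
// under set.seed); an erroneous base becomes one of the three others with
// equal probability.
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double rate) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      if (unif_rand() < rate) {
        const int b = baseCode(s[p]);
        if (b < 0) continue;
        int nb = (int)(unif_rand() * 3.0);
        if (nb > 2) nb = 2;
        s[p] = codeBase((b + 1 + nb) % 4);
      }
    }
    out[i] = s;
  }
  return out;
}
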