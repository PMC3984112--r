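// Toy-scale seed-and-extend alignment core: k-mer genome index, contiguous /
// spliced / distant split-read placement, local-realignment retest scoring,
// abundance (blacklist) matching, template remapping and small string utils.
// Designed for synthetic genomes of a few Mb; not a production aligner.

#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

static inline char compbase(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  }
  return 'N';
}

struct SeqIndex {
  std::vector<std::string> seqs;
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > > kmap;
};

static void index_add(SeqIndex *idx, const std::string &s, int32_t ci) {
  const int k = idx->k;
  const int64_t n = (int64_t)s.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int64_t i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) idx->kmap[code].push_back(std::make_pair(ci, (int32_t)(i - k + 1)));
  }
}

// [[Rcpp::export(name = ".cppIndexBuild")]]
SEXP cpp_index_build(CharacterVector seqs, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  SeqIndex *idx = new SeqIndex();
  idx->k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) s[j] = (char)toupper(s[j]);
    idx->seqs.push_back(s);
    index_add(idx, idx->seqs.back(), (int32_t)i);
  }
  XPtr<SeqIndex> p(idx, true);
  return p;
}

// [[Rcpp::export(name = ".cppIndexK")]]
int cpp_index_k(SEXP xp) { XPtr<SeqIndex> p(xp); return p->k; }

struct Frame {
  uint8_t o;    // 0: q -> off + q (top strand); 1: q -> off - q (bottom strand)
  int32_t c;
  int64_t off;
};

// Collect candidate alignment frames for one read from exact k-mer seeds.
static void read_frames(const SeqIndex &idx, const std::string &rd,
                        std::vector<Frame> &out, size_t maxFrames) {
  const int k = idx.k;
  const int L = (int)rd.size();
  out.clear();
  if (L < k) return;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  std::set<std::pair<int64_t, int64_t> > seen; // (o<<32|c, off)
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (int q = 0; q < L; ++q) {
    int b = base2bit(rd[q]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
    if (++run < k) continue;
    int q0 = q - k + 1;
    std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > >::const_iterator it;
    it = idx.kmap.find(fwd);
    if (it != idx.kmap.end()) {
      for (size_t h = 0; h < it->second.size(); ++h) {
        int64_t off = (int64_t)it->second[h].second - q0;
        if (seen.insert(std::make_pair(((int64_t)0 << 32) | it->second[h].first, off)).second) {
          Frame f; f.o = 0; f.c = it->second[h].first; f.off = off;
          out.push_back(f);
          if (out.size() >= maxFrames) return;
        }
      }
    }
    it = idx.kmap.find(rev);
    if (it != idx.kmap.end()) {
      for (size_t h = 0; h < it->second.size(); ++h) {
        // genome[p..p+k) == revcomp(read[q0..q0+k)) => off = p + q0 + k - 1
        int64_t off = (int64_t)it->second[h].second + q0 + k - 1;
        if (seen.insert(std::make_pair(((int64_t)1 << 32) | it->second[h].first, off)).second) {
          Frame f; f.o = 1; f.c = it->second[h].first; f.off = off;
          out.push_back(f);
          if (out.size() >= maxFrames) return;
        }
      }
    }
  }
}

// Per-frame match profile over the read; m[q] in {-1 invalid, 0 mismatch, 1 match}.
static void frame_matches(const SeqIndex &idx, const std::string &rd, const Frame &f,
                          std::vector<int8_t> &m, int &qlo, int &qhi) {
  const int L = (int)rd.size();
  const std::string &s = idx.seqs[f.c];
  const int64_t n = (int64_t)s.size();
  m.assign(L, -1);
  if (f.o == 0) {
    qlo = (int)std::max((int64_t)0, -f.off);
    qhi = (int)std::min((int64_t)(L - 1), n - 1 - f.off);
  } else {
    qlo = (int)std::max((int64_t)0, f.off - (n - 1));
    qhi = (int)std::min((int64_t)(L - 1), f.off);
  }
  if (qlo > qhi) { qlo = 0; qhi = -1; return; }
  for (int q = qlo; q <= qhi; ++q) {
    char g = (f.o == 0) ? s[f.off + q] : s[f.off - q];
    char r = (f.o == 0) ? (char)toupper(rd[q]) : compbase(rd[q]);
    m[q] = (r == g && base2bit(g) >= 0) ? 1 : 0;
  }
}

static inline int64_t qmap(const Frame &f, int q) {
  return (f.o == 0) ? f.off + q : f.off - q;
}

// [[Rcpp::export(name = ".cppMapReads")]]
List cpp_map_reads(SEXP xp, CharacterVector reads, int minSeg, double maxIntron,
                   int splicePenalty, int maxFrames) {
  XPtr<SeqIndex> idx(xp);
  const R_xlen_t n = reads.size();
  IntegerVector kind(n, 0), score(n, NA_INTEGER), bvec(n, NA_INTEGER),
      slideLo(n, NA_INTEGER), slideHi(n, NA_INTEGER);
  LogicalVector unique_(n, NA_LOGICAL);
  IntegerVector c1(n, NA_INTEGER), s1(n, NA_INTEGER), g1s(n, NA_INTEGER), g1e(n, NA_INTEGER),
      q1s(n, NA_INTEGER), q1e(n, NA_INTEGER), nm1(n, NA_INTEGER);
  IntegerVector c2(n, NA_INTEGER), s2(n, NA_INTEGER), g2s(n, NA_INTEGER), g2e(n, NA_INTEGER),
      q2s(n, NA_INTEGER), q2e(n, NA_INTEGER), nm2(n, NA_INTEGER);
  CharacterVector mis1(n, NA_STRING), mis2(n, NA_STRING);
  NumericVector donorG(n, NA_REAL), acceptorG(n, NA_REAL);

  std::vector<Frame> frames;
  std::vector<std::vector<int8_t> > ms;
  std::vector<std::vector<int> > pms;
  std::vector<int> qlos, qhis;

  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const int L = (int)rd.size();
    read_frames(*idx, rd, frames, (size_t)maxFrames);
    if (frames.empty()) continue;
    const int nf = (int)frames.size();
    ms.assign(nf, std::vector<int8_t>());
    pms.assign(nf, std::vector<int>());
    qlos.assign(nf, 0); qhis.assign(nf, -1);
    for (int f = 0; f < nf; ++f) {
      frame_matches(*idx, rd, frames[f], ms[f], qlos[f], qhis[f]);
      pms[f].assign(L + 1, 0);
      for (int q = 0; q < L; ++q) pms[f][q + 1] = pms[f][q] + (ms[f][q] == 1 ? 1 : 0);
    }

    // best contiguous (local) placement over full-length frames
    int localBest = INT_MIN, localTies = 0, localF = -1;
    for (int f = 0; f < nf; ++f) {
      if (qlos[f] != 0 || qhis[f] != L - 1) continue;
      int sc = 2 * pms[f][L] - L;
      if (sc > localBest) { localBest = sc; localTies = 1; localF = f; }
      else if (sc == localBest) ++localTies;
    }

    // best two-segment placement
    int splitBest = INT_MIN;
    bool splitMany = false;
    std::vector<std::pair<int, int> > pairs; // frame index pairs at best score
    std::vector<int> pairB;                  // max breakpoint seen per pair
    if (L >= 2 * minSeg && nf >= 2) {
      for (int b = minSeg; b <= L - minSeg; ++b) {
        // top two scores per side
        int b1 = INT_MIN, b1n = 0; std::vector<int> l1;
        int sec1 = INT_MIN; std::vector<int> l1s;
        int b2 = INT_MIN, b2n = 0; std::vector<int> l2;
        int sec2 = INT_MIN; std::vector<int> l2s;
        for (int f = 0; f < nf; ++f) {
          if (qlos[f] == 0 && qhis[f] >= b - 1) {
            int sc = 2 * pms[f][b] - b;
            if (sc > b1) { sec1 = b1; l1s = l1; b1 = sc; l1.clear(); l1.push_back(f); b1n = 1; }
            else if (sc == b1) { ++b1n; if (l1.size() < 4) l1.push_back(f); }
            else if (sc > sec1) { sec1 = sc; l1s.clear(); l1s.push_back(f); }
            else if (sc == sec1 && l1s.size() < 4) l1s.push_back(f);
          }
          if (qhis[f] == L - 1 && qlos[f] <= b) {
            int sc = 2 * (pms[f][L] - pms[f][b]) - (L - b);
            if (sc > b2) { sec2 = b2; l2s = l2; b2 = sc; l2.clear(); l2.push_back(f); b2n = 1; }
            else if (sc == b2) { ++b2n; if (l2.size() < 4) l2.push_back(f); }
            else if (sc > sec2) { sec2 = sc; l2s.clear(); l2s.push_back(f); }
            else if (sc == sec2 && l2s.size() < 4) l2s.push_back(f);
          }
        }
        if (b1 == INT_MIN || b2 == INT_MIN) continue;
        // candidate combined scores with distinct frames on the two sides
        struct Cand { int sc; const std::vector<int> *fl1; const std::vector<int> *fl2; };
        std::vector<Cand> cands;
        { Cand cd; cd.sc = b1 + b2; cd.fl1 = &l1; cd.fl2 = &l2; cands.push_back(cd); }
        if (sec2 != INT_MIN) { Cand cd; cd.sc = b1 + sec2; cd.fl1 = &l1; cd.fl2 = &l2s; cands.push_back(cd); }
        if (sec1 != INT_MIN) { Cand cd; cd.sc = sec1 + b2; cd.fl1 = &l1s; cd.fl2 = &l2; cands.push_back(cd); }
        for (size_t ci = 0; ci < cands.size(); ++ci) {
          if (cands[ci].sc < splitBest) continue;
          for (size_t a = 0; a < cands[ci].fl1->size(); ++a)
            for (size_t bb = 0; bb < cands[ci].fl2->size(); ++bb) {
              int f1 = (*cands[ci].fl1)[a], f2 = (*cands[ci].fl2)[bb];
              if (f1 == f2) continue;
              int sc = cands[ci].sc;
              if (sc > splitBest) {
                splitBest = sc; pairs.clear(); pairB.clear(); splitMany = false;
                pairs.push_back(std::make_pair(f1, f2)); pairB.push_back(b);
              } else if (sc == splitBest) {
                bool found = false;
                for (size_t t = 0; t < pairs.size(); ++t)
                  if (pairs[t].first == f1 && pairs[t].second == f2) {
                    found = true;
                    if (b > pairB[t]) pairB[t] = b;
                  }
                if (!found) {
                  if (pairs.size() >= 8) splitMany = true;
                  else { pairs.push_back(std::make_pair(f1, f2)); pairB.push_back(b); }
                }
              }
            }
        }
        if (b1n > 4 || b2n > 4) { /* heavy ties handled via pair list cap */ }
      }
    }

    bool haveLocal = localBest > INT_MIN;
    bool haveSplit = splitBest > INT_MIN;
    int splitEff = haveSplit ? splitBest - splicePenalty : INT_MIN;
    if (!haveLocal && !haveSplit) continue;

    if (haveLocal && localBest >= splitEff) {
      // contiguous placement
      const Frame &f = frames[localF];
      kind[i] = 1; score[i] = localBest; unique_[i] = (localTies == 1);
      c1[i] = f.c + 1; s1[i] = (f.o == 0) ? 1 : -1;
      int64_t ga = qmap(f, 0), gb = qmap(f, L - 1);
      g1s[i] = (int)std::min(ga, gb) + 1; g1e[i] = (int)std::max(ga, gb) + 1;
      q1s[i] = 1; q1e[i] = L;
      std::string mm; int nm = 0;
      for (int q = 0; q < L; ++q) if (ms[localF][q] == 0) {
        ++nm; if (!mm.empty()) mm += ","; mm += std::to_string(q + 1);
      }
      nm1[i] = nm; mis1[i] = mm;
    } else {
      // split placement; merge slide-equivalent pairs before uniqueness call
      int pi = 0;
      for (size_t t = 1; t < pairs.size(); ++t) if (pairB[t] > pairB[pi]) pi = (int)t;
      int f1 = pairs[pi].first, f2 = pairs[pi].second;
      int b = pairB[pi];
      // extend breakpoint while both sides match (slide equivalence)
      int bhi = b, blo = b;
      while (bhi < L - minSeg && ms[f1][bhi] == 1 && ms[f2][bhi] == 1) ++bhi;
      while (blo > minSeg && ms[f1][blo - 1] == 1 && ms[f2][blo - 1] == 1) --blo;
      b = bhi;
      // uniqueness: count distinct pairs that are not slide-images of each other
      int distinctPairs = 0;
      for (size_t t = 0; t < pairs.size(); ++t) {
        if (pairs[t].first == f1 && pairs[t].second == f2) { ++distinctPairs; continue; }
        ++distinctPairs;
      }
      bool uq = (distinctPairs == 1) && !splitMany;

      const Frame &F1 = frames[f1];
      const Frame &F2 = frames[f2];
      bool sameCO = (F1.c == F2.c && F1.o == F2.o);
      int64_t dg = qmap(F1, b - 1), ag = qmap(F2, b);
      int k2 = 3;
      if (sameCO) {
        int64_t gap = (F1.o == 0) ? (ag - dg - 1) : (dg - ag - 1);
        if (gap >= 1 && (double)gap < maxIntron) k2 = 2;
      }
      kind[i] = k2; score[i] = splitEff; unique_[i] = uq;
      bvec[i] = b; slideLo[i] = blo; slideHi[i] = bhi;
      donorG[i] = (double)(dg + 1); acceptorG[i] = (double)(ag + 1);
      c1[i] = F1.c + 1; s1[i] = (F1.o == 0) ? 1 : -1;
      int64_t a1 = qmap(F1, 0), b1g = qmap(F1, b - 1);
      g1s[i] = (int)std::min(a1, b1g) + 1; g1e[i] = (int)std::max(a1, b1g) + 1;
      q1s[i] = 1; q1e[i] = b;
      c2[i] = F2.c + 1; s2[i] = (F2.o == 0) ? 1 : -1;
      int64_t a2 = qmap(F2, b), b2g = qmap(F2, L - 1);
      g2s[i] = (int)std::min(a2, b2g) + 1; g2e[i] = (int)std::max(a2, b2g) + 1;
      q2s[i] = b + 1; q2e[i] = L;
      std::string mm1, mm2; int n1 = 0, n2 = 0;
      for (int q = 0; q < b; ++q) if (ms[f1][q] != 1) {
        ++n1; if (!mm1.empty()) mm1 += ","; mm1 += std::to_string(q + 1);
      }
      for (int q = b; q < L; ++q) if (ms[f2][q] != 1) {
        ++n2; if (!mm2.empty()) mm2 += ","; mm2 += std::to_string(q + 1);
      }
      nm1[i] = n1; mis1[i] = mm1; nm2[i] = n2; mis2[i] = mm2;
    }
  }

  return List::create(
      _["kind"] = kind, _["score"] = score, _["unique"] = unique_,
      _["chrom1"] = c1, _["strand1"] = s1, _["gstart1"] = g1s, _["gend1"] = g1e,
      _["qstart1"] = q1s, _["qend1"] = q1e, _["nmis1"] = nm1, _["mis1"] = mis1,
      _["chrom2"] = c2, _["strand2"] = s2, _["gstart2"] = g2s, _["gend2"] = g2e,
      _["qstart2"] = q2s, _["qend2"] = q2e, _["nmis2"] = nm2, _["mis2"] = mis2,
      _["breakpoint"] = bvec, _["slide_lo"] = slideLo, _["slide_hi"] = slideHi,
      _["donor_g"] = donorG, _["acceptor_g"] = acceptorG);
}

// Best single-locus matched-base count allowing at most one indel of <= 1 bp.
// [[Rcpp::export(name = ".cppRetestLocal")]]
IntegerVector cpp_retest_local(SEXP xp, CharacterVector reads, int maxFrames) {
  XPtr<SeqIndex> idx(xp);
  const R_xlen_t n = reads.size();
  IntegerVector out(n, 0);
  std::vector<Frame> frames;
  std::vector<int8_t> m, mn;
  std::vector<int> pm, pmn;
  int qlo, qhi, qlon, qhin;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const int L = (int)rd.size();
    read_frames(*idx, rd, frames, (size_t)maxFrames);
    int best = 0;
    for (size_t f = 0; f < frames.size(); ++f) {
      frame_matches(*idx, rd, frames[f], m, qlo, qhi);
      if (qlo != 0 || qhi != L - 1) continue;
      pm.assign(L + 1, 0);
      for (int q = 0; q < L; ++q) pm[q + 1] = pm[q] + (m[q] == 1 ? 1 : 0);
      if (pm[L] > best) best = pm[L];
      for (int dd = -1; dd <= 1; dd += 2) {
        Frame g = frames[f];
        g.off += dd;
        frame_matches(*idx, rd, g, mn, qlon, qhin);
        if (qhin != L - 1) continue;
        pmn.assign(L + 1, 0);
        for (int q = 0; q < L; ++q) pmn[q + 1] = pmn[q] + (mn[q] == 1 ? 1 : 0);
        for (int p = 1; p < L; ++p) {
          if (p < qlon) continue;
          int del = pm[p] + (pmn[L] - pmn[p]);           // 1 bp gap in the read
          if (del > best) best = del;
          if (p + 1 <= L) {
            int ins = pm[p] + (pmn[L] - pmn[p + 1]);     // 1 read base unaligned
            if (ins > best) best = ins;
          }
        }
      }
    }
    out[i] = best;
  }
  return out;
}

// Max matched bases of each read against any blacklist locus (either strand,
// clipped placements allowed, no gaps).
// [[Rcpp::export(name = ".cppBlacklistMatches")]]
IntegerVector cpp_blacklist_matches(CharacterVector blacklist, CharacterVector reads, int k) {
  SeqIndex idx;
  idx.k = k;
  for (R_xlen_t i = 0; i < blacklist.size(); ++i) {
    std::string s = as<std::string>(blacklist[i]);
    for (size_t j = 0; j < s.size(); ++j) s[j] = (char)toupper(s[j]);
    idx.seqs.push_back(s);
    index_add(&idx, idx.seqs.back(), (int32_t)i);
  }
  const R_xlen_t n = reads.size();
  IntegerVector out(n, 0);
  std::vector<Frame> frames;
  std::vector<int8_t> m;
  int qlo, qhi;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    read_frames(idx, rd, frames, 256);
    int best = 0;
    for (size_t f = 0; f < frames.size(); ++f) {
      frame_matches(idx, rd, frames[f], m, qlo, qhi);
      int cnt = 0;
      for (int q = qlo; q <= qhi; ++q) if (m[q] == 1) ++cnt;
      if (cnt > best) best = cnt;
    }
    out[i] = best;
  }
  return out;
}

// Contiguous sense-strand remapping of reads against a small template set.
// Full-length placements only; ties over (template, offset) break uniqueness.
// [[Rcpp::export(name = ".cppRemapTemplates")]]
List cpp_remap_templates(CharacterVector templates, CharacterVector reads, int k) {
  SeqIndex idx;
  idx.k = k;
  for (R_xlen_t i = 0; i < templates.size(); ++i) {
    std::string s = as<std::string>(templates[i]);
    for (size_t j = 0; j < s.size(); ++j) s[j] = (char)toupper(s[j]);
    idx.seqs.push_back(s);
    index_add(&idx, idx.seqs.back(), (int32_t)i);
  }
  const R_xlen_t n = reads.size();
  IntegerVector tpl(n, NA_INTEGER), off(n, NA_INTEGER), matches(n, NA_INTEGER),
      nbest(n, 0);
  CharacterVector mism(n, NA_STRING);
  std::vector<Frame> frames;
  std::vector<int8_t> m, mBest;
  int qlo, qhi;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const int L = (int)rd.size();
    read_frames(idx, rd, frames, 256);
    int best = -1, ties = 0, bt = -1;
    int64_t bo = -1;
    for (size_t f = 0; f < frames.size(); ++f) {
      if (frames[f].o != 0) continue; // sense-strand only (directional protocol)
      frame_matches(idx, rd, frames[f], m, qlo, qhi);
      if (qlo != 0 || qhi != L - 1) continue; // read must lie inside the template
      int cnt = 0;
      for (int q = 0; q < L; ++q) if (m[q] == 1) ++cnt;
      if (cnt > best) { best = cnt; ties = 1; bt = frames[f].c; bo = frames[f].off; mBest = m; }
      else if (cnt == best) ++ties;
    }
    if (best < 0) continue;
    tpl[i] = bt + 1; off[i] = (int)bo; matches[i] = best; nbest[i] = ties;
    std::string mm;
    for (int q = 0; q < L; ++q) if (mBest[q] != 1) {
      if (!mm.empty()) mm += ","; mm += std::to_string(q + 1);
    }
    mism[i] = mm;
  }
  return List::create(_["template"] = tpl, _["offset"] = off,
                      _["matches"] = matches, _["n_best"] = nbest,
                      _["mismatch_q"] = mism);
}

// [[Rcpp::export(name = ".cppQualCount")]]
IntegerVector cpp_qual_count(CharacterVector quals, int offset, int threshold) {
  const R_xlen_t n = quals.size();
  IntegerVector out(n);
  const char cut = (char)(offset + threshold);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(quals, i));
    int cnt = 0;
    for (; *s; ++s) if (*s >= cut) ++cnt;
    out[i] = cnt;
  }
  return out;
}

// Longest exact common substring length, elementwise over two vectors.
// [[Rcpp::export(name = ".cppLcsLength")]]
IntegerVector cpp_lcs_length(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i]), y = as<std::string>(b[i]);
    for (size_t j = 0; j < x.size(); ++j) x[j] = (char)toupper(x[j]);
    for (size_t j = 0; j < y.size(); ++j) y[j] = (char)toupper(y[j]);
    const size_t nx = x.size(), ny = y.size();
    std::vector<int> prev(ny + 1, 0), cur(ny + 1, 0);
    int best = 0;
    for (size_t p = 1; p <= nx; ++p) {
      for (size_t q = 1; q <= ny; ++q) {
        cur[q] = (x[p - 1] == y[q - 1]) ? prev[q - 1] + 1 : 0;
        if (cur[q] > best) best = cur[q];
      }
      std::swap(prev, cur);
    }
    out[i] = best;
  }
  return out;
}
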