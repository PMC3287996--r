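#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// DNA encoding: A=0 C=1 G=2 T=3, anything else (N) = 4.
// N is a universal mismatch: it never scores as a match, and never seeds.

static const int NEG = -1000000000;

static std::vector<int> encode_dna(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
    case 'A': v[i] = 0; break;
    case 'C': v[i] = 1; break;
    case 'G': v[i] = 2; break;
    case 'T': v[i] = 3; break;
    default:  v[i] = 4; break;
    }
  }
  return v;
}

static inline char decode_dna(int v) { return "ACGTN"[v]; }

static inline int subst(int a, int b, int match, int mismatch) {
  return (a == b && a < 4) ? match : mismatch;
}

// ---------------------------------------------------------------------------
// Banded affine-gap extension DP.
//
// Extends an alignment rightwards from an implicit anchor at (0,0): the path
// must start at cell (0,0) in state M with score 0 and may end at any cell in
// state M (a locally optimal extension never ends in a gap).  Gap of length L
// costs gap_open + gap_ext * L.  The band is centred on the main diagonal;
// rows whose running maximum falls more than `xdrop` below the best score
// seen so far terminate the extension (X-drop).
// ---------------------------------------------------------------------------
struct ExtResult {
  int score;        // best extension score (0 = empty extension)
  int a_used;       // residues of a consumed
  int b_used;       // residues of b consumed
  std::string a_aln, b_aln;
};

static ExtResult extend_affine(const std::vector<int>& a, const std::vector<int>& b,
                               int match, int mismatch, int gap_open, int gap_ext,
                               int band, int xdrop) {
  ExtResult res; res.score = 0; res.a_used = 0; res.b_used = 0;
  const int Ka = (int)a.size(), Kb = (int)b.size();
  if (Ka == 0 && Kb == 0) return res;
  const int w = 2 * band + 1;
  // column index of cell (k, l) within row k
  auto colof = [band](int k, int l) { return l - k + band; };

  std::vector<int> Mprev(w, NEG), Xprev(w, NEG), Yprev(w, NEG);
  std::vector<int> Mcur(w, NEG), Xcur(w, NEG), Ycur(w, NEG);
  // traceback: tb[state][row*w + col]; states 0=M,1=X(consume a),2=Y(consume b)
  // codes: 0 unset, 1 from M, 2 from X, 3 from Y
  int maxrows = Ka + 1;
  std::vector<char> tbM((size_t)maxrows * w, 0), tbX((size_t)maxrows * w, 0),
                    tbY((size_t)maxrows * w, 0);

  int best = 0, bk = 0, bl = 0;
  int lastrow = 0;

  for (int k = 0; k <= Ka; ++k) {
    int lo = std::max(0, k - band), hi = std::min(Kb, k + band);
    if (lo > hi) break;
    std::fill(Mcur.begin(), Mcur.end(), NEG);
    std::fill(Xcur.begin(), Xcur.end(), NEG);
    std::fill(Ycur.begin(), Ycur.end(), NEG);
    int rowmax = NEG;
    for (int l = lo; l <= hi; ++l) {
      int c = colof(k, l);
      if (k == 0 && l == 0) { Mcur[c] = 0; rowmax = 0; continue; }
      // M: diagonal move from (k-1, l-1)
      if (k >= 1 && l >= 1) {
        int cp = colof(k - 1, l - 1);
        if (cp >= 0 && cp < w) {
          int pm = Mprev[cp], px = Xprev[cp], py = Yprev[cp];
          int from = pm; char code = 1;               // tie-break: match first,
          if (px > from) { from = px; code = 2; }     // then delete, then insert
          if (py > from) { from = py; code = 3; }
          if (from > NEG / 2) {
            Mcur[c] = from + subst(a[k - 1], b[l - 1], match, mismatch);
            tbM[(size_t)k * w + c] = code;
          }
        }
      }
      // X: gap in b, consume a[k-1]; from (k-1, l)
      if (k >= 1) {
        int cp = colof(k - 1, l);
        if (cp >= 0 && cp < w) {
          int om = (Mprev[cp] > NEG / 2) ? Mprev[cp] - gap_open - gap_ext : NEG;
          int ox = (Xprev[cp] > NEG / 2) ? Xprev[cp] - gap_ext : NEG;
          if (om >= ox && om > NEG / 2) { Xcur[c] = om; tbX[(size_t)k * w + c] = 1; }
          else if (ox > NEG / 2)        { Xcur[c] = ox; tbX[(size_t)k * w + c] = 2; }
        }
      }
      // Y: gap in a, consume b[l-1]; from (k, l-1) in current row
      if (l >= 1) {
        int cp = colof(k, l - 1);
        if (cp >= 0 && cp < w) {
          int om = (Mcur[cp] > NEG / 2) ? Mcur[cp] - gap_open - gap_ext : NEG;
          int oy = (Ycur[cp] > NEG / 2) ? Ycur[cp] - gap_ext : NEG;
          if (om >= oy && om > NEG / 2) { Ycur[c] = om; tbY[(size_t)k * w + c] = 1; }
          else if (oy > NEG / 2)        { Ycur[c] = oy; tbY[(size_t)k * w + c] = 3; }
        }
      }
      int cellmax = std::max(Mcur[c], std::max(Xcur[c], Ycur[c]));
      if (cellmax > rowmax) rowmax = cellmax;
      if (Mcur[c] > best) { best = Mcur[c]; bk = k; bl = l; }
    }
    lastrow = k;
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    if (rowmax < best - xdrop) break;
  }
  (void)lastrow;

  if (best <= 0) return res;
  // traceback from (bk, bl), state M
  std::string aa, bb;
  int k = bk, l = bl; int state = 0;
  while (!(k == 0 && l == 0)) {
    int c = colof(k, l);
    if (state == 0) {
      char code = tbM[(size_t)k * w + c];
      aa.push_back(decode_dna(a[k - 1]));
      bb.push_back(decode_dna(b[l - 1]));
      --k; --l;
      state = (code == 1) ? 0 : (code == 2 ? 1 : 2);
    } else if (state == 1) {
      char code = tbX[(size_t)k * w + c];
      aa.push_back(decode_dna(a[k - 1]));
      bb.push_back('-');
      --k;
      state = (code == 1) ? 0 : 1;
    } else {
      char code = tbY[(size_t)k * w + c];
      aa.push_back('-');
      bb.push_back(decode_dna(b[l - 1]));
      --l;
      state = (code == 1) ? 0 : 2;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  res.score = best; res.a_used = bk; res.b_used = bl;
  res.a_aln = aa; res.b_aln = bb;
  return res;
}

// ---------------------------------------------------------------------------
// Seed-and-extend gapped local alignment (one query/subject pair, same strand).
// ---------------------------------------------------------------------------

struct Hsp {
  int qs, qe, ss, se;       // 0-based inclusive
  int score, nident, ncols;
  std::string qa, sa;
};

// [[Rcpp::export]]
DataFrame seed_extend_cpp(std::string query, std::string subject,
                          int match, int mismatch, int gap_open, int gap_ext,
                          int word, int xdrop, int band, int gap_trigger,
                          int xdrop_gap) {
  std::vector<int> q = encode_dna(query), s = encode_dna(subject);
  const int m = (int)q.size(), n = (int)s.size();
  std::vector<Hsp> hsps;

  if (m >= word && n >= word && word >= 1) {
    const uint64_t mask = (word < 32) ? ((1ULL << (2 * word)) - 1) : ~0ULL;
    std::unordered_map<uint64_t, std::vector<int>> H;
    { // index subject words (skip words containing N)
      uint64_t key = 0; int run = 0;
      for (int j = 0; j < n; ++j) {
        if (s[j] > 3) { key = 0; run = 0; continue; }
        key = ((key << 2) | (uint64_t)s[j]) & mask; ++run;
        if (run >= word) H[key].push_back(j - word + 1);
      }
    }
    // seeds over query
    struct Seed { int d, i, j; };
    std::vector<Seed> seeds;
    {
      uint64_t key = 0; int run = 0;
      for (int i = 0; i < m; ++i) {
        if (q[i] > 3) { key = 0; run = 0; continue; }
        key = ((key << 2) | (uint64_t)q[i]) & mask; ++run;
        if (run >= word) {
          auto it = H.find(key);
          if (it != H.end()) {
            int i0 = i - word + 1;
            for (int j0 : it->second) seeds.push_back({ i0 - j0, i0, j0 });
          }
        }
      }
    }
    std::sort(seeds.begin(), seeds.end(), [](const Seed& x, const Seed& y) {
      if (x.d != y.d) return x.d < y.d;
      return x.i < y.i;
    });

    // ungapped X-drop extension; skip seeds covered by the previous
    // extension on the same diagonal.  `ai` is the right end of the best
    // ungapped segment (always a match pair): the gapped extension is
    // anchored there rather than on the seed word, so a seed upstream of
    // the true high-scoring core cannot drag the anchor off it.
    struct Ung { int i, j, ai, score; };
    std::vector<Ung> ungs;
    int last_d = INT_MIN, cover_end = -1;
    for (const Seed& sd : seeds) {
      if (sd.d != last_d) { last_d = sd.d; cover_end = -1; }
      if (sd.i + word - 1 <= cover_end) continue;
      int sc = word * match, best = sc;
      // rightward
      int i = sd.i + word, j = sd.j + word, bi = sd.i + word - 1;
      int cur = sc;
      while (i < m && j < n) {
        cur += subst(q[i], s[j], match, mismatch);
        if (cur > best) { best = cur; bi = i; }
        if (cur < best - xdrop) break;
        ++i; ++j;
      }
      int right_best = best;
      // leftward
      i = sd.i - 1; j = sd.j - 1;
      cur = right_best; best = right_best;
      while (i >= 0 && j >= 0) {
        cur += subst(q[i], s[j], match, mismatch);
        if (cur > best) best = cur;
        if (cur < best - xdrop) break;
        --i; --j;
      }
      cover_end = bi;
      ungs.push_back({ sd.i, sd.j, bi, best });
    }

    // gapped extension anchored at the best ungapped position
    for (const Ung& u : ungs) {
      if (u.score < gap_trigger) continue;
      int i0 = u.ai, j0 = u.ai - (u.i - u.j);   // anchor pair (match)
      // left: reversed prefixes before the anchor
      std::vector<int> la(q.rend() - i0, q.rend());     // q[0..i0) reversed
      std::vector<int> lb(s.rend() - j0, s.rend());
      ExtResult L = extend_affine(la, lb, match, mismatch, gap_open, gap_ext,
                                  band, xdrop_gap);
      // right: suffixes after the anchor
      std::vector<int> ra(q.begin() + i0 + 1, q.end());
      std::vector<int> rb(s.begin() + j0 + 1, s.end());
      ExtResult R = extend_affine(ra, rb, match, mismatch, gap_open, gap_ext,
                                  band, xdrop_gap);
      Hsp h;
      h.qs = i0 - L.a_used; h.qe = i0 + R.a_used;
      h.ss = j0 - L.b_used; h.se = j0 + R.b_used;
      h.score = L.score + match + R.score;
      std::string qa = L.a_aln, sa = L.b_aln;
      std::reverse(qa.begin(), qa.end());
      std::reverse(sa.begin(), sa.end());
      qa.push_back(decode_dna(q[i0])); sa.push_back(decode_dna(s[j0]));
      qa += R.a_aln; sa += R.b_aln;
      h.ncols = (int)qa.size();
      h.nident = 0;
      for (int t = 0; t < h.ncols; ++t)
        if (qa[t] == sa[t] && qa[t] != '-' && qa[t] != 'N') ++h.nident;
      h.qa = qa; h.sa = sa;
      hsps.push_back(std::move(h));
    }

    // greedy de-duplication: keep best-scoring, drop candidates whose query
    // AND subject intervals are >=50% covered by an already kept alignment
    std::sort(hsps.begin(), hsps.end(), [](const Hsp& x, const Hsp& y) {
      if (x.score != y.score) return x.score > y.score;
      if (x.qs != y.qs) return x.qs < y.qs;
      return x.ss < y.ss;
    });
    std::vector<Hsp> kept;
    for (const Hsp& h : hsps) {
      bool redundant = false;
      for (const Hsp& k : kept) {
        int qo = std::min(h.qe, k.qe) - std::max(h.qs, k.qs) + 1;
        int so = std::min(h.se, k.se) - std::max(h.ss, k.ss) + 1;
        int qlen = h.qe - h.qs + 1, slen = h.se - h.ss + 1;
        if (qo * 2 >= qlen && so * 2 >= slen) { redundant = true; break; }
      }
      if (!redundant) kept.push_back(h);
    }
    hsps.swap(kept);
    // deterministic report order: by query start, then score desc, then sstart
    std::sort(hsps.begin(), hsps.end(), [](const Hsp& x, const Hsp& y) {
      if (x.qs != y.qs) return x.qs < y.qs;
      if (x.score != y.score) return x.score > y.score;
      return x.ss < y.ss;
    });
  }

  int N = (int)hsps.size();
  IntegerVector qs(N), qe(N), ss(N), se(N), score(N), nid(N), nc(N);
  CharacterVector qa(N), sa(N);
  for (int i = 0; i < N; ++i) {
    qs[i] = hsps[i].qs + 1; qe[i] = hsps[i].qe + 1;
    ss[i] = hsps[i].ss + 1; se[i] = hsps[i].se + 1;
    score[i] = hsps[i].score; nid[i] = hsps[i].nident; nc[i] = hsps[i].ncols;
    qa[i] = hsps[i].qa; sa[i] = hsps[i].sa;
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
    _["score"] = score, _["n_ident"] = nid, _["n_cols"] = nc,
    _["aligned_query"] = qa, _["aligned_subject"] = sa,
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Global (Needleman-Wunsch) affine-gap alignment with deterministic
// tie-breaking (match > delete > insert).  Gap of length L costs
// gap_open + gap_ext * L; terminal gaps are charged.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List nw_affine_cpp(std::string a, std::string b,
                   int match, int mismatch, int gap_open, int gap_ext) {
  std::vector<int> ea = encode_dna(a), eb = encode_dna(b);
  const int Ka = (int)ea.size(), Kb = (int)eb.size();
  const size_t W = Kb + 1;
  std::vector<int> M((size_t)(Ka + 1) * W, NEG), X((size_t)(Ka + 1) * W, NEG),
                   Y((size_t)(Ka + 1) * W, NEG);
  std::vector<char> tM((size_t)(Ka + 1) * W, 0), tX((size_t)(Ka + 1) * W, 0),
                    tY((size_t)(Ka + 1) * W, 0);
  auto at = [W](int k, int l) { return (size_t)k * W + l; };
  M[at(0, 0)] = 0;
  for (int k = 1; k <= Ka; ++k) {
    X[at(k, 0)] = -gap_open - gap_ext * k;
    tX[at(k, 0)] = (k == 1) ? 1 : 2;
  }
  for (int l = 1; l <= Kb; ++l) {
    Y[at(0, l)] = -gap_open - gap_ext * l;
    tY[at(0, l)] = (l == 1) ? 1 : 3;
  }
  for (int k = 1; k <= Ka; ++k) {
    for (int l = 1; l <= Kb; ++l) {
      int pm = M[at(k - 1, l - 1)], px = X[at(k - 1, l - 1)], py = Y[at(k - 1, l - 1)];
      int from = pm; char code = 1;
      if (px > from) { from = px; code = 2; }
      if (py > from) { from = py; code = 3; }
      if (from > NEG / 2) {
        M[at(k, l)] = from + subst(ea[k - 1], eb[l - 1], match, mismatch);
        tM[at(k, l)] = code;
      }
      int om = (M[at(k - 1, l)] > NEG / 2) ? M[at(k - 1, l)] - gap_open - gap_ext : NEG;
      int ox = (X[at(k - 1, l)] > NEG / 2) ? X[at(k - 1, l)] - gap_ext : NEG;
      if (om >= ox && om > NEG / 2) { X[at(k, l)] = om; tX[at(k, l)] = 1; }
      else if (ox > NEG / 2)        { X[at(k, l)] = ox; tX[at(k, l)] = 2; }
      int oy = (Y[at(k, l - 1)] > NEG / 2) ? Y[at(k, l - 1)] - gap_ext : NEG;
      int o2 = (M[at(k, l - 1)] > NEG / 2) ? M[at(k, l - 1)] - gap_open - gap_ext : NEG;
      if (o2 >= oy && o2 > NEG / 2) { Y[at(k, l)] = o2; tY[at(k, l)] = 1; }
      else if (oy > NEG / 2)        { Y[at(k, l)] = oy; tY[at(k, l)] = 3; }
    }
  }
  int sc = M[at(Ka, Kb)]; int state = 0;
  if (X[at(Ka, Kb)] > sc) { sc = X[at(Ka, Kb)]; state = 1; }
  if (Y[at(Ka, Kb)] > sc) { sc = Y[at(Ka, Kb)]; state = 2; }
  std::string aa, bb;
  int k = Ka, l = Kb;
  while (!(k == 0 && l == 0)) {
    if (state == 0) {
      char code = tM[at(k, l)];
      aa.push_back(decode_dna(ea[k - 1])); bb.push_back(decode_dna(eb[l - 1]));
      --k; --l; state = (code == 1) ? 0 : (code == 2 ? 1 : 2);
    } else if (state == 1) {
      char code = tX[at(k, l)];
      aa.push_back(decode_dna(ea[k - 1])); bb.push_back('-');
      --k; state = (code == 1) ? 0 : 1;
    } else {
      char code = tY[at(k, l)];
      aa.push_back('-'); bb.push_back(decode_dna(eb[l - 1]));
      --l; state = (code == 1) ? 0 : 2;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = sc, _["aligned_a"] = aa, _["aligned_b"] = bb);
}

// ---------------------------------------------------------------------------
// Profile-profile global alignment for progressive MSA.
//
// U, V: 5 x L matrices of residue counts per column (rows A,C,G,T,N; gap
// characters contribute nothing).  Column-column score is the mean pairwise
// substitution score over residue pairs; affine gap penalties are applied
// once per gapped column.  Returns the merge path as a string over
// {M = both, X = consume U column, Y = consume V column}.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix U, NumericMatrix V,
                       double nU, double nV,
                       double match, double mismatch,
                       double gap_open, double gap_ext) {
  const int Ka = U.ncol(), Kb = V.ncol();
  const double DNEG = -1e30;
  // precompute column-column scores
  std::vector<double> colsc((size_t)Ka * Kb);
  for (int i = 0; i < Ka; ++i) {
    double ua = U(0, i), uc = U(1, i), ug = U(2, i), ut = U(3, i), un = U(4, i);
    double usum = ua + uc + ug + ut + un;
    for (int j = 0; j < Kb; ++j) {
      double va = V(0, j), vc = V(1, j), vg = V(2, j), vt = V(3, j), vn = V(4, j);
      double vsum = va + vc + vg + vt + vn;
      double same = ua * va + uc * vc + ug * vg + ut * vt; // N never matches
      double total = usum * vsum;
      colsc[(size_t)i * Kb + j] =
        (same * match + (total - same) * mismatch) / (nU * nV);
    }
  }
  const size_t W = Kb + 1;
  std::vector<double> M((size_t)(Ka + 1) * W, DNEG), X((size_t)(Ka + 1) * W, DNEG),
                      Y((size_t)(Ka + 1) * W, DNEG);
  std::vector<char> tM((size_t)(Ka + 1) * W, 0), tX((size_t)(Ka + 1) * W, 0),
                    tY((size_t)(Ka + 1) * W, 0);
  auto at = [W](int k, int l) { return (size_t)k * W + l; };
  M[at(0, 0)] = 0.0;
  for (int k = 1; k <= Ka; ++k) { X[at(k, 0)] = -gap_open - gap_ext * k; tX[at(k, 0)] = (k == 1) ? 1 : 2; }
  for (int l = 1; l <= Kb; ++l) { Y[at(0, l)] = -gap_open - gap_ext * l; tY[at(0, l)] = (l == 1) ? 1 : 3; }
  for (int k = 1; k <= Ka; ++k) {
    for (int l = 1; l <= Kb; ++l) {
      double pm = M[at(k - 1, l - 1)], px = X[at(k - 1, l - 1)], py = Y[at(k - 1, l - 1)];
      double from = pm; char code = 1;
      if (px > from) { from = px; code = 2; }
      if (py > from) { from = py; code = 3; }
      if (from > DNEG / 2) {
        M[at(k, l)] = from + colsc[(size_t)(k - 1) * Kb + (l - 1)];
        tM[at(k, l)] = code;
      }
      double om = (M[at(k - 1, l)] > DNEG / 2) ? M[at(k - 1, l)] - gap_open - gap_ext : DNEG;
      double ox = (X[at(k - 1, l)] > DNEG / 2) ? X[at(k - 1, l)] - gap_ext : DNEG;
      if (om >= ox && om > DNEG / 2) { X[at(k, l)] = om; tX[at(k, l)] = 1; }
      else if (ox > DNEG / 2)        { X[at(k, l)] = ox; tX[at(k, l)] = 2; }
      double o2 = (M[at(k, l - 1)] > DNEG / 2) ? M[at(k, l - 1)] - gap_open - gap_ext : DNEG;
      double oy = (Y[at(k, l - 1)] > DNEG / 2) ? Y[at(k, l - 1)] - gap_ext : DNEG;
      if (o2 >= oy && o2 > DNEG / 2) { Y[at(k, l)] = o2; tY[at(k, l)] = 1; }
      else if (oy > DNEG / 2)        { Y[at(k, l)] = oy; tY[at(k, l)] = 3; }
    }
  }
  double sc = M[at(Ka, Kb)]; int state = 0;
  if (X[at(Ka, Kb)] > sc) { sc = X[at(Ka, Kb)]; state = 1; }
  if (Y[at(Ka, Kb)] > sc) { sc = Y[at(Ka, Kb)]; state = 2; }
  std::string path;
  int k = Ka, l = Kb;
  while (!(k == 0 && l == 0)) {
    if (state == 0) {
      char code = tM[at(k, l)];
      path.push_back('M'); --k; --l;
      state = (code == 1) ? 0 : (code == 2 ? 1 : 2);
    } else if (state == 1) {
      char code = tX[at(k, l)];
      path.push_back('X'); --k; state = (code == 1) ? 0 : 1;
    } else {
      char code = tY[at(k, l)];
      path.push_back('Y'); --l; state = (code == 1) ? 0 : 2;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = sc, _["path"] = path);
}
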