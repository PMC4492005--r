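#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Affine-gap DP engines for VDJ partitioning.
//
// Conventions shared with the R layer:
//  * coordinates are 0-based, half-open, 5'->3' top strand;
//  * 'I' consumes query (insertion relative to germline), 'D' consumes
//    germline, 'M' match, 'X' mismatch;
//  * a gap of length L costs gap_open + (L-1)*gap_extend (both negative);
//  * 'N' never matches anything (scores as mismatch);
//  * tie-breaks: diagonal > deletion > insertion for moves; smallest query
//    index, then smallest germline index for end cells.

static const double NEG = -1e18;

enum State { ST_M = 0, ST_D = 1, ST_I = 2, ST_START = 3 };
enum Mode { MODE_OVERLAP = 0, MODE_LOCAL = 1, MODE_ANCHORED = 2 };

struct Scoring {
  double match, mismatch, open, ext;
};

static inline double subst(char a, char b, const Scoring& sc) {
  if (a == b && a != 'N') return sc.match;
  return sc.mismatch;
}

// pick best of (m, d, i) with preference M > D > I; returns state, best in *val
static inline int best3(double m, double d, double i, double* val) {
  int st = ST_M; double v = m;
  if (d > v) { v = d; st = ST_D; }
  if (i > v) { v = i; st = ST_I; }
  *val = v;
  return st;
}

struct DPResult {
  double score;
  int q_start, q_end, g_start, g_end;
  std::string ops;   // 5'->3' per-base op codes
  int n_match;
};

// Core Gotoh fill + traceback. q along rows (i), g along columns (j).
static DPResult gotoh(const std::string& q, const std::string& g,
                      const Scoring& sc, int mode,
                      bool end_block_boundary = false) {
  const int n = (int)q.size(), m = (int)g.size();
  std::vector<double> M((n + 1) * (m + 1), NEG), D(M), I(M);
  std::vector<unsigned char> pM((n + 1) * (m + 1), ST_START), pD(pM), pI(pM);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  if (mode == MODE_OVERLAP || mode == MODE_LOCAL) {
    for (int i = 1; i <= n; ++i) M[at(i, 0)] = 0.0;
    for (int j = 1; j <= m; ++j) M[at(0, j)] = 0.0;
  } else { // anchored: first row/col reachable only through gap chains
    for (int i = 1; i <= n; ++i) {
      I[at(i, 0)] = sc.open + (i - 1) * sc.ext;
      pI[at(i, 0)] = (i == 1) ? ST_M : ST_I;
    }
    for (int j = 1; j <= m; ++j) {
      D[at(0, j)] = sc.open + (j - 1) * sc.ext;
      pD[at(0, j)] = (j == 1) ? ST_M : ST_D;
    }
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = at(i, j);
      // diagonal
      double dv;
      int dst = best3(M[at(i - 1, j - 1)], D[at(i - 1, j - 1)],
                      I[at(i - 1, j - 1)], &dv);
      double mv = dv + subst(q[i - 1], g[j - 1], sc);
      unsigned char mp = (unsigned char)dst;
      if (dv <= NEG / 2) { mv = NEG; }
      if (mode == MODE_LOCAL && mv < subst(q[i - 1], g[j - 1], sc)) {
        // restart: alignment begins with this pair
        mv = subst(q[i - 1], g[j - 1], sc);
        mp = ST_START;
      }
      M[ij] = mv; pM[ij] = mp;
      // deletion (consumes germline, horizontal)
      {
        double cm = M[at(i, j - 1)] + sc.open;
        double cd = D[at(i, j - 1)] + sc.ext;
        double ci = I[at(i, j - 1)] + sc.open;
        double v; int st = best3(cm, cd, ci, &v);
        D[ij] = (v <= NEG / 2) ? NEG : v;
        pD[ij] = (unsigned char)st;
      }
      // insertion (consumes query, vertical)
      {
        double cm = M[at(i - 1, j)] + sc.open;
        double cd = D[at(i - 1, j)] + sc.open;
        double ci = I[at(i - 1, j)] + sc.ext;
        double v; int st = best3(cm, cd, ci, &v);
        I[ij] = (v <= NEG / 2) ? NEG : v;
        pI[ij] = (unsigned char)st;
      }
    }
  }

  // end cell selection
  double best = NEG; int bi = 0, bj = 0, bst = ST_M;
  if (!end_block_boundary) {
    // max anywhere; smallest query index, then germline index, then M>D>I
    best = 0.0; bi = 0; bj = 0; bst = ST_M; // empty alignment floor
    if (mode == MODE_ANCHORED) best = NEG;  // anchored may be forced negative
    for (int i = 0; i <= n; ++i) {
      for (int j = 0; j <= m; ++j) {
        const int ij = at(i, j);
        if (i > 0 && j > 0) {
          if (M[ij] > best) { best = M[ij]; bi = i; bj = j; bst = ST_M; }
          if (D[ij] > best) { best = D[ij]; bi = i; bj = j; bst = ST_D; }
          if (I[ij] > best) { best = I[ij]; bi = i; bj = j; bst = ST_I; }
        }
      }
    }
    if (best <= NEG / 2) { best = 0.0; bi = bj = 0; bst = ST_M; }
  } else {
    // block mode: entries restricted to last row (i==n) or last column (j==m)
    // in the reversed frame; ties -> smaller |i-j|, then i==n side, then
    // larger i, then larger j.
    bool have = false;
    for (int i = 0; i <= n; ++i) {
      for (int j = 0; j <= m; ++j) {
        if (i != n && j != m) continue;
        if (i == 0 && j == 0) continue;
        const int ij = at(i, j);
        double vals[3] = { M[ij], D[ij], I[ij] };
        int sts[3] = { ST_M, ST_D, ST_I };
        for (int k = 0; k < 3; ++k) {
          double v = vals[k];
          if (v <= NEG / 2) continue;
          bool take = false;
          if (!have || v > best) take = true;
          else if (v == best) {
            int dnew = std::abs(i - j), dold = std::abs(bi - bj);
            if (dnew < dold) take = true;
            else if (dnew == dold) {
              bool rnew = (i == n), rold = (bi == n);
              if (rnew && !rold) take = true;
              else if (rnew == rold) {
                if (i > bi) take = true;
                else if (i == bi && j > bj) take = true;
              }
            }
          }
          if (take) { best = v; bi = i; bj = j; bst = sts[k]; have = true; }
        }
      }
    }
    if (!have) { best = 0.0; bi = bj = 0; bst = ST_M; }
  }

  // traceback
  std::string rev; // emitted end -> start
  int i = bi, j = bj, st = bst, nmatch = 0;
  while (!(i == 0 && j == 0)) {
    if (st == ST_M) {
      if (i == 0 || j == 0) break;            // free leading region
      unsigned char p = pM[at(i, j)];
      char op = (q[i - 1] == g[j - 1] && q[i - 1] != 'N') ? 'M' : 'X';
      if (op == 'M') ++nmatch;
      rev.push_back(op);
      --i; --j;
      if (p == ST_START) break;
      st = p;
    } else if (st == ST_D) {
      unsigned char p = pD[at(i, j)];
      rev.push_back('D');
      --j;
      st = p;
    } else { // ST_I
      unsigned char p = pI[at(i, j)];
      rev.push_back('I');
      --i;
      st = p;
    }
  }

  DPResult res;
  res.score = best;
  res.q_start = i; res.q_end = bi;
  res.g_start = j; res.g_end = bj;
  res.ops.assign(rev.rbegin(), rev.rend());
  res.n_match = nmatch;
  return res;
}

static std::string rle(const std::string& ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out.push_back(ops[i]);
    i = j;
  }
  return out;
}

static double score_opstring(const std::string& ops, const Scoring& sc) {
  double s = 0.0;
  for (size_t i = 0; i < ops.size(); ++i) {
    char c = ops[i];
    if (c == 'M') s += sc.match;
    else if (c == 'X') s += sc.mismatch;
    else { // gap run
      size_t j = i;
      while (j < ops.size() && ops[j] == c) ++j;
      s += sc.open + (double)(j - i - 1) * sc.ext;
      i = j - 1;
    }
  }
  return s;
}

static List dp_to_list(const DPResult& r) {
  return List::create(
    _["score"] = r.score,
    _["q_start"] = r.q_start, _["q_end"] = r.q_end,
    _["g_start"] = r.g_start, _["g_end"] = r.g_end,
    _["cigar"] = rle(r.ops), _["n_match"] = r.n_match);
}

// [[Rcpp::export]]
List cpp_align(std::string q, std::string g,
               double match, double mismatch, double gap_open,
               double gap_extend, std::string mode) {
  Scoring sc{match, mismatch, gap_open, gap_extend};
  int md = MODE_OVERLAP;
  if (mode == "local") md = MODE_LOCAL;
  else if (mode == "anchored") md = MODE_ANCHORED;
  else if (mode != "overlap") stop("unknown mode: %s", mode.c_str());
  DPResult r = gotoh(q, g, sc, md);
  return dp_to_list(r);
}

// Block submatrix used by the approximate backwards walk.  (q_pos, g_pos) is
// the 3' (exclusive, high-index) corner; the block spans up to block_size
// bases backwards in each sequence (truncated at the 5' starts).  Returns the
// best entry restricted to the block's 5' boundary (first row or column in
// the forward frame) and the ops from the corner to that entry (3'->5').
static void block_core(const std::string& q, const std::string& g,
                       int q_pos, int g_pos, const Scoring& sc, int block_size,
                       int* consumed_q, int* consumed_g,
                       std::string* ops_back, double* score) {
  int nq = std::min(block_size, q_pos);
  int ng = std::min(block_size, g_pos);
  std::string qs(q.rbegin() + (q.size() - q_pos), q.rbegin() + (q.size() - q_pos) + nq);
  std::string gs(g.rbegin() + (g.size() - g_pos), g.rbegin() + (g.size() - g_pos) + ng);
  DPResult r = gotoh(qs, gs, sc, MODE_ANCHORED, true);
  *consumed_q = r.q_end;
  *consumed_g = r.g_end;
  // r.ops runs origin(corner)->entry in the reversed frame, i.e. 3'->5'
  // already; keep as-is.
  *ops_back = r.ops;
  *score = r.score;
}

// [[Rcpp::export]]
List cpp_block_submatrix(std::string q, std::string g, int q_pos, int g_pos,
                         double match, double mismatch, double gap_open,
                         double gap_extend, int block_size) {
  if (q_pos < 0 || q_pos > (int)q.size() || g_pos < 0 || g_pos > (int)g.size())
    stop("block corner out of range");
  if (q_pos == 0 && g_pos == 0)
    stop("reached sequence start");
  Scoring sc{match, mismatch, gap_open, gap_extend};
  int cq, cg; std::string ops; double sco;
  block_core(q, g, q_pos, g_pos, sc, block_size, &cq, &cg, &ops, &sco);
  std::string fwd(ops.rbegin(), ops.rend());
  return List::create(
    _["q_entry"] = q_pos - cq, _["g_entry"] = g_pos - cg,
    _["consumed_q"] = cq, _["consumed_g"] = cg,
    _["score"] = sco, _["cigar"] = rle(fwd));
}

// The approximate backwards algorithm: anchored at (q_anchor, g_anchor) (the
// first base of the conserved motif in each sequence), walks the diagonal
// 3'->5'; on a mismatch steps forward step_back bases and aligns a
// block_size^2 submatrix, resuming from its best boundary entry; terminates
// when either sequence's 5' end is consumed.
// [[Rcpp::export]]
List cpp_approx_backwards(std::string q, std::string g, int q_anchor,
                          int g_anchor, double match, double mismatch,
                          double gap_open, double gap_extend,
                          int block_size, int step_back) {
  if (q_anchor < 0 || q_anchor > (int)q.size())
    stop("q_anchor out of range");
  if (g_anchor < 0 || g_anchor > (int)g.size())
    stop("g_anchor out of range");
  Scoring sc{match, mismatch, gap_open, gap_extend};
  std::string ops; // accumulated 3'->5'
  int qi = q_anchor, gi = g_anchor;
  int diag_run = 0; // diagonal matches since the last block / anchor
  while (qi > 0 && gi > 0) {
    char a = q[qi - 1], b = g[gi - 1];
    if (a == b && a != 'N') {
      ops.push_back('M');
      --qi; --gi; ++diag_run;
      continue;
    }
    // mismatch: step forward (3') and solve a block submatrix
    int sb = std::min(step_back, diag_run);
    for (int k = 0; k < sb; ++k) ops.pop_back(); // re-done inside the block
    int qc = qi + sb, gc = gi + sb;
    int cq, cg; std::string bops; double bsc;
    block_core(q, g, qc, gc, sc, block_size, &cq, &cg, &bops, &bsc);
    ops += bops;
    qi = qc - cq;
    gi = gc - cg;
    diag_run = 0;
    if (cq == 0 && cg == 0) break; // cannot happen, but guard against stall
  }
  std::string fwd(ops.rbegin(), ops.rend());
  double score = score_opstring(fwd, sc);
  int nm = (int)std::count(fwd.begin(), fwd.end(), 'M');
  return List::create(
    _["score"] = score,
    _["q_start"] = qi, _["q_end"] = q_anchor,
    _["g_start"] = gi, _["g_end"] = g_anchor,
    _["cigar"] = rle(fwd), _["n_match"] = nm);
}

// Run-length D matcher: +1 per match, mismatch resets the run to 0; when a
// new run reaches 3 matches and the run score immediately before the mismatch
// exceeded bridge_min_prev, the previous score is added (the mismatch is
// recognised as a somatic mutation).  Max anywhere; gapless (diagonal only).
// [[Rcpp::export]]
List cpp_d_match(std::string junction, std::string d,
                 int bridge_run = 3, int bridge_min_prev = 3) {
  const int nj = (int)junction.size(), nd = (int)d.size();
  double best = 0.0;
  int b_i0 = 0, b_j0 = 0, b_t0 = 0, b_t1 = -1;
  for (int off = -(nd - 1); off <= nj - 1; ++off) {
    int i0 = off >= 0 ? off : 0;
    int j0 = off >= 0 ? 0 : -off;
    int L = std::min(nj - i0, nd - j0);
    if (L <= 0) continue;
    double cur = 0.0, before = 0.0;
    int since = 0, cur_start = 0, before_start = 0;
    for (int t = 0; t < L; ++t) {
      char a = junction[i0 + t], b = d[j0 + t];
      if (a == b && a != 'N') {
        if (since == 0) cur_start = t;
        ++since; cur += 1.0;
        if (since == bridge_run && before > (double)bridge_min_prev) {
          cur += before;
          cur_start = before_start;
        }
        if (cur > best) {
          best = cur; b_i0 = i0; b_j0 = j0; b_t0 = cur_start; b_t1 = t;
        }
      } else {
        before = cur;
        before_start = cur_start;
        cur = 0.0; since = 0;
      }
    }
  }
  std::string ops;
  int nm = 0;
  for (int t = b_t0; t <= b_t1; ++t) {
    char a = junction[b_i0 + t], b = d[b_j0 + t];
    if (a == b && a != 'N') { ops.push_back('M'); ++nm; }
    else ops.push_back('X');
  }
  return List::create(
    _["score"] = best,
    _["q_start"] = b_i0 + b_t0, _["q_end"] = b_i0 + b_t1 + 1,
    _["g_start"] = b_j0 + b_t0, _["g_end"] = b_j0 + b_t1 + 1,
    _["cigar"] = rle(ops), _["n_match"] = nm);
}
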