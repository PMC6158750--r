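#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Plain base codes A=0, C=1, G=2, T=3. These coincide with the 2-bit sRNA
// code; the mRNA code for a base is (3 - plain), so a perfect antiparallel
// Watson-Crick pairing gives equal encoded numbers for the two strands.

static const int WLEN = 32;        // candidate window length (nt)
static const int ANCHOR_SRNA = 10; // sRNA position anchored at the cleavage site
static const int ANCHOR_WIN = 17;  // window index opposite sRNA position 10

static inline int bcode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

// 0 = Watson-Crick match, 1 = G:U wobble, 2 = mismatch (plain codes)
static inline int classify_pair(int s, int t) {
  if (s + t == 3) return 0;
  if ((s == 2 && t == 3) || (s == 3 && t == 2)) return 1;
  return 2;
}

// ---------------------------------------------------------------------------
// targeting rules
// ---------------------------------------------------------------------------

struct Rules {
  double max_score, mismatch_score, gu_score, gap_score;
  double core_mult, pos10_score, pos11_score;
  int max_mm, max_adj, max_gu, max_gaps;
  int core_start, core_end, max_mm_core, max_adj_core;
  bool allow10, allow11, gu_counts, has_permissible;
  std::vector<bool> permissible, non_permissible;
};

static Rules parse_rules(List rl) {
  Rules r;
  r.max_score       = as<double>(rl["max_score"]);
  r.mismatch_score  = as<double>(rl["mismatch_score"]);
  r.gu_score        = as<double>(rl["gu_wobble_score"]);
  r.gap_score       = as<double>(rl["gap_score"]);
  r.core_mult       = as<double>(rl["core_multiplier"]);
  r.pos10_score     = as<double>(rl["pos10_mismatch_score"]);
  r.pos11_score     = as<double>(rl["pos11_mismatch_score"]);
  r.max_mm          = as<int>(rl["max_mismatches"]);
  r.max_adj         = as<int>(rl["max_adjacent_mismatches"]);
  r.max_gu          = as<int>(rl["max_gu_wobbles"]);
  r.max_gaps        = as<int>(rl["max_gaps"]);
  r.core_start      = as<int>(rl["core_start"]);
  r.core_end        = as<int>(rl["core_end"]);
  r.max_mm_core     = as<int>(rl["max_mismatches_core"]);
  r.max_adj_core    = as<int>(rl["max_adjacent_mismatches_core"]);
  r.allow10         = as<bool>(rl["allow_mismatch_pos10"]);
  r.allow11         = as<bool>(rl["allow_mismatch_pos11"]);
  r.gu_counts       = as<bool>(rl["gu_counts_as_mismatch"]);
  r.permissible.assign(64, false);
  r.non_permissible.assign(64, false);
  IntegerVector pm  = rl["permissible_mismatch_positions"];
  IntegerVector npm = rl["non_permissible_mismatch_positions"];
  r.has_permissible = pm.size() > 0;
  for (int i = 0; i < pm.size(); ++i)
    if (pm[i] >= 0 && pm[i] < 64) r.permissible[pm[i]] = true;
  for (int i = 0; i < npm.size(); ++i)
    if (npm[i] >= 0 && npm[i] < 64) r.non_permissible[npm[i]] = true;
  return r;
}

// ---------------------------------------------------------------------------
// duplex alignment: depth-first enumeration anchored at the cleavage site
// ---------------------------------------------------------------------------

// column states: 0 match, 1 wobble, 2 mismatch,
//                3 srna_gap ('-' on sRNA line, window base consumed),
//                4 target_gap ('-' on target line, sRNA base consumed)
struct Col { char sc, tc; int state; };

struct Save {
  double score;
  int n_mm, n_wob, n_gaps, core_mm, run, core_run, center_run, center_core_run;
  bool copen, ccopen;
  size_t n5, n3;
};

struct DupCtx {
  std::string sseq, wseq;
  std::vector<int> s, w;   // 1-based plain codes
  int L;
  Rules r;
  double score;
  int n_mm, n_wob, n_gaps, core_mm;
  int run, core_run;             // current adjacent-defect run (traversal order)
  int center_run, center_core_run; // run containing the anchor, grown 5'-ward
  bool copen, ccopen;
  Col anchor;
  std::vector<Col> cols5, cols3;
  std::vector<List> out;
};

static inline Save save_state(const DupCtx &C) {
  return Save{C.score, C.n_mm, C.n_wob, C.n_gaps, C.core_mm, C.run, C.core_run,
              C.center_run, C.center_core_run, C.copen, C.ccopen,
              C.cols5.size(), C.cols3.size()};
}

static inline void restore_state(DupCtx &C, const Save &s) {
  C.score = s.score; C.n_mm = s.n_mm; C.n_wob = s.n_wob; C.n_gaps = s.n_gaps;
  C.core_mm = s.core_mm; C.run = s.run; C.core_run = s.core_run;
  C.center_run = s.center_run; C.center_core_run = s.center_core_run;
  C.copen = s.copen; C.ccopen = s.ccopen;
  C.cols5.resize(s.n5); C.cols3.resize(s.n3);
}

// apply one column at sRNA position ipos; returns false if any rule is broken
static bool apply_col(DupCtx &C, int ipos, int state) {
  const Rules &r = C.r;
  bool core = (ipos >= r.core_start && ipos <= r.core_end);
  double mult = core ? r.core_mult : 1.0;
  double pen = 0.0;
  bool mmlike = false;
  if (state == 1) {
    if ((ipos == 10 && !r.allow10) || (ipos == 11 && !r.allow11)) return false;
    pen = r.gu_score * mult;
    C.n_wob++;
    if (C.n_wob > r.max_gu) return false;
    if (r.gu_counts) {
      C.n_mm++; if (core) C.core_mm++;
      mmlike = true;
    }
  } else if (state == 2) {
    if ((ipos == 10 && !r.allow10) || (ipos == 11 && !r.allow11)) return false;
    if (ipos < 64 && r.non_permissible[ipos]) return false;
    if (r.has_permissible && (ipos >= 64 || !r.permissible[ipos])) return false;
    double ms = (ipos == 10) ? r.pos10_score : (ipos == 11) ? r.pos11_score
                                                            : r.mismatch_score;
    pen = ms * mult;
    C.n_mm++; if (core) C.core_mm++;
    mmlike = true;
  } else if (state >= 3) {
    if ((ipos == 10 && !r.allow10) || (ipos == 11 && !r.allow11)) return false;
    pen = r.gap_score * mult;
    C.n_gaps++;
    if (C.n_gaps > r.max_gaps) return false;
    mmlike = true;
  }
  C.score += pen;
  if (C.score > r.max_score + 1e-9) return false;
  if (C.n_mm > r.max_mm) return false;
  if (core && C.core_mm > r.max_mm_core) return false;
  if (mmlike) C.run++; else C.run = 0;
  if (core) { if (mmlike) C.core_run++; else C.core_run = 0; } else C.core_run = 0;
  if (C.run > r.max_adj) return false;
  if (C.core_run > r.max_adj_core) return false;
  if (C.copen)  { if (mmlike) C.center_run++;       else C.copen  = false; }
  if (C.ccopen) { if (core && mmlike) C.center_core_run++; else C.ccopen = false; }
  return true;
}

static void record_alignment(DupCtx &C) {
  size_t n = C.cols3.size() + 1 + C.cols5.size();
  std::string tl, sl;
  tl.reserve(n); sl.reserve(n);
  IntegerVector st(n);
  size_t k = 0;
  for (size_t j = C.cols3.size(); j-- > 0; ) { // ascending window position
    tl.push_back(C.cols3[j].tc); sl.push_back(C.cols3[j].sc);
    st[k++] = C.cols3[j].state;
  }
  tl.push_back(C.anchor.tc); sl.push_back(C.anchor.sc); st[k++] = C.anchor.state;
  for (size_t j = 0; j < C.cols5.size(); ++j) {
    tl.push_back(C.cols5[j].tc); sl.push_back(C.cols5[j].sc);
    st[k++] = C.cols5[j].state;
  }
  int mm = 0, wob = 0, gaps = 0;
  for (size_t j = 0; j < n; ++j) {
    if (st[j] == 1) wob++;
    else if (st[j] == 2) mm++;
    else if (st[j] >= 3) gaps++;
  }
  C.out.push_back(List::create(
      _["score"] = C.score, _["n_mismatches"] = mm, _["n_wobbles"] = wob,
      _["n_gaps"] = gaps, _["states"] = st,
      _["target_line"] = tl, _["srna_line"] = sl));
}

static void dfs3(DupCtx &C, int i, int t);

// 5'-ward phase: sRNA positions 9..1, window cursor increasing from 18
static void dfs5(DupCtx &C, int i, int t) {
  if (C.out.size() > 200000) stop("alignment enumeration exploded");
  if (i == 0) {
    Save sv = save_state(C);
    C.run = C.center_run;            // duplex columns ..12,11,(10,9,.. run continuity
    C.core_run = C.center_core_run;
    dfs3(C, ANCHOR_SRNA + 1, ANCHOR_WIN - 1);
    restore_state(C, sv);
    return;
  }
  if (t <= WLEN && C.w[t] >= 0) {
    Save sv = save_state(C);
    int stt = classify_pair(C.s[i], C.w[t]);
    if (apply_col(C, i, stt)) {
      C.cols5.push_back(Col{C.sseq[i - 1], C.wseq[t - 1], stt});
      dfs5(C, i - 1, t + 1);
    }
    restore_state(C, sv);
  }
  if (t <= WLEN && C.n_gaps < C.r.max_gaps) { // skip a window base (sRNA-line gap)
    Save sv = save_state(C);
    if (apply_col(C, i, 3)) {
      C.cols5.push_back(Col{'-', C.wseq[t - 1], 3});
      dfs5(C, i, t + 1);
    }
    restore_state(C, sv);
  }
  if (C.n_gaps < C.r.max_gaps) { // bulge the sRNA base (target-line gap)
    Save sv = save_state(C);
    if (apply_col(C, i, 4)) {
      C.cols5.push_back(Col{C.sseq[i - 1], '-', 4});
      dfs5(C, i - 1, t);
    }
    restore_state(C, sv);
  }
}

// 3'-ward phase: sRNA positions 11..L, window cursor decreasing from 16
static void dfs3(DupCtx &C, int i, int t) {
  if (i > C.L) { record_alignment(C); return; }
  if (t >= 1 && C.w[t] >= 0) {
    Save sv = save_state(C);
    int stt = classify_pair(C.s[i], C.w[t]);
    if (apply_col(C, i, stt)) {
      C.cols3.push_back(Col{C.sseq[i - 1], C.wseq[t - 1], stt});
      dfs3(C, i + 1, t - 1);
    }
    restore_state(C, sv);
  }
  if (t >= 1 && C.n_gaps < C.r.max_gaps) {
    Save sv = save_state(C);
    if (apply_col(C, i, 3)) {
      C.cols3.push_back(Col{'-', C.wseq[t - 1], 3});
      dfs3(C, i, t - 1);
    }
    restore_state(C, sv);
  }
  if (C.n_gaps < C.r.max_gaps) {
    Save sv = save_state(C);
    if (apply_col(C, i, 4)) {
      C.cols3.push_back(Col{C.sseq[i - 1], '-', 4});
      dfs3(C, i + 1, t);
    }
    restore_state(C, sv);
  }
}

// Enumerate every rule-compliant alignment of `srna` (5'->3') against a 32-nt
// candidate window, anchored with sRNA position 10 opposite window index 17.
// [[Rcpp::export]]
List duplex_align_all_cpp(std::string srna, std::string window, List rules) {
  if ((int)window.size() != WLEN) stop("candidate window must be exactly 32 nt");
  DupCtx C;
  C.sseq = srna; C.wseq = window;
  C.L = (int)srna.size();
  if (C.L < ANCHOR_SRNA) stop("sRNA shorter than the anchor position (10 nt)");
  if (27 - C.L < 1)
    stop("sRNA 3' end would overhang the candidate window"); // hard error, no truncation
  C.s.assign(C.L + 1, -1);
  for (int i = 1; i <= C.L; ++i) {
    C.s[i] = bcode(srna[i - 1]);
    if (C.s[i] < 0) stop("sRNA contains a non-ACGT base");
  }
  C.w.assign(WLEN + 1, -1);
  for (int i = 1; i <= WLEN; ++i) C.w[i] = bcode(window[i - 1]);
  C.r = parse_rules(rules);
  C.score = 0; C.n_mm = C.n_wob = C.n_gaps = C.core_mm = 0;
  C.run = C.core_run = 0;
  C.center_run = C.center_core_run = 0;
  C.copen = C.ccopen = true;
  if (C.w[ANCHOR_WIN] >= 0) {
    int stt = classify_pair(C.s[ANCHOR_SRNA], C.w[ANCHOR_WIN]);
    if (apply_col(C, ANCHOR_SRNA, stt)) {
      C.anchor = Col{srna[ANCHOR_SRNA - 1], window[ANCHOR_WIN - 1], stt};
      dfs5(C, ANCHOR_SRNA - 1, ANCHOR_WIN + 1);
    }
  }
  return wrap(C.out);
}

// ---------------------------------------------------------------------------
// region feasibility: can a sRNA 7-mer region pair with a mRNA 7-mer without,
// within the region alone, exceeding any global rule budget?
// ---------------------------------------------------------------------------

struct RegCtx {
  int s[8], t[8];   // 1-based plain codes of the two 7-mers
  int abs0;         // absolute sRNA position of region index k is abs0 + k
  Rules r;
  double score;
  int n_mm, n_wob, n_gaps, core_mm, run, core_run;
  int center_run, center_core_run;
  bool copen, ccopen;
};

struct RegSave {
  double score;
  int n_mm, n_wob, n_gaps, core_mm, run, core_run, center_run, center_core_run;
  bool copen, ccopen;
};

static inline RegSave reg_save(const RegCtx &C) {
  return RegSave{C.score, C.n_mm, C.n_wob, C.n_gaps, C.core_mm, C.run, C.core_run,
                 C.center_run, C.center_core_run, C.copen, C.ccopen};
}
static inline void reg_restore(RegCtx &C, const RegSave &s) {
  C.score = s.score; C.n_mm = s.n_mm; C.n_wob = s.n_wob; C.n_gaps = s.n_gaps;
  C.core_mm = s.core_mm; C.run = s.run; C.core_run = s.core_run;
  C.center_run = s.center_run; C.center_core_run = s.center_core_run;
  C.copen = s.copen; C.ccopen = s.ccopen;
}

// state -1 denotes a free column (target base outside the 7-mer: zero cost)
static bool reg_apply(RegCtx &C, int ipos, int state) {
  const Rules &r = C.r;
  bool core = (ipos >= r.core_start && ipos <= r.core_end);
  double mult = core ? r.core_mult : 1.0;
  double pen = 0.0;
  bool mmlike = false;
  if (state == 1) {
    if ((ipos == 10 && !r.allow10) || (ipos == 11 && !r.allow11)) return false;
    pen = r.gu_score * mult;
    C.n_wob++;
    if (C.n_wob > r.max_gu) return false;
    if (r.gu_counts) { C.n_mm++; if (core) C.core_mm++; mmlike = true; }
  } else if (state == 2) {
    if ((ipos == 10 && !r.allow10) || (ipos == 11 && !r.allow11)) return false;
    if (ipos < 64 && r.non_permissible[ipos]) return false;
    if (r.has_permissible && (ipos >= 64 || !r.permissible[ipos])) return false;
    double ms = (ipos == 10) ? r.pos10_score : (ipos == 11) ? r.pos11_score
                                                            : r.mismatch_score;
    pen = ms * mult;
    C.n_mm++; if (core) C.core_mm++;
    mmlike = true;
  } else if (state >= 3) {
    if ((ipos == 10 && !r.allow10) || (ipos == 11 && !r.allow11)) return false;
    pen = r.gap_score * mult;
    C.n_gaps++;
    if (C.n_gaps > r.max_gaps) return false;
    mmlike = true;
  }
  C.score += pen;
  if (C.score > r.max_score + 1e-9) return false;
  if (C.n_mm > r.max_mm) return false;
  if (core && C.core_mm > r.max_mm_core) return false;
  if (mmlike) C.run++; else C.run = 0;
  if (core) { if (mmlike) C.core_run++; else C.core_run = 0; } else C.core_run = 0;
  if (C.run > r.max_adj) return false;
  if (C.core_run > r.max_adj_core) return false;
  if (C.copen)  { if (mmlike) C.center_run++;            else C.copen  = false; }
  if (C.ccopen) { if (core && mmlike) C.center_core_run++; else C.ccopen = false; }
  return true;
}

struct Phase {
  std::vector<int> ks; // region indices in traversal order
  int c0;              // target cursor paired with ks[0] when unshifted
  int dc;              // cursor step on a paired column
  bool seed_center;    // seed the run from the anchor-containing run on entry
};

static bool reg_dfs(RegCtx &C, const Phase *ph, size_t idx, int c, const Phase *next) {
  if (idx == ph->ks.size()) {
    if (!next) return true;
    RegSave sv = reg_save(C);
    C.run = C.center_run;
    C.core_run = C.center_core_run;
    bool ok = reg_dfs(C, next, 0, next->c0, NULL);
    reg_restore(C, sv);
    return ok;
  }
  int k = ph->ks[idx];
  int ipos = C.abs0 + k;
  { // pair (or free column when the cursor is outside the 7-mer)
    RegSave sv = reg_save(C);
    bool ok;
    if (c >= 1 && c <= 7) ok = reg_apply(C, ipos, classify_pair(C.s[k], C.t[c]));
    else                  ok = reg_apply(C, ipos, 0);
    if (ok && reg_dfs(C, ph, idx + 1, c + ph->dc, next)) return true;
    reg_restore(C, sv);
  }
  if (C.n_gaps < C.r.max_gaps) { // consume a target base without pairing
    RegSave sv = reg_save(C);
    if (reg_apply(C, ipos, 3) && reg_dfs(C, ph, idx, c + ph->dc, next)) return true;
    reg_restore(C, sv);
  }
  if (C.n_gaps < C.r.max_gaps) { // bulge the sRNA base
    RegSave sv = reg_save(C);
    if (reg_apply(C, ipos, 4) && reg_dfs(C, ph, idx + 1, c, next)) return true;
    reg_restore(C, sv);
  }
  return false;
}

// region: 1, 2 or 3; scode/mcode: encoded 7-mers (sRNA / mRNA Table-1 codes)
static bool region_pair_valid_one(int region, int scode, int mcode, int srna_len,
                                  const Rules &rr) {
  RegCtx C;
  C.r = rr;
  for (int k = 1; k <= 7; ++k) {
    C.s[k] = (scode >> (2 * (7 - k))) & 3;       // sRNA 2-bit code == plain code
    C.t[k] = 3 - ((mcode >> (2 * (7 - k))) & 3); // mRNA 2-bit code is inverted
  }
  int g = rr.max_gaps;
  double off_mult = std::min(1.0, rr.core_mult);
  if (region == 2) {
    C.abs0 = 7;
    C.score = 0; C.n_mm = C.n_wob = C.n_gaps = C.core_mm = 0;
    C.run = C.core_run = C.center_run = C.center_core_run = 0;
    C.copen = C.ccopen = true;
    // anchor: region index 3 == sRNA position 10, never shifted
    if (!reg_apply(C, 10, classify_pair(C.s[3], C.t[3]))) return false;
    Phase a; a.ks.push_back(2); a.ks.push_back(1); a.c0 = 2; a.dc = -1;
    Phase b; b.ks.push_back(4); b.ks.push_back(5); b.ks.push_back(6); b.ks.push_back(7);
    b.c0 = 4; b.dc = +1;
    return reg_dfs(C, &a, 0, a.c0, &b);
  }
  // R1 / R3: gaps between the anchor and the region can shift its register
  for (int e = -g; e <= g; ++e) {
    C.score = std::abs(e) * rr.gap_score * off_mult;
    if (C.score > rr.max_score + 1e-9) continue;
    C.n_mm = C.n_wob = 0; C.n_gaps = std::abs(e);
    if (C.n_gaps > g) continue;
    C.core_mm = 0; C.run = C.core_run = C.center_run = C.center_core_run = 0;
    C.copen = C.ccopen = false;
    Phase p; p.dc = (region == 1) ? -1 : +1;
    if (region == 1) {
      C.abs0 = 0;
      for (int k = 7; k >= 1; --k) p.ks.push_back(k);
      p.c0 = 7 - e;
    } else {
      C.abs0 = srna_len - 7;
      for (int k = 1; k <= 7; ++k) p.ks.push_back(k);
      p.c0 = 1 + e;
    }
    if (reg_dfs(C, &p, 0, p.c0, NULL)) return true;
  }
  return false;
}

// [[Rcpp::export]]
bool region_pair_valid_cpp(int region, int scode, int mcode, int srna_len, List rules) {
  Rules r = parse_rules(rules);
  return region_pair_valid_one(region, scode, mcode, srna_len, r);
}

// One full row of the conceptual 16384 x 16384 valid-alignment matrix.
// [[Rcpp::export]]
LogicalVector region_row_cpp(int region, int scode, int srna_len, List rules) {
  Rules r = parse_rules(rules);
  LogicalVector out(16384);
  for (int m = 0; m < 16384; ++m)
    out[m] = region_pair_valid_one(region, scode, m, srna_len, r);
  return out;
}

// ---------------------------------------------------------------------------
// 2-bit encoding and the sorted-list binary-search transcript scan
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector encode_values_cpp(CharacterVector seqs, bool srna_mode) {
  int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (s.empty()) stop("cannot encode an empty sequence");
    double v = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      int c = bcode(s[j]);
      if (c < 0) stop("ambiguous base '%s' at position %d", std::string(1, s[j]), (int)j + 1);
      v = v * 4.0 + (srna_mode ? c : 3 - c);
    }
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector decode_values_cpp(NumericVector values, IntegerVector lengths,
                                  bool srna_mode) {
  int n = values.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    int len = lengths[i % lengths.size()];
    long long lim = 1; // 4^len, exact in int64 for len <= 26
    for (int j = 0; j < len; ++j) lim *= 4;
    long long v = (long long)values[i];
    if (values[i] < 0 || v >= lim) stop("encoded value out of range for length");
    std::string s(len, 'A');
    for (int j = len - 1; j >= 0; --j) {
      int c = (int)(v & 3);
      v >>= 2;
      s[j] = "ACGT"[srna_mode ? c : 3 - c];
    }
    out[i] = s;
  }
  return out;
}

// Slide a length-`len` window along `seq`, encode each window with the same
// 2-bit code used for the reads, and binary-search the sorted value list.
// Returns the 1-based window start positions and the matched list indices.
// [[Rcpp::export]]
List scan_transcript_cpp(std::string seq, NumericVector sorted_vals, int len) {
  int L = (int)seq.size();
  std::vector<int> pos_out, idx_out;
  if (L >= len && sorted_vals.size() > 0) {
    std::vector<int> code(L);
    for (int i = 0; i < L; ++i) code[i] = bcode(seq[i]);
    double p4 = 1.0;
    for (int i = 1; i < len; ++i) p4 *= 4.0;
    double v = 0;
    int bad = 0;
    for (int i = 0; i < len; ++i) {
      v = v * 4.0 + (code[i] < 0 ? 0 : code[i]);
      if (code[i] < 0) bad++;
    }
    const double *lo = sorted_vals.begin(), *hi = sorted_vals.end();
    for (int start = 0; ; ++start) {
      if (bad == 0) {
        const double *it = std::lower_bound(lo, hi, v);
        if (it != hi && *it == v) {
          pos_out.push_back(start + 1);
          idx_out.push_back((int)(it - lo) + 1);
        }
      }
      if (start + len >= L) break;
      int c_out = code[start], c_in = code[start + len];
      if (c_out < 0) bad--;
      v = (v - (c_out < 0 ? 0 : c_out) * p4) * 4.0 + (c_in < 0 ? 0 : c_in);
      if (c_in < 0) bad++;
    }
  }
  return List::create(_["pos"] = wrap(pos_out), _["idx"] = wrap(idx_out));
}
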