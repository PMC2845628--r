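#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Sequences are integer vectors with 1=A, 2=C, 3=G, 4=T, 0=unknown (N).
// Masked positions (logical mask TRUE, or code 0) are excluded from every
// window: a window overlapping any masked base is skipped entirely.

// ---------------------------------------------------------------------------
// PWM scanning: best log-odds site score per sequence, both strands.
// lom is a 4 x L matrix of log2-odds (rows A,C,G,T).
// Sequences with no fully unmasked window of length L get -Inf.
// [[Rcpp::export]]
NumericVector cpp_scan_best(List seqs, List masks, NumericMatrix lom) {
  const int L = lom.ncol();
  const int ns = seqs.size();
  NumericVector out(ns);
  std::vector<double> fwd(4 * L), rev(4 * L);
  for (int j = 0; j < L; ++j)
    for (int b = 0; b < 4; ++b) {
      fwd[j * 4 + b] = lom(b, j);
      rev[j * 4 + b] = lom(3 - b, L - 1 - j); // reverse complement strand
    }
  for (int s = 0; s < ns; ++s) {
    IntegerVector q = seqs[s];
    LogicalVector m = masks[s];
    const int n = q.size();
    double best = R_NegInf;
    for (int i = 0; i + L <= n; ++i) {
      bool ok = true;
      double sf = 0.0, sr = 0.0;
      for (int j = 0; j < L; ++j) {
        const int b = q[i + j];
        if (b < 1 || m[i + j]) { ok = false; break; }
        sf += fwd[j * 4 + b - 1];
        sr += rev[j * 4 + b - 1];
      }
      if (!ok) continue;
      const double sc = sf > sr ? sf : sr;
      if (sc > best) best = sc;
    }
    out[s] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Rank/copula kernel MI estimator.
// Copula transform u_i = midrank_i/(n+1); Gaussian product-kernel density for
// the joint and Gaussian kernels for the marginals; normal-reference
// bandwidths (d=2: h = sd*n^{-1/6}; d=1: h = 1.06*sd*n^{-1/5}).
// Midranks are stored doubled (integers), so kernel values over all possible
// rank differences are precomputed in a lookup table: no exp() in the O(n^2)
// accumulation loop.

struct ColInfo {
  std::vector<int> r2;          // doubled midranks in [2, 2n]
  std::vector<double> tabJ;     // joint-bandwidth kernel by doubled rank diff
  std::vector<double> logmarg;  // log marginal density at the sample points
  double hJ;
  bool constant;
};

static void rank2(const double* x, int n, std::vector<int>& r2) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return x[a] < x[b]; });
  r2.assign(n, 0);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    // midrank of the tie run [i, j] is (i+1 + j+1)/2; doubled -> i + j + 2
    const int dr = i + j + 2;
    for (int k = i; k <= j; ++k) r2[idx[k]] = dr;
    i = j + 1;
  }
}

static void make_colinfo(const double* x, int n, ColInfo& ci) {
  rank2(x, n, ci.r2);
  const double denom = 2.0 * (n + 1);
  double mu = 0.0, ss = 0.0;
  for (int i = 0; i < n; ++i) mu += ci.r2[i] / denom;
  mu /= n;
  for (int i = 0; i < n; ++i) {
    const double d = ci.r2[i] / denom - mu;
    ss += d * d;
  }
  const double sd = std::sqrt(ss / (n - 1));
  ci.constant = (sd <= 0.0);
  if (ci.constant) return;
  ci.hJ = sd * std::pow((double)n, -1.0 / 6.0);
  const double hM = 1.06 * sd * std::pow((double)n, -0.2);
  const int tmax = 2 * n;
  ci.tabJ.assign(tmax + 1, 0.0);
  std::vector<double> tabM(tmax + 1, 0.0);
  for (int d = 0; d <= tmax; ++d) {
    const double u = d / denom;
    const double tj = u / ci.hJ, tm = u / hM;
    ci.tabJ[d] = std::exp(-0.5 * tj * tj);
    tabM[d] = std::exp(-0.5 * tm * tm);
  }
  const double cM = 1.0 / (n * hM * std::sqrt(2.0 * M_PI));
  ci.logmarg.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double f = 0.0;
    for (int j = 0; j < n; ++j) f += tabM[std::abs(ci.r2[i] - ci.r2[j])];
    ci.logmarg[i] = std::log(cM * f);
  }
}

// X: samples x variables. pairs: 2-column 1-based variable indices.
// [[Rcpp::export]]
NumericVector cpp_mi_pairs(NumericMatrix X, IntegerMatrix pairs) {
  const int n = X.nrow();
  const int np = pairs.nrow();
  NumericVector out(np);
  std::unordered_map<int, int> slot;
  std::vector<ColInfo> cols;
  for (int p = 0; p < np; ++p)
    for (int k = 0; k < 2; ++k) {
      const int v = pairs(p, k);
      if (!slot.count(v)) {
        slot[v] = cols.size();
        cols.emplace_back();
        make_colinfo(&X(0, v - 1), n, cols.back());
      }
    }
  const double c2 = 1.0 / (2.0 * M_PI * n);
  for (int p = 0; p < np; ++p) {
    const ColInfo& a = cols[slot[pairs(p, 0)]];
    const ColInfo& b = cols[slot[pairs(p, 1)]];
    if (a.constant || b.constant) { out[p] = 0.0; continue; }
    const double cJ = c2 / (a.hJ * b.hJ);
    double mi = 0.0;
    for (int i = 0; i < n; ++i) {
      double f = 0.0;
      const int ra = a.r2[i], rb = b.r2[i];
      for (int j = 0; j < n; ++j)
        f += a.tabJ[std::abs(ra - a.r2[j])] * b.tabJ[std::abs(rb - b.r2[j])];
      mi += std::log(cJ * f) - a.logmarg[i] - b.logmarg[i];
    }
    mi /= n;
    out[p] = mi > 0.0 ? mi : 0.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Word counting over unmasked windows, both strands.
// Returns counts over the 4^L word codes (A=0,C=1,G=2,T=3, big-endian).
// [[Rcpp::export]]
IntegerVector cpp_count_words(List seqs, List masks, int L) {
  if (L < 1 || L > 12) stop("word length must be in [1, 12]");
  const size_t nw = ((size_t)1) << (2 * L);
  IntegerVector out((R_xlen_t)nw);
  const unsigned int cmask = (unsigned int)(nw - 1);
  const int shift = 2 * (L - 1);
  for (int s = 0; s < seqs.size(); ++s) {
    IntegerVector q = seqs[s];
    LogicalVector m = masks[s];
    const int n = q.size();
    unsigned int code = 0, rcode = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      const int b = q[i];
      if (b < 1 || m[i]) { run = 0; code = 0; rcode = 0; continue; }
      code = ((code << 2) | (unsigned int)(b - 1)) & cmask;
      rcode = (rcode >> 2) | ((unsigned int)(4 - b) << shift);
      if (++run >= L) {
        ++out[(R_xlen_t)code];
        ++out[(R_xlen_t)rcode];
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sparse-pattern scan: enumerate unique fully-unmasked 8-base seed words from
// the reference (species 1), then find, in every species, windows matching the
// seed (or its reverse complement) in >= min_match of wlen positions.
// Returns per-seed per-species occurrence counts and best match quality, plus
// the full occurrence table (seed, species, offset, nmatch, strand).
// [[Rcpp::export]]
List cpp_sparse_scan(List sp_seqs, List sp_masks, int wlen, int min_match) {
  const int nsp = sp_seqs.size();
  if (nsp < 1) stop("need at least the reference sequence");
  IntegerVector ref = sp_seqs[0];
  LogicalVector refmask = sp_masks[0];
  const int rn = ref.size();

  if (wlen > 16) stop("seed window length must be <= 16");
  const int refn = rn;
  const int* refp = INTEGER(ref);
  const int* refmp = LOGICAL(refmask);

  // collect unique seeds as packed 2-bit codes (fwd and rc)
  std::unordered_map<unsigned int, int> seed_id;
  std::vector<unsigned int> sF, sR;
  std::vector<int> seed_first_off;
  for (int i = 0; i + wlen <= refn; ++i) {
    bool ok = true;
    unsigned int code = 0, rcode = 0;
    for (int j = 0; j < wlen; ++j) {
      const int b = refp[i + j];
      if (b < 1 || refmp[i + j]) { ok = false; break; }
      code = (code << 2) | (unsigned int)(b - 1);
      rcode = (rcode >> 2) | ((unsigned int)(4 - b) << (2 * (wlen - 1)));
    }
    if (!ok) continue;
    if (!seed_id.count(code)) {
      seed_id[code] = sF.size();
      sF.push_back(code);
      sR.push_back(rcode);
      seed_first_off.push_back(i);
    }
  }
  const int nseed = sF.size();

  IntegerMatrix counts(nseed, nsp), bestq(nseed, nsp);
  std::vector<int> o_seed, o_sp, o_off, o_nm, o_str;
  const int maxmiss = wlen - min_match;
  const unsigned int lowbits = 0x55555555u >> (32 - 2 * wlen);

  for (int s = 0; s < nsp; ++s) {
    IntegerVector q = sp_seqs[s];
    LogicalVector m = sp_masks[s];
    const int n = q.size();
    const int* qp = INTEGER(q);
    const int* mp = LOGICAL(m);
    const unsigned int cmask =
      (wlen == 16) ? 0xFFFFFFFFu : ((1u << (2 * wlen)) - 1u);
    unsigned int wcode = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      const int b = qp[i];
      if (b < 1 || mp[i]) { run = 0; wcode = 0; continue; }
      wcode = ((wcode << 2) | (unsigned int)(b - 1)) & cmask;
      if (++run < wlen) continue;
      const int off = i - wlen + 1;
      for (int k = 0; k < nseed; ++k) {
        // mismatching base count via 2-bit XOR
        unsigned int uF = wcode ^ sF[k];
        unsigned int uR = wcode ^ sR[k];
        const int missF = __builtin_popcount((uF | (uF >> 1)) & lowbits);
        const int missR = __builtin_popcount((uR | (uR >> 1)) & lowbits);
        int nm, strand;
        if (missF <= maxmiss && missF <= missR) {
          nm = wlen - missF; strand = 1;
        } else if (missR <= maxmiss) {
          nm = wlen - missR; strand = -1;
        } else continue;
        ++counts(k, s);
        if (nm > bestq(k, s)) bestq(k, s) = nm;
        o_seed.push_back(k + 1); o_sp.push_back(s + 1);
        o_off.push_back(off); o_nm.push_back(nm); o_str.push_back(strand);
      }
    }
  }

  CharacterVector seedstr(nseed);
  const char* abc = "ACGT";
  for (int k = 0; k < nseed; ++k) {
    std::string w(wlen, 'N');
    for (int j = 0; j < wlen; ++j)
      w[j] = abc[(sF[k] >> (2 * (wlen - 1 - j))) & 3u];
    seedstr[k] = w;
  }
  return List::create(
    _["seed"] = seedstr,
    _["first_offset"] = wrap(seed_first_off),
    _["counts"] = counts,
    _["bestq"] = bestq,
    _["occ_seed"] = wrap(o_seed), _["occ_species"] = wrap(o_sp),
    _["occ_offset"] = wrap(o_off), _["occ_nmatch"] = wrap(o_nm),
    _["occ_strand"] = wrap(o_str));
}

// ---------------------------------------------------------------------------
// Minimum classification relative error over all attainable cutoffs.
// A sequence is positive iff score >= cutoff; err = (FPR + FNR)/2.
// Cutoffs considered: every attained finite score and +Inf (all-negative).
// Ties in err resolved toward the larger cutoff (fewer positives).
// [[Rcpp::export]]
List cpp_min_err(NumericVector scores, LogicalVector is_fg) {
  const int n = scores.size();
  int nf = 0, nb = 0;
  for (int i = 0; i < n; ++i) (is_fg[i] ? nf : nb)++;
  if (nf == 0 || nb == 0) stop("need non-empty foreground and background");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return scores[a] > scores[b]; });
  double best_err = 0.5; // +Inf cutoff: FPR=0, FNR=1
  double best_cut = R_PosInf;
  int tp = 0, fp = 0;
  int i = 0;
  while (i < n) {
    const double v = scores[idx[i]];
    if (v == R_NegInf) break; // -Inf is never an attainable positive cutoff
    int j = i;
    while (j < n && scores[idx[j]] == v) {
      if (is_fg[idx[j]]) ++tp; else ++fp;
      ++j;
    }
    const double err = ((double)fp / nb + (double)(nf - tp) / nf) / 2.0;
    if (err < best_err) { best_err = err; best_cut = v; }
    i = j;
  }
  return List::create(_["err"] = best_err, _["cutoff"] = best_cut);
}

// ---------------------------------------------------------------------------
// One steepest-descent refinement step over single-column replacements.
// Window scores for the current PWM are computed once; each candidate
// (column j, alphabet column k) is evaluated incrementally by adding the
// per-window delta of the changed column. Returns the best strictly
// err-improving change (ties resolved by column index then alphabet
// order), or j = 0 when the current matrix is locally optimal.
// [[Rcpp::export]]
List cpp_refine_step(List seqs, List masks, NumericMatrix cur,
                     NumericMatrix A, NumericVector bgc,
                     LogicalVector is_fg) {
  const int L = cur.ncol(), K = A.ncol();
  const int ns = seqs.size();
  int nf = 0, nb = 0;
  for (int s = 0; s < ns; ++s) (is_fg[s] ? nf : nb)++;
  std::vector<double> lom(4 * L);
  for (int j = 0; j < L; ++j)
    for (int b = 0; b < 4; ++b)
      lom[j * 4 + b] = std::log2(cur(b, j) / bgc[b]);
  // collect windows
  std::vector<double> wf, wr;
  std::vector<int> wseq;
  std::vector<std::vector<int> > wbase; // per window, base codes 0..3
  for (int s = 0; s < ns; ++s) {
    IntegerVector q = seqs[s];
    LogicalVector m = masks[s];
    const int n = q.size();
    const int* qp = INTEGER(q);
    const int* mp = LOGICAL(m);
    for (int i = 0; i + L <= n; ++i) {
      bool ok = true;
      double sf = 0.0, sr = 0.0;
      for (int j = 0; j < L; ++j) {
        const int b = qp[i + j];
        if (b < 1 || mp[i + j]) { ok = false; break; }
        sf += lom[j * 4 + b - 1];
        // reverse-complement strand: complemented base read from the
        // mirrored PWM column
        sr += lom[(L - 1 - j) * 4 + (4 - b)];
      }
      if (!ok) continue;
      wf.push_back(sf); wr.push_back(sr); wseq.push_back(s);
      std::vector<int> wb(L);
      for (int j = 0; j < L; ++j) wb[j] = qp[i + j] - 1;
      wbase.push_back(wb);
    }
  }
  const int nw = wf.size();
  // helper: minimised relative error over per-sequence best scores
  std::vector<double> best(ns);
  std::vector<int> ord(ns);
  auto min_err = [&](double* out_cut) {
    for (int s = 0; s < ns; ++s) ord[s] = s;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return best[a] > best[b];
    });
    double be = 0.5, bc = R_PosInf;
    int tp = 0, fp = 0, i = 0;
    while (i < ns) {
      const double v = best[ord[i]];
      if (v == R_NegInf) break;
      int j = i;
      while (j < ns && best[ord[j]] == v) {
        if (is_fg[ord[j]]) ++tp; else ++fp;
        ++j;
      }
      const double err = ((double)fp / nb + (double)(nf - tp) / nf) / 2.0;
      if (err < be) { be = err; bc = v; }
      i = j;
    }
    if (out_cut) *out_cut = bc;
    return be;
  };
  auto eval_delta = [&](int j, const double* dF) {
    for (int s = 0; s < ns; ++s) best[s] = R_NegInf;
    for (int w = 0; w < nw; ++w) {
      const int bF = wbase[w][j];
      const int bR = 3 - wbase[w][L - 1 - j];
      const double nf2 = wf[w] + dF[bF];
      const double nr2 = wr[w] + dF[bR];
      const double sc = nf2 > nr2 ? nf2 : nr2;
      if (sc > best[wseq[w]]) best[wseq[w]] = sc;
    }
  };
  // current err
  for (int s = 0; s < ns; ++s) best[s] = R_NegInf;
  for (int w = 0; w < nw; ++w) {
    const double sc = wf[w] > wr[w] ? wf[w] : wr[w];
    if (sc > best[wseq[w]]) best[wseq[w]] = sc;
  }
  double cur_cut;
  const double cur_err = min_err(&cur_cut);
  double best_err = cur_err, best_cut = cur_cut;
  int best_j = 0, best_k = 0;
  double dF[4];
  for (int j = 0; j < L; ++j) {
    for (int k = 0; k < K; ++k) {
      bool same = true;
      for (int b = 0; b < 4; ++b)
        if (std::abs(A(b, k) - cur(b, j)) > 1e-12) { same = false; break; }
      if (same) continue;
      for (int b = 0; b < 4; ++b)
        dF[b] = std::log2(A(b, k) / bgc[b]) - lom[j * 4 + b];
      eval_delta(j, dF);
      double cut;
      const double e = min_err(&cut);
      if (e < best_err - 1e-12) {
        best_err = e; best_cut = cut; best_j = j + 1; best_k = k + 1;
      }
    }
  }
  return List::create(_["j"] = best_j, _["k"] = best_k,
                      _["err"] = best_err, _["cutoff"] = best_cut,
                      _["current_err"] = cur_err,
                      _["current_cutoff"] = cur_cut);
}

// Min-err under many label permutations; scores fixed per motif.
// scoremat: n x M; labels: n x P logical (TRUE = foreground).
// Returns M x P matrix of minimized errs.
// [[Rcpp::export]]
NumericMatrix cpp_perm_min_err(NumericMatrix scoremat, LogicalMatrix labels) {
  const int n = scoremat.nrow(), M = scoremat.ncol(), P = labels.ncol();
  NumericMatrix out(M, P);
  // per-motif descending order and tie-run boundaries
  std::vector<std::vector<int> > orders(M);
  for (int m = 0; m < M; ++m) {
    orders[m].resize(n);
    for (int i = 0; i < n; ++i) orders[m][i] = i;
    std::sort(orders[m].begin(), orders[m].end(), [&](int a, int b) {
      return scoremat(a, m) > scoremat(b, m);
    });
  }
  for (int p = 0; p < P; ++p) {
    int nf = 0;
    for (int i = 0; i < n; ++i) if (labels(i, p)) ++nf;
    const int nb = n - nf;
    for (int m = 0; m < M; ++m) {
      const std::vector<int>& ord = orders[m];
      double best = 0.5;
      int tp = 0, fp = 0, i = 0;
      while (i < n) {
        const double v = scoremat(ord[i], m);
        if (v == R_NegInf) break;
        int j = i;
        while (j < n && scoremat(ord[j], m) == v) {
          if (labels(ord[j], p)) ++tp; else ++fp;
          ++j;
        }
        const double err = ((double)fp / nb + (double)(nf - tp) / nf) / 2.0;
        if (err < best) best = err;
        i = j;
      }
      out(m, p) = best;
    }
  }
  return out;
}
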