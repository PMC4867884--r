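// Dynamic programming on the counting-augmented HMM.
//
// Extended hidden state is (x, e, s): x the HMM state (0..M-1), e the
// excursion phase (0 or 1; a single dummy value for plain counting) and s the
// counter value (0..cap).  The counter is absorbing at `cap`: once s = cap no
// further increments happen, so entries s < cap carry exact counts and the
// mass at s = cap is the tail probability of counts exceeding cap - 1.
// All recursions run in the log domain; -Inf encodes zero probability.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logadd(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

// Deterministic auxiliary-chain step tables.
// variant: 0 = counting (standard/generalized via C), 1 = excursion,
//          2 = restricted excursion.
// etab[e_p + 2*(x_p + M*x)] = next e (-1 when the step is infeasible,
// i.e. the restricted-excursion phase variable would leave {0,1}).
// itab[...] = counter increment (0/1) for that step.
struct AuxTables {
  int M, E;
  std::vector<int> etab, itab;
  inline int e_next(int e_p, int x_p, int x) const {
    return etab[e_p + 2 * (x_p + M * x)];
  }
  inline int inc(int e_p, int x_p, int x) const {
    return itab[e_p + 2 * (x_p + M * x)];
  }
};

static AuxTables build_tables(int M, int variant, const IntegerMatrix& C,
                              const LogicalVector& is_null) {
  AuxTables t;
  t.M = M;
  t.E = (variant == 0) ? 1 : 2;
  t.etab.assign(2 * M * M, 0);
  t.itab.assign(2 * M * M, 0);
  for (int xp = 0; xp < M; ++xp) {
    for (int x = 0; x < M; ++x) {
      for (int ep = 0; ep < 2; ++ep) {
        int en, inc;
        if (variant == 0) {
          en = 0;
          inc = C(xp, x);
        } else {
          bool pn = is_null[xp], cn = is_null[x];
          if (pn && !cn) {            // null -> abnormal: excursion opens
            en = 1; inc = 0;
          } else if (!pn && cn) {     // abnormal -> null: excursion closes
            en = 0; inc = (ep == 1) ? 1 : 0;
          } else {                    // within null set or within abnormal set
            if (variant == 2 && ep == 1 && xp != x) {
              en = -1; inc = 0;       // switching abnormal state mid-excursion
            } else {
              en = ep; inc = 0;
            }
          }
        }
        t.etab[ep + 2 * (xp + M * x)] = en;
        t.itab[ep + 2 * (xp + M * x)] = inc;
      }
    }
  }
  return t;
}

static inline int idx3(int x, int e, int s, int M, int E) {
  return x + M * (e + E * s);
}

// Forward pass.  Returns the final message slice (M x E x S) and, when
// keep_all, the full alpha array (M x E x S x N).
// [[Rcpp::export]]
List kseg_forward_cpp(const NumericMatrix& logB, const NumericVector& lpi0,
                      const NumericMatrix& lA, const IntegerVector& s_init,
                      int variant, const IntegerMatrix& C,
                      const LogicalVector& is_null, int cap, bool keep_all) {
  const int N = logB.nrow(), M = logB.ncol();
  AuxTables t = build_tables(M, variant, C, is_null);
  const int E = t.E, S = cap + 1;
  const int K = M * E * S;
  int s1max = 0;
  for (int m = 0; m < M; ++m) if (s_init[m] > s1max) s1max = s_init[m];

  std::vector<double> cur(K, NEG_INF), nxt(K);
  NumericVector all;
  if (keep_all) all = NumericVector((R_xlen_t)K * N, NEG_INF);

  for (int x = 0; x < M; ++x) {
    int s0 = std::min(s_init[x], cap);
    double v = lpi0[x] + logB(0, x);
    if (v != NEG_INF) cur[idx3(x, 0, s0, M, E)] = v;
  }
  if (keep_all) for (int i = 0; i < K; ++i) all[i] = cur[i];

  for (int n = 1; n < N; ++n) {
    std::fill(nxt.begin(), nxt.end(), NEG_INF);
    int smax_prev = std::min(s1max + n - 1, cap);
    for (int sp = 0; sp <= smax_prev; ++sp) {
      for (int ep = 0; ep < E; ++ep) {
        for (int xp = 0; xp < M; ++xp) {
          double a = cur[idx3(xp, ep, sp, M, E)];
          if (a == NEG_INF) continue;
          for (int x = 0; x < M; ++x) {
            double la = lA(xp, x);
            if (la == NEG_INF) continue;
            int en = t.e_next(ep, xp, x);
            if (en < 0) continue;
            int sn = (sp >= cap) ? cap : sp + t.inc(ep, xp, x);
            double v = a + la + logB(n, x);
            int j = idx3(x, en, sn, M, E);
            nxt[j] = logadd(nxt[j], v);
          }
        }
      }
    }
    cur.swap(nxt);
    if (keep_all) {
      R_xlen_t off = (R_xlen_t)K * n;
      for (int i = 0; i < K; ++i) all[off + i] = cur[i];
    }
  }

  NumericVector last(K);
  for (int i = 0; i < K; ++i) last[i] = cur[i];
  last.attr("dim") = IntegerVector::create(M, E, S);
  List out = List::create(_["last"] = last, _["E"] = E);
  if (keep_all) {
    all.attr("dim") = IntegerVector::create(M, E, S, N);
    out["alpha"] = all;
  }
  return out;
}

// Backward pass with terminal constraint: beta_N(x,e,s) = 0 when allowed[s],
// -Inf otherwise.  Returns the full beta array (M x E x S x N).
// [[Rcpp::export]]
NumericVector kseg_backward_cpp(const NumericMatrix& logB,
                                const NumericMatrix& lA,
                                const IntegerVector& s_init, int variant,
                                const IntegerMatrix& C,
                                const LogicalVector& is_null, int cap,
                                const LogicalVector& allowed) {
  const int N = logB.nrow(), M = logB.ncol();
  AuxTables t = build_tables(M, variant, C, is_null);
  const int E = t.E, S = cap + 1;
  const int K = M * E * S;
  int s1max = 0;
  for (int m = 0; m < M; ++m) if (s_init[m] > s1max) s1max = s_init[m];

  NumericVector all((R_xlen_t)K * N, NEG_INF);
  std::vector<double> cur(K, NEG_INF), prv(K);
  for (int s = 0; s < S; ++s)
    if (allowed[s])
      for (int e = 0; e < E; ++e)
        for (int x = 0; x < M; ++x) cur[idx3(x, e, s, M, E)] = 0.0;
  {
    R_xlen_t off = (R_xlen_t)K * (N - 1);
    for (int i = 0; i < K; ++i) all[off + i] = cur[i];
  }

  for (int n = N - 1; n >= 1; --n) {
    std::fill(prv.begin(), prv.end(), NEG_INF);
    int smax_prev = std::min(s1max + n - 1, cap);
    for (int sp = 0; sp <= smax_prev; ++sp) {
      for (int ep = 0; ep < E; ++ep) {
        for (int xp = 0; xp < M; ++xp) {
          double acc = NEG_INF;
          for (int x = 0; x < M; ++x) {
            double la = lA(xp, x);
            if (la == NEG_INF) continue;
            int en = t.e_next(ep, xp, x);
            if (en < 0) continue;
            int sn = (sp >= cap) ? cap : sp + t.inc(ep, xp, x);
            double b = cur[idx3(x, en, sn, M, E)];
            if (b == NEG_INF) continue;
            acc = logadd(acc, la + logB(n, x) + b);
          }
          prv[idx3(xp, ep, sp, M, E)] = acc;
        }
      }
    }
    cur.swap(prv);
    R_xlen_t off = (R_xlen_t)K * (n - 1);
    for (int i = 0; i < K; ++i) all[off + i] = cur[i];
  }
  all.attr("dim") = IntegerVector::create(M, E, S, N);
  return all;
}

// Site marginals p(x_n | event, y) and pairwise marginals
// p(x_{n-1}, x_n | event, y) from full alpha/beta arrays.
// [[Rcpp::export]]
List kseg_marginals_cpp(const NumericMatrix& logB, const NumericMatrix& lA,
                        const NumericVector& alpha, const NumericVector& beta,
                        int variant, const IntegerMatrix& C,
                        const LogicalVector& is_null, int cap, double logZ) {
  const int N = logB.nrow(), M = logB.ncol();
  AuxTables t = build_tables(M, variant, C, is_null);
  const int E = t.E, S = cap + 1;
  const int K = M * E * S;

  NumericMatrix gamma(N, M);
  NumericVector pair((R_xlen_t)(N - 1) * M * M, 0.0);

  for (int n = 0; n < N; ++n) {
    R_xlen_t off = (R_xlen_t)K * n;
    for (int x = 0; x < M; ++x) {
      double acc = NEG_INF;
      for (int e = 0; e < E; ++e)
        for (int s = 0; s < S; ++s) {
          double a = alpha[off + idx3(x, e, s, M, E)];
          if (a == NEG_INF) continue;
          double b = beta[off + idx3(x, e, s, M, E)];
          if (b == NEG_INF) continue;
          acc = logadd(acc, a + b);
        }
      gamma(n, x) = (acc == NEG_INF) ? 0.0 : std::exp(acc - logZ);
    }
  }

  for (int n = 1; n < N; ++n) {
    R_xlen_t offp = (R_xlen_t)K * (n - 1), offc = (R_xlen_t)K * n;
    for (int xp = 0; xp < M; ++xp) {
      for (int x = 0; x < M; ++x) {
        double la = lA(xp, x);
        double acc = NEG_INF;
        if (la != NEG_INF) {
          for (int ep = 0; ep < E; ++ep) {
            int en = t.e_next(ep, xp, x);
            if (en < 0) continue;
            int inc = t.inc(ep, xp, x);
            for (int sp = 0; sp < S; ++sp) {
              double a = alpha[offp + idx3(xp, ep, sp, M, E)];
              if (a == NEG_INF) continue;
              int sn = (sp >= cap) ? cap : sp + inc;
              double b = beta[offc + idx3(x, en, sn, M, E)];
              if (b == NEG_INF) continue;
              acc = logadd(acc, a + la + logB(n, x) + b);
            }
          }
        }
        pair[(R_xlen_t)(n - 1) + (R_xlen_t)(N - 1) * (xp + M * x)] =
            (acc == NEG_INF) ? 0.0 : std::exp(acc - logZ);
      }
    }
  }
  pair.attr("dim") = IntegerVector::create(N - 1, M, M);
  return List::create(_["gamma"] = gamma, _["pair"] = pair);
}

// Constrained Viterbi: max-product recursion with backpointers, returning for
// every terminal counter value s the best path ending with s_N = s and its
// joint log score.  Ties are broken toward the lexicographically smallest
// (s, e, x) extended state, making the output deterministic.
// [[Rcpp::export]]
List kseg_viterbi_cpp(const NumericMatrix& logB, const NumericVector& lpi0,
                      const NumericMatrix& lA, const IntegerVector& s_init,
                      int variant, const IntegerMatrix& C,
                      const LogicalVector& is_null, int cap) {
  const int N = logB.nrow(), M = logB.ncol();
  AuxTables t = build_tables(M, variant, C, is_null);
  const int E = t.E, S = cap + 1;
  const int K = M * E * S;
  int s1max = 0;
  for (int m = 0; m < M; ++m) if (s_init[m] > s1max) s1max = s_init[m];

  std::vector<double> cur(K, NEG_INF), nxt(K);
  std::vector<int> bp((R_xlen_t)K * N, -1);

  for (int x = 0; x < M; ++x) {
    int s0 = std::min(s_init[x], cap);
    double v = lpi0[x] + logB(0, x);
    if (v != NEG_INF) cur[idx3(x, 0, s0, M, E)] = v;
  }

  for (int n = 1; n < N; ++n) {
    std::fill(nxt.begin(), nxt.end(), NEG_INF);
    R_xlen_t off = (R_xlen_t)K * n;
    int smax_prev = std::min(s1max + n - 1, cap);
    for (int sp = 0; sp <= smax_prev; ++sp) {
      for (int ep = 0; ep < E; ++ep) {
        for (int xp = 0; xp < M; ++xp) {
          int src = idx3(xp, ep, sp, M, E);
          double a = cur[src];
          if (a == NEG_INF) continue;
          for (int x = 0; x < M; ++x) {
            double la = lA(xp, x);
            if (la == NEG_INF) continue;
            int en = t.e_next(ep, xp, x);
            if (en < 0) continue;
            int sn = (sp >= cap) ? cap : sp + t.inc(ep, xp, x);
            double v = a + la + logB(n, x);
            int j = idx3(x, en, sn, M, E);
            if (v > nxt[j]) {  // strict: keeps smallest (s,e,x) source on ties
              nxt[j] = v;
              bp[off + j] = src;
            }
          }
        }
      }
    }
    cur.swap(nxt);
  }

  IntegerMatrix paths(S, N);
  NumericVector scores(S);
  std::fill(paths.begin(), paths.end(), NA_INTEGER);
  for (int s = 0; s < S; ++s) {
    double best = NEG_INF;
    int argj = -1;
    for (int e = 0; e < E; ++e)
      for (int x = 0; x < M; ++x) {
        int j = idx3(x, e, s, M, E);
        if (cur[j] > best) { best = cur[j]; argj = j; }
      }
    scores[s] = best;
    if (argj < 0) continue;
    int j = argj;
    for (int n = N - 1; n >= 0; --n) {
      paths(s, n) = (j % M) + 1;  // 1-based state
      if (n > 0) j = bp[(R_xlen_t)K * n + j];
    }
  }
  return List::create(_["paths"] = paths, _["scores"] = scores);
}

// Backward sampling on the augmented chain given the full alpha array.
// U is an n_samples x N matrix of uniforms; sample i consumes U(i, N-1) for
// position N, then U(i, n-1) for position n, i.e. draws are used in position
// order n = N..1.
// [[Rcpp::export]]
IntegerMatrix kseg_sample_cpp(const NumericVector& alpha,
                              const NumericMatrix& lA, int variant,
                              const IntegerMatrix& C,
                              const LogicalVector& is_null, int cap,
                              const LogicalVector& allowed,
                              const NumericMatrix& U) {
  IntegerVector dims = alpha.attr("dim");
  const int M = dims[0], E = dims[1], S = dims[2], N = dims[3];
  AuxTables t = build_tables(M, variant, C, is_null);
  const int K = M * E * S;
  const int nsamp = U.nrow();

  // terminal distribution over (x, e, s in allowed)
  R_xlen_t offN = (R_xlen_t)K * (N - 1);
  std::vector<int> term_idx;
  std::vector<double> term_w;
  double wmax = NEG_INF;
  for (int s = 0; s < S; ++s) {
    if (!allowed[s]) continue;
    for (int e = 0; e < E; ++e)
      for (int x = 0; x < M; ++x) {
        double a = alpha[offN + idx3(x, e, s, M, E)];
        if (a == NEG_INF) continue;
        term_idx.push_back(idx3(x, e, s, M, E));
        term_w.push_back(a);
        if (a > wmax) wmax = a;
      }
  }
  if (term_idx.empty()) stop("event has zero posterior probability");
  double tot = 0.0;
  for (size_t i = 0; i < term_w.size(); ++i) {
    term_w[i] = std::exp(term_w[i] - wmax);
    tot += term_w[i];
  }

  IntegerMatrix out(nsamp, N);
  std::vector<double> cw(M * E * 2);
  std::vector<int> cx(M * E * 2), ce(M * E * 2), cs(M * E * 2);

  for (int i = 0; i < nsamp; ++i) {
    // terminal
    double u = U(i, N - 1) * tot, acc = 0.0;
    int j = term_idx.back();
    for (size_t q = 0; q < term_w.size(); ++q) {
      acc += term_w[q];
      if (u <= acc) { j = term_idx[q]; break; }
    }
    int x = j % M, e = (j / M) % E, s = j / (M * E);
    out(i, N - 1) = x + 1;

    for (int n = N - 1; n >= 1; --n) {
      R_xlen_t offp = (R_xlen_t)K * (n - 1);
      int nc = 0;
      double mx = NEG_INF;
      for (int ep = 0; ep < E; ++ep) {
        for (int xp = 0; xp < M; ++xp) {
          double la = lA(xp, x);
          if (la == NEG_INF) continue;
          if (t.e_next(ep, xp, x) != e) continue;
          int inc = t.inc(ep, xp, x);
          if (s < cap) {
            int sp = s - inc;
            if (sp >= 0 && sp < cap) {
              double a = alpha[offp + idx3(xp, ep, sp, M, E)];
              if (a != NEG_INF) {
                cw[nc] = a + la; cx[nc] = xp; ce[nc] = ep; cs[nc] = sp;
                if (cw[nc] > mx) mx = cw[nc];
                ++nc;
              }
            }
          } else {  // s == cap: either already absorbed, or just incremented in
            double a = alpha[offp + idx3(xp, ep, cap, M, E)];
            if (a != NEG_INF) {
              cw[nc] = a + la; cx[nc] = xp; ce[nc] = ep; cs[nc] = cap;
              if (cw[nc] > mx) mx = cw[nc];
              ++nc;
            }
            if (inc == 1 && cap >= 1) {
              double a2 = alpha[offp + idx3(xp, ep, cap - 1, M, E)];
              if (a2 != NEG_INF) {
                cw[nc] = a2 + la; cx[nc] = xp; ce[nc] = ep; cs[nc] = cap - 1;
                if (cw[nc] > mx) mx = cw[nc];
                ++nc;
              }
            }
          }
        }
      }
      if (nc == 0) stop("internal error: no feasible predecessor in sampling");
      double ct = 0.0;
      for (int q = 0; q < nc; ++q) { cw[q] = std::exp(cw[q] - mx); ct += cw[q]; }
      double u2 = U(i, n - 1) * ct, a2 = 0.0;
      int pick = nc - 1;
      for (int q = 0; q < nc; ++q) {
        a2 += cw[q];
        if (u2 <= a2) { pick = q; break; }
      }
      x = cx[pick]; e = ce[pick]; s = cs[pick];
      out(i, n - 1) = x + 1;
    }
  }
  return out;
}
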