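// Linear-chain CRF internals: penalized negative log-likelihood with exact
// forward-backward gradients, and Viterbi decoding. Documents arrive in CSR
// form: per-token unigram feature ids (each id owns a block of L weights) and
// per-token bigram feature ids (each id owns a block of L*L weights applying
// to the transition into that token; position 0 has no incoming transition).
//
// The forward-backward pass runs in the linear domain with per-step
// normalization. Because a token's transition matrix is the sum of a handful
// of feature blocks, exp() of every bigram block is cached once per
// evaluation (shifted by the block maximum for stability) and each token's
// matrix is an elementwise product of cached blocks — far cheaper than
// exponentiating T transition matrices.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct DocView {
  const int *uptr, *uidx, *bptr, *bidx, *y;
  int T;
};

static DocView view(List doc) {
  DocView v;
  IntegerVector uptr = doc["uptr"], uidx = doc["uidx"],
                bptr = doc["bptr"], bidx = doc["bidx"], y = doc["y"];
  v.uptr = INTEGER(uptr); v.uidx = INTEGER(uidx);
  v.bptr = INTEGER(bptr); v.bidx = INTEGER(bidx); v.y = INTEGER(y);
  v.T = y.size();
  return v;
}

static void raw_psi(const DocView& v, const double* W, int L,
                    std::vector<double>& psi) {
  const int T = v.T;
  psi.assign((size_t)T * L, 0.0);
  for (int t = 0; t < T; ++t) {
    double* p = &psi[(size_t)t * L];
    for (int j = v.uptr[t]; j < v.uptr[t + 1]; ++j) {
      const double* blk = W + (long)v.uidx[j] * L;
      for (int l = 0; l < L; ++l) p[l] += blk[l];
    }
  }
}

// [[Rcpp::export(name = ".crf_nll_grad")]]
List crf_nll_grad(List docs, NumericVector w, int L, int n_uni, double lambda,
                  bool want_grad) {
  const double* W = REAL(w);
  const long nw = w.size();
  const long bi_base = (long)n_uni * L;
  const int LL = L * L;
  const long n_bi = (nw - bi_base) / LL;

  // cache exp(block - max(block)) for every bigram feature block
  std::vector<double> expB((size_t)n_bi * LL);
  std::vector<double> maxB(n_bi, 0.0);
  for (long k = 0; k < n_bi; ++k) {
    const double* blk = W + bi_base + k * LL;
    double m = blk[0];
    for (int j = 1; j < LL; ++j) if (blk[j] > m) m = blk[j];
    maxB[k] = m;
    double* e = &expB[(size_t)k * LL];
    for (int j = 0; j < LL; ++j) e[j] = std::exp(blk[j] - m);
  }

  std::vector<double> grad;
  if (want_grad) grad.assign(nw, 0.0);
  double nll = 0.0;
  std::vector<double> psi, ePsi, M, a, b, tmp(L), q((size_t)LL);

  for (int d = 0; d < docs.size(); ++d) {
    DocView v = view(docs[d]);
    const int T = v.T;
    if (T == 0) continue;
    raw_psi(v, W, L, psi);

    // shifted emission exponentials
    ePsi.assign((size_t)T * L, 0.0);
    double logZ = 0.0;
    for (int t = 0; t < T; ++t) {
      const double* p = &psi[(size_t)t * L];
      double m = p[0];
      for (int l = 1; l < L; ++l) if (p[l] > m) m = p[l];
      double* e = &ePsi[(size_t)t * L];
      for (int l = 0; l < L; ++l) e[l] = std::exp(p[l] - m);
      logZ += m;  // emission shift enters Z once per position
    }

    // per-token transition matrices as products of cached blocks
    M.assign(T > 1 ? (size_t)(T - 1) * LL : 0, 0.0);
    for (int t = 1; t < T; ++t) {
      double* Mt = &M[(size_t)(t - 1) * LL];
      bool first = true;
      for (int j = v.bptr[t]; j < v.bptr[t + 1]; ++j) {
        const double* e = &expB[(size_t)v.bidx[j] * LL];
        if (first) { for (int k = 0; k < LL; ++k) Mt[k] = e[k]; first = false; }
        else       { for (int k = 0; k < LL; ++k) Mt[k] *= e[k]; }
        logZ += maxB[v.bidx[j]];
      }
      if (first) for (int k = 0; k < LL; ++k) Mt[k] = 1.0;
    }

    // scaled forward pass
    a.assign((size_t)T * L, 0.0);
    {
      double s = 0.0;
      for (int l = 0; l < L; ++l) { a[l] = ePsi[l]; s += a[l]; }
      if (s <= 0.0) { for (int l = 0; l < L; ++l) a[l] = 1.0 / L; s = 1.0; }
      for (int l = 0; l < L; ++l) a[l] /= s;
      logZ += std::log(s);
    }
    for (int t = 1; t < T; ++t) {
      const double* Mt = &M[(size_t)(t - 1) * LL];
      const double* ap = &a[(size_t)(t - 1) * L];
      const double* e = &ePsi[(size_t)t * L];
      double* ac = &a[(size_t)t * L];
      for (int l = 0; l < L; ++l) tmp[l] = 0.0;
      for (int k = 0; k < L; ++k) {
        const double ak = ap[k];
        if (ak == 0.0) continue;
        const double* row = Mt + (size_t)k * L;
        for (int l = 0; l < L; ++l) tmp[l] += ak * row[l];
      }
      double s = 0.0;
      for (int l = 0; l < L; ++l) { ac[l] = tmp[l] * e[l]; s += ac[l]; }
      if (s <= 0.0) { for (int l = 0; l < L; ++l) ac[l] = 1.0 / L; s = 1.0; }
      else for (int l = 0; l < L; ++l) ac[l] /= s;
      logZ += std::log(s);
    }

    // gold path score from raw parameters
    double gold = 0.0;
    for (int t = 0; t < T; ++t) gold += psi[(size_t)t * L + v.y[t]];
    for (int t = 1; t < T; ++t)
      for (int j = v.bptr[t]; j < v.bptr[t + 1]; ++j)
        gold += W[bi_base + (long)v.bidx[j] * LL + (long)v.y[t - 1] * L + v.y[t]];
    nll += logZ - gold;
    if (!want_grad) continue;

    // scaled backward pass
    b.assign((size_t)T * L, 0.0);
    for (int l = 0; l < L; ++l) b[(size_t)(T - 1) * L + l] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      const double* Mt = &M[(size_t)t * LL];  // transition t -> t+1
      const double* bn = &b[(size_t)(t + 1) * L];
      const double* e = &ePsi[(size_t)(t + 1) * L];
      double* bc = &b[(size_t)t * L];
      for (int l = 0; l < L; ++l) tmp[l] = e[l] * bn[l];
      double s = 0.0;
      for (int k = 0; k < L; ++k) {
        const double* row = Mt + (size_t)k * L;
        double acc = 0.0;
        for (int l = 0; l < L; ++l) acc += row[l] * tmp[l];
        bc[k] = acc; s += acc;
      }
      if (s <= 0.0) for (int k = 0; k < L; ++k) bc[k] = 1.0 / L;
      else for (int k = 0; k < L; ++k) bc[k] /= s;
    }

    // unigram marginals (normalized per token)
    for (int t = 0; t < T; ++t) {
      const double* ac = &a[(size_t)t * L];
      const double* bc = &b[(size_t)t * L];
      double s = 0.0;
      for (int l = 0; l < L; ++l) { tmp[l] = ac[l] * bc[l]; s += tmp[l]; }
      if (s > 0.0) for (int l = 0; l < L; ++l) tmp[l] /= s;
      for (int j = v.uptr[t]; j < v.uptr[t + 1]; ++j) {
        double* g = grad.data() + (long)v.uidx[j] * L;
        for (int l = 0; l < L; ++l) g[l] += tmp[l];
        g[v.y[t]] -= 1.0;
      }
    }
    // pairwise marginals (normalized per transition)
    for (int t = 1; t < T; ++t) {
      if (v.bptr[t] == v.bptr[t + 1]) continue;
      const double* Mt = &M[(size_t)(t - 1) * LL];
      const double* ap = &a[(size_t)(t - 1) * L];
      const double* bc = &b[(size_t)t * L];
      const double* e = &ePsi[(size_t)t * L];
      double s = 0.0;
      for (int k = 0; k < L; ++k) {
        const double ak = ap[k];
        const double* row = Mt + (size_t)k * L;
        double* qr = &q[(size_t)k * L];
        for (int l = 0; l < L; ++l) { qr[l] = ak * row[l] * e[l] * bc[l]; s += qr[l]; }
      }
      if (s > 0.0) { const double inv = 1.0 / s; for (int k = 0; k < LL; ++k) q[k] *= inv; }
      for (int j = v.bptr[t]; j < v.bptr[t + 1]; ++j) {
        double* g = grad.data() + bi_base + (long)v.bidx[j] * LL;
        for (int k = 0; k < LL; ++k) g[k] += q[k];
        g[(long)v.y[t - 1] * L + v.y[t]] -= 1.0;
      }
    }
  }

  double pen = 0.0;
  for (long i = 0; i < nw; ++i) pen += W[i] * W[i];
  nll += 0.5 * lambda * pen;
  if (!want_grad) return List::create(_["nll"] = nll);
  for (long i = 0; i < nw; ++i) grad[i] += lambda * W[i];
  return List::create(_["nll"] = nll,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// [[Rcpp::export(name = ".crf_viterbi")]]
IntegerVector crf_viterbi(List doc, NumericVector w, int L, int n_uni) {
  DocView v = view(doc);
  const int T = v.T, LL = L * L;
  if (T == 0) return IntegerVector(0);
  const double* W = REAL(w);
  const long bi_base = (long)n_uni * L;
  std::vector<double> psi;
  raw_psi(v, W, L, psi);
  std::vector<double> phi(T > 1 ? (size_t)(T - 1) * LL : 0, 0.0);
  for (int t = 1; t < T; ++t) {
    double* ph = &phi[(size_t)(t - 1) * LL];
    for (int j = v.bptr[t]; j < v.bptr[t + 1]; ++j) {
      const double* blk = W + bi_base + (long)v.bidx[j] * LL;
      for (int k = 0; k < LL; ++k) ph[k] += blk[k];
    }
  }
  std::vector<double> delta((size_t)T * L);
  std::vector<int> back((size_t)T * L, 0);
  for (int l = 0; l < L; ++l) delta[l] = psi[l];
  for (int t = 1; t < T; ++t) {
    const double* ph = &phi[(size_t)(t - 1) * LL];
    const double* dp = &delta[(size_t)(t - 1) * L];
    double* dc = &delta[(size_t)t * L];
    int* bc = &back[(size_t)t * L];
    for (int l = 0; l < L; ++l) {
      double best = dp[0] + ph[l];
      int arg = 0;
      for (int k = 1; k < L; ++k) {
        const double s = dp[k] + ph[(size_t)k * L + l];
        if (s > best) { best = s; arg = k; }
      }
      dc[l] = best + psi[(size_t)t * L + l];
      bc[l] = arg;
    }
  }
  IntegerVector out(T);
  int arg = 0;
  const double* dl = &delta[(size_t)(T - 1) * L];
  for (int l = 1; l < L; ++l) if (dl[l] > dl[arg]) arg = l;
  out[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) {
    arg = back[(size_t)t * L + arg];
    out[t - 1] = arg;
  }
  return out;
}
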