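// Batched multi-head self-attention, forward and backward.
//
// Matrices arrive sample-major: row (b-1)*T + t holds sample b, position t.
// Per-sample, per-head blocks are copied into small contiguous buffers
// (dh x T, positions as columns) so all inner products run down unit-stride
// memory. Attention probabilities are cached C++-side and handed back as an
// external pointer, avoiding any copy across the R/C++ boundary between the
// forward and backward passes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void load_block(const arma::mat &M, arma::mat &buf,
                              int r0, int c0, int T, int dh) {
  // buf is dh x T
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < dh; ++k)
      buf(k, t) = M(r0 + t, c0 + k);
}

static inline void store_block(arma::mat &M, const arma::mat &buf,
                               int r0, int c0, int T, int dh) {
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < dh; ++k)
      M(r0 + t, c0 + k) = buf(k, t);
}

// [[Rcpp::export(name = ".attn_fwd_cpp")]]
List attn_fwd_cpp(const arma::mat &Q, const arma::mat &K, const arma::mat &V,
                  int B, int T, int H, bool causal,
                  const arma::imat &mask_keys, bool has_mask,
                  bool keep_cache) {
  const int d = Q.n_cols;
  const int dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat O(B * T, d);
  arma::cube *cache = keep_cache ? new arma::cube(T, T, (size_t)B * H) : nullptr;
  arma::mat Qb(dh, T), Kb(dh, T), Vb(dh, T), S(T, T), Ob(dh, T);
  const double NEG = -1e30;
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T;
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dh;
      load_block(Q, Qb, r0, c0, T, dh);
      load_block(K, Kb, r0, c0, T, dh);
      load_block(V, Vb, r0, c0, T, dh);
      // S = Qb^T Kb * scale  (query position t as row)
      S = Qb.t() * Kb * scale;
      if (causal) {
        for (int t2 = 1; t2 < T; ++t2)
          for (int t = 0; t < t2; ++t) S(t, t2) = NEG;
      } else if (has_mask) {
        for (int t2 = 0; t2 < T; ++t2)
          if (mask_keys(b, t2) == 0)
            for (int t = 0; t < T; ++t) S(t, t2) = NEG;
      }
      // row softmax in place
      for (int t = 0; t < T; ++t) {
        double m = S(t, 0);
        for (int t2 = 1; t2 < T; ++t2) if (S(t, t2) > m) m = S(t, t2);
        double z = 0.0;
        for (int t2 = 0; t2 < T; ++t2) { double e = std::exp(S(t, t2) - m); S(t, t2) = e; z += e; }
        const double inv = 1.0 / z;
        for (int t2 = 0; t2 < T; ++t2) S(t, t2) *= inv;
      }
      // Ob(k, t) = sum_t2 S(t, t2) Vb(k, t2)
      Ob = Vb * S.t();
      store_block(O, Ob, r0, c0, T, dh);
      if (keep_cache) cache->slice((size_t)b * H + h) = S;
    }
  }
  List out = List::create(Named("O") = O);
  if (keep_cache) {
    XPtr<arma::cube> ptr(cache, true);
    out["cache"] = ptr;
  }
  return out;
}

// [[Rcpp::export(name = ".attn_bwd_cpp")]]
List attn_bwd_cpp(const arma::mat &dO, SEXP cache_ptr,
                  const arma::mat &Q, const arma::mat &K, const arma::mat &V,
                  int B, int T, int H) {
  XPtr<arma::cube> cache(cache_ptr);
  const int d = Q.n_cols;
  const int dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat dQ(B * T, d), dK(B * T, d), dV(B * T, d);
  arma::mat Qb(dh, T), Kb(dh, T), Vb(dh, T), dOb(dh, T);
  arma::mat dP(T, T), dS(T, T), dQb(dh, T), dKb(dh, T), dVb(dh, T);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T;
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dh;
      load_block(Q, Qb, r0, c0, T, dh);
      load_block(K, Kb, r0, c0, T, dh);
      load_block(V, Vb, r0, c0, T, dh);
      load_block(dO, dOb, r0, c0, T, dh);
      const arma::mat &P = cache->slice((size_t)b * H + h);
      // dP = dOb^T Vb
      dP = dOb.t() * Vb;
      // dS = P % (dP - rowsum(dP % P)) * scale
      for (int t = 0; t < T; ++t) {
        double rs = 0.0;
        for (int t2 = 0; t2 < T; ++t2) rs += dP(t, t2) * P(t, t2);
        for (int t2 = 0; t2 < T; ++t2)
          dS(t, t2) = P(t, t2) * (dP(t, t2) - rs) * scale;
      }
      dVb = dOb * P;        // dV_t2 = sum_t P(t,t2) dO_t
      dKb = Qb * dS;        // dK_t2 = sum_t dS(t,t2) Q_t
      dQb = Kb * dS.t();    // dQ_t  = sum_t2 dS(t,t2) K_t2
      store_block(dQ, dQb, r0, c0, T, dh);
      store_block(dK, dKb, r0, c0, T, dh);
      store_block(dV, dVb, r0, c0, T, dh);
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}
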