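// Subvolume fitting core: minimizes
//   mean((A v - p)^2) + lambda * R(v),   v = G_theta(C)
// where G_theta is a sine-activation MLP over positionally encoded
// coordinates and A the sparse per-slice projection operator.
// Gradients are hand-derived and the whole loop runs in float32 (the
// precision coordinate networks are normally trained at); weights are
// exchanged with R as doubles.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

static inline void sincos_mat(const fmat& Z, fmat& S, fmat& C) {
  const float* zp = Z.memptr();
  float* sp = S.memptr();
  float* cp = C.memptr();
  const uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i) {
#if defined(__GLIBC__)
    sincosf(zp[i], &sp[i], &cp[i]);
#else
    sp[i] = std::sin(zp[i]);
    cp[i] = std::cos(zp[i]);
#endif
  }
}

// smoothed anisotropic total variation on the subvolume held as an
// (x*z) x k slice matrix; y-differences only when slices are the full
// consecutive set.  Returns mean-per-edge TV; accumulates d(TV)/dv into g.
static double tv_value_grad(const fmat& O, int x, int z, int k,
                            bool y_coupled, fmat& g) {
  const float eps = 1e-6f;
  double e = 0.0;
  long nterm = 0;
  for (int s = 0; s < k; ++s) {
    const float* o = O.colptr(s);
    float* gs = g.colptr(s);
    for (int iz = 0; iz < z; ++iz) {
      const int base = x * iz;
      for (int ix = 0; ix + 1 < x; ++ix) {       // x-differences
        float d = o[base + ix + 1] - o[base + ix];
        float r = std::sqrt(d * d + eps);
        e += r; ++nterm;
        float gd = d / r;
        gs[base + ix + 1] += gd;
        gs[base + ix] -= gd;
      }
    }
    for (int iz = 0; iz + 1 < z; ++iz) {         // z-differences
      const int b0 = x * iz, b1 = x * (iz + 1);
      for (int ix = 0; ix < x; ++ix) {
        float d = o[b1 + ix] - o[b0 + ix];
        float r = std::sqrt(d * d + eps);
        e += r; ++nterm;
        float gd = d / r;
        gs[b1 + ix] += gd;
        gs[b0 + ix] -= gd;
      }
    }
  }
  if (y_coupled) {
    for (int s = 0; s + 1 < k; ++s) {            // y-differences
      const float* o0 = O.colptr(s);
      const float* o1 = O.colptr(s + 1);
      float* g0 = g.colptr(s);
      float* g1 = g.colptr(s + 1);
      for (int c = 0; c < x * z; ++c) {
        float d = o1[c] - o0[c];
        float r = std::sqrt(d * d + eps);
        e += r; ++nterm;
        float gd = d / r;
        g1[c] += gd;
        g0[c] -= gd;
      }
    }
  }
  if (nterm == 0) return 0.0;
  // mean-per-edge normalization keeps lambda scale-free; fold 1/nterm
  // into the gradient as well
  g *= (1.0f / (float)nterm);
  return e / (double)nterm;
}

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<frowvec> mb, vb;
  float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  Adam(float beta1, float beta2) : b1(beta1), b2(beta2) {}
  long t = 0;
  void init(const std::vector<fmat>& W, const std::vector<frowvec>& b) {
    for (size_t i = 0; i < W.size(); ++i) {
      mW.push_back(zeros<fmat>(W[i].n_rows, W[i].n_cols));
      vW.push_back(zeros<fmat>(W[i].n_rows, W[i].n_cols));
      mb.push_back(zeros<frowvec>(b[i].n_elem));
      vb.push_back(zeros<frowvec>(b[i].n_elem));
    }
  }
  void step(std::vector<fmat>& W, std::vector<frowvec>& b,
            const std::vector<fmat>& gW, const std::vector<frowvec>& gb,
            float lr) {
    ++t;
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < W.size(); ++i) {
      mW[i] = b1 * mW[i] + (1.0f - b1) * gW[i];
      vW[i] = b2 * vW[i] + (1.0f - b2) * square(gW[i]);
      W[i] -= lr * (mW[i] / c1) / (sqrt(vW[i] / c2) + eps);
      mb[i] = b1 * mb[i] + (1.0f - b1) * gb[i];
      vb[i] = b2 * vb[i] + (1.0f - b2) * square(gb[i]);
      b[i] -= lr * (mb[i] / c1) / (sqrt(vb[i] / c2) + eps);
    }
  }
};

// [[Rcpp::export(name = ".fit_core")]]
Rcpp::List fit_core(Rcpp::List W0, Rcpp::List b0, const arma::mat& enc,
                    int x, int j, int z,
                    const Rcpp::IntegerVector& Ap,
                    const Rcpp::IntegerVector& Ai,
                    const Rcpp::NumericVector& Ax, int n_pix,
                    const arma::mat& target, int iterations,
                    double lr_start, double lr_end, double omega0,
                    double lambda, bool use_tv, int batch_slices, int seed,
                    double adam_beta1, double adam_beta2) {
  const int n_xz = x * z;
  const long n = (long)n_xz * j;
  if ((long)enc.n_rows != n)
    Rcpp::stop("encoded coordinate count does not match subvolume dims");
  if ((int)target.n_rows != n_pix || (int)target.n_cols != j)
    Rcpp::stop("target projection shape does not match projector/plan");

  const int L = W0.size();          // hidden layers + output layer
  const int H = L - 1;
  std::vector<fmat> W(L);
  std::vector<frowvec> b(L);
  for (int i = 0; i < L; ++i) {
    W[i] = conv_to<fmat>::from(Rcpp::as<arma::mat>(W0[i]));
    b[i] = conv_to<frowvec>::from(Rcpp::as<arma::rowvec>(b0[i]));
  }
  const float w0f = (float)omega0;

  // encoded coordinates reordered slice-major: for each y-slice s, the
  // n_xz rows ordered (ix fastest, then iz).  Grid order is
  // idx = ix + x*(s + j*iz).
  fmat encSM((uword)n, enc.n_cols);
  {
    fmat encF = conv_to<fmat>::from(enc);
    for (int s = 0; s < j; ++s) {
      for (int iz = 0; iz < z; ++iz) {
        for (int ix = 0; ix < x; ++ix) {
          encSM.row((uword)s * n_xz + (uword)iz * x + ix) =
            encF.row((uword)ix + (uword)x * (s + (uword)j * iz));
        }
      }
    }
  }
  fmat Tt = conv_to<fmat>::from(target.t());     // j x n_pix
  std::vector<float> Axf(Ax.begin(), Ax.end());

  // The projector is only ~70% sparse at subvolume scale, so a dense
  // float copy turns both its application and its adjoint into sgemm
  // calls; fall back to sparse scatter loops when the dense operator
  // would be too large.
  const bool dense_ok = (double)n_pix * n_xz <= 3e8;
  fmat Ad;
  if (dense_ok) {
    Ad.zeros(n_pix, n_xz);
    for (int c = 0; c < n_xz; ++c) {
      for (int p = Ap[c]; p < Ap[c + 1]; ++p) Ad(Ai[p], c) = Axf[p];
    }
  }

  Adam opt((float)adam_beta1, (float)adam_beta2);
  opt.init(W, b);

  const bool batching = batch_slices > 0 && batch_slices < j;
  std::vector<int> order(j);
  for (int s = 0; s < j; ++s) order[s] = s;
  std::mt19937 rng((unsigned)seed);

  Rcpp::NumericVector loss_trace(iterations);
  std::vector<fmat> A_act(H + 1), Zc(H);
  std::vector<fmat> gW(L);
  std::vector<frowvec> gb(L);

  for (int it = 0; it < iterations; ++it) {
    // --- pick slice batch -------------------------------------------
    int k = j;
    std::vector<int> sel;
    if (batching) {
      std::shuffle(order.begin(), order.end(), rng);
      k = batch_slices;
      sel.assign(order.begin(), order.begin() + k);
      std::sort(sel.begin(), sel.end());
    }
    const uword nS = (uword)n_xz * k;

    // --- forward through the MLP ------------------------------------
    if (batching) {
      fmat encS(nS, encSM.n_cols);
      for (int si = 0; si < k; ++si) {
        encS.rows((uword)si * n_xz, (uword)(si + 1) * n_xz - 1) =
          encSM.rows((uword)sel[si] * n_xz, (uword)(sel[si] + 1) * n_xz - 1);
      }
      A_act[0] = std::move(encS);
    } else {
      A_act[0] = encSM;            // shallow copy-on-write would be nicer;
    }                              // arma copies, but only in batch=all once
    for (int i = 0; i < H; ++i) {
      fmat Zi = A_act[i] * W[i];
      Zi.each_row() += b[i];
      Zi *= w0f;
      fmat Si(Zi.n_rows, Zi.n_cols), Ci(Zi.n_rows, Zi.n_cols);
      sincos_mat(Zi, Si, Ci);
      A_act[i + 1] = std::move(Si);
      Zc[i] = std::move(Ci);       // cos, reused in the backward pass
    }
    fvec out = A_act[H] * W[H] + b[H](0);

    // --- data term and its gradient wrt the subvolume ---------------
    fmat O(out.memptr(), n_xz, k, false, true);  // view: (x*z) x k
    fmat Pt;                                     // k x n_pix residual
    if (dense_ok) {
      Pt = (Ad * O).t();
    } else {
      fmat Vt = O.t();
      Pt.zeros(k, n_pix);
      for (int c = 0; c < n_xz; ++c) {
        for (int p = Ap[c]; p < Ap[c + 1]; ++p) {
          Pt.col(Ai[p]) += Axf[p] * Vt.col(c);
        }
      }
    }
    if (batching) {
      for (int si = 0; si < k; ++si) Pt.row(si) -= Tt.row(sel[si]);
    } else {
      Pt -= Tt;
    }
    const double npix_tot = (double)n_pix * k;
    double loss = accu(conv_to<mat>::from(square(Pt))) / npix_tot;
    Pt *= (float)(2.0 / npix_tot);
    fmat dO;                                     // (x*z) x k
    if (dense_ok) {
      dO = Ad.t() * Pt.t();
    } else {
      fmat Gt(k, n_xz, fill::zeros);
      for (int c = 0; c < n_xz; ++c) {
        for (int p = Ap[c]; p < Ap[c + 1]; ++p) {
          Gt.col(c) += Axf[p] * Pt.col(Ai[p]);
        }
      }
      dO = Gt.t();
    }

    if (lambda > 0 && use_tv) {
      fmat gtv(n_xz, k, fill::zeros);
      double tv = tv_value_grad(O, x, z, k, !batching, gtv);
      loss += lambda * tv;
      dO += (float)lambda * gtv;
    }
    if (!std::isfinite(loss)) {
      Rcpp::stop("non-finite loss at iteration %d", it + 1);
    }
    loss_trace[it] = loss;

    // --- backward through the MLP -----------------------------------
    fvec dout(dO.memptr(), nS, false, true);
    gW[H] = A_act[H].t() * dout;
    gb[H] = frowvec(1);
    gb[H](0) = accu(dout);
    fmat G = dout * W[H].t();
    for (int i = H - 1; i >= 0; --i) {
      G %= Zc[i];
      G *= w0f;
      gW[i] = A_act[i].t() * G;
      gb[i] = sum(G, 0);
      if (i > 0) G = G * W[i].t();
    }

    // --- Adam with log-decayed learning rate ------------------------
    double frac = iterations < 2 ? 0.0 : (double)it / (iterations - 1);
    float lr = (float)(lr_start * std::pow(lr_end / lr_start, frac));
    opt.step(W, b, gW, gb, lr);
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List Wout(L), bout(L);
  for (int i = 0; i < L; ++i) {
    Wout[i] = Rcpp::wrap(conv_to<mat>::from(W[i]));
    bout[i] = Rcpp::wrap(conv_to<rowvec>::from(b[i]));
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = Wout, Rcpp::Named("b") = bout,
    Rcpp::Named("loss") = loss_trace
  );
}
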