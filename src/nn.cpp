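// Primitives for the dilated 1D convolutional network: same-padded dilated
// convolution, width-w max pooling, batch normalization and ReLU, each with
// forward and backward passes. Tensors are R arrays of dim (L, C, B):
// positions x channels x batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// Convolutions run in single precision: weights and activations are well
// inside float range and the ~1e-7 relative rounding is negligible next to
// SGD noise, while sgemm doubles the arithmetic throughput.

// Stack a (L, C, B) cube into a (L*B, C) float matrix (slices as row
// blocks).
static fmat stack_rows(const cube& X) {
  const uword L = X.n_rows, C = X.n_cols, B = X.n_slices;
  fmat X2(L * B, C);
  for (uword s = 0; s < B; ++s)
    for (uword c = 0; c < C; ++c) {
      const double* src = X.slice_colptr(s, c);
      float* dst = X2.colptr(c) + s * L;
      for (uword l = 0; l < L; ++l) dst[l] = float(src[l]);
    }
  return X2;
}

// Kernel (k, Cin, Cout) as (Cin, k*Cout): block t holds W(t, , ).
static fmat kernel_blocks(const cube& W) {
  const uword k = W.n_rows, Cin = W.n_cols, Cout = W.n_slices;
  fmat Wb(Cin, k * Cout);
  for (uword o = 0; o < Cout; ++o)
    for (uword t = 0; t < k; ++t)
      for (uword c = 0; c < Cin; ++c)
        Wb(c, t * Cout + o) = float(W(t, c, o));
  return Wb;
}

// Valid output range [y0, y1] for tap offset `off` on length L.
static inline bool tap_range(int off, int L, int& y0, int& y1) {
  y0 = std::max(0, -off);
  y1 = std::min(L - 1, L - 1 - off);
  return y0 <= y1;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fw(const arma::cube& X, const arma::cube& W,
                         const arma::vec& b, int dilation,
                         bool relu = false) {
  const uword L = X.n_rows, B = X.n_slices;
  const uword k = W.n_rows, Cout = W.n_slices;
  const int center = (int(k) - 1) / 2;
  fmat X2 = stack_rows(X);
  fmat P = X2 * kernel_blocks(W);  // (L*B, k*Cout)
  fmat Y2(L * B, Cout, fill::zeros);
  int y0, y1;
  for (uword t = 0; t < k; ++t) {
    const int off = (int(t) - center) * dilation;
    if (!tap_range(off, int(L), y0, y1)) continue;
    for (uword s = 0; s < B; ++s)
      Y2.submat(s * L + y0, 0, s * L + y1, Cout - 1) +=
        P.submat(s * L + y0 + off, t * Cout, s * L + y1 + off,
                 t * Cout + Cout - 1);
  }
  cube Y(L, Cout, B);
  for (uword s = 0; s < B; ++s)
    for (uword o = 0; o < Cout; ++o) {
      const float* src = Y2.colptr(o) + s * L;
      const double bo = b(o);
      double* dst = Y.slice_colptr(s, o);
      if (relu)
        for (uword l = 0; l < L; ++l) {
          const double v = double(src[l]) + bo;
          dst[l] = v > 0 ? v : 0;
        }
      else
        for (uword l = 0; l < L; ++l) dst[l] = double(src[l]) + bo;
    }
  return Y;
}

// Backward of conv1d (optionally fused with ReLU: Yact is the activated
// output; incoming gradients are masked where Yact == 0).
// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bw(const arma::cube& X, const arma::cube& W,
                         const arma::cube& dY, int dilation,
                         Rcpp::Nullable<Rcpp::NumericVector> Yact =
                           R_NilValue) {
  const uword L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const uword k = W.n_rows, Cout = W.n_slices;
  const int center = (int(k) - 1) / 2;
  fmat X2 = stack_rows(X);
  fmat dY2 = stack_rows(dY);
  if (Yact.isNotNull()) {
    Rcpp::NumericVector yv(Yact);
    const double* y = yv.begin();
    // same (l, o, s) layout as dY; column of dY2 = o, row = s*L + l
    for (uword s = 0; s < B; ++s)
      for (uword o = 0; o < Cout; ++o) {
        const double* yc = y + (s * Cout + o) * L;
        float* d = dY2.colptr(o) + s * L;
        for (uword l = 0; l < L; ++l)
          if (yc[l] <= 0) d[l] = 0.0f;
      }
  }
  // dX: Q(g, t*Cin + c) = sum_o dY2(g, o) W(t, c, o)
  fmat Wc(Cout, k * Cin);
  for (uword o = 0; o < Cout; ++o)
    for (uword t = 0; t < k; ++t)
      for (uword c = 0; c < Cin; ++c)
        Wc(o, t * Cin + c) = float(W(t, c, o));
  fmat Q = dY2 * Wc;  // (L*B, k*Cin)
  fmat dX2(L * B, Cin, fill::zeros);
  // dW: D(g + off, t*Cout + o) = dY2(g, o); dWall = X2' * D
  fmat D(L * B, k * Cout, fill::zeros);
  int y0, y1;
  for (uword t = 0; t < k; ++t) {
    const int off = (int(t) - center) * dilation;
    if (!tap_range(off, int(L), y0, y1)) continue;
    for (uword s = 0; s < B; ++s) {
      dX2.submat(s * L + y0 + off, 0, s * L + y1 + off, Cin - 1) +=
        Q.submat(s * L + y0, t * Cin, s * L + y1, t * Cin + Cin - 1);
      D.submat(s * L + y0 + off, t * Cout, s * L + y1 + off,
               t * Cout + Cout - 1) =
        dY2.submat(s * L + y0, 0, s * L + y1, Cout - 1);
    }
  }
  fmat dWall = X2.t() * D;  // (Cin, k*Cout)
  cube dW(k, Cin, Cout);
  for (uword o = 0; o < Cout; ++o)
    for (uword t = 0; t < k; ++t)
      for (uword c = 0; c < Cin; ++c)
        dW(t, c, o) = double(dWall(c, t * Cout + o));
  cube dX(L, Cin, B);
  for (uword s = 0; s < B; ++s)
    for (uword c = 0; c < Cin; ++c) {
      const float* src = dX2.colptr(c) + s * L;
      double* dst = dX.slice_colptr(s, c);
      for (uword l = 0; l < L; ++l) dst[l] = double(src[l]);
    }
  fvec dbf = sum(dY2, 0).t();
  vec db = conv_to<vec>::from(dbf);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fw(const arma::cube& X, int width) {
  const uword L = X.n_rows, C = X.n_cols, B = X.n_slices;
  const uword Lout = L / uword(width);
  cube Y(Lout, C, B);
  icube amax(Lout, C, B);  // 0-based row index into X
  for (uword s = 0; s < B; ++s)
    for (uword c = 0; c < C; ++c)
      for (uword j = 0; j < Lout; ++j) {
        uword best = j * width;
        double bv = X(best, c, s);
        for (uword t = 1; t < uword(width); ++t) {
          const uword l = j * width + t;
          if (X(l, c, s) > bv) { bv = X(l, c, s); best = l; }
        }
        Y(j, c, s) = bv;
        amax(j, c, s) = sword(best);
      }
  return List::create(_["Y"] = Y, _["amax"] = amax);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::icube& amax, const arma::cube& dY,
                          int Lin) {
  const uword Lout = dY.n_rows, C = dY.n_cols, B = dY.n_slices;
  cube dX(uword(Lin), C, B, fill::zeros);
  for (uword s = 0; s < B; ++s)
    for (uword c = 0; c < C; ++c)
      for (uword j = 0; j < Lout; ++j)
        dX(uword(amax(j, c, s)), c, s) += dY(j, c, s);
  return dX;
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_fw(const arma::cube& X, const arma::vec& gamma,
                     const arma::vec& beta, double eps, bool training,
                     const arma::vec& running_mean,
                     const arma::vec& running_var, double momentum) {
  const uword L = X.n_rows, C = X.n_cols, B = X.n_slices;
  vec mu(C), v(C);
  if (training) {
    const double n = double(L) * double(B);
    for (uword c = 0; c < C; ++c) {
      double s = 0, ss = 0;
      for (uword b = 0; b < B; ++b) {
        const vec col = X.slice(b).col(c);
        s += accu(col);
        ss += dot(col, col);
      }
      mu(c) = s / n;
      v(c) = ss / n - mu(c) * mu(c);
      if (v(c) < 0) v(c) = 0;
    }
  } else {
    mu = running_mean;
    v = running_var;
  }
  cube Y(L, C, B);
  for (uword c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(v(c) + eps);
    for (uword b = 0; b < B; ++b)
      Y.slice(b).col(c) = gamma(c) * (X.slice(b).col(c) - mu(c)) * inv + beta(c);
  }
  vec rm = running_mean, rv = running_var;
  if (training) {
    rm = momentum * running_mean + (1.0 - momentum) * mu;
    rv = momentum * running_var + (1.0 - momentum) * v;
  }
  return List::create(_["Y"] = Y, _["mean"] = mu, _["var"] = v,
                      _["running_mean"] = rm, _["running_var"] = rv);
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_bw(const arma::cube& X, const arma::vec& gamma,
                     const arma::vec& mu, const arma::vec& v,
                     const arma::cube& dY, double eps) {
  const uword L = X.n_rows, C = X.n_cols, B = X.n_slices;
  const double n = double(L) * double(B);
  cube dX(L, C, B);
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(v(c) + eps);
    double sum_dy = 0, sum_dy_xhat = 0;
    for (uword b = 0; b < B; ++b) {
      const vec xhat = (X.slice(b).col(c) - mu(c)) * inv;
      const vec dy = dY.slice(b).col(c);
      sum_dy += accu(dy);
      sum_dy_xhat += dot(dy, xhat);
    }
    dgamma(c) = sum_dy_xhat;
    dbeta(c) = sum_dy;
    for (uword b = 0; b < B; ++b) {
      const vec xhat = (X.slice(b).col(c) - mu(c)) * inv;
      const vec dy = dY.slice(b).col(c);
      dX.slice(b).col(c) =
        gamma(c) * inv * (dy - sum_dy / n - xhat * (sum_dy_xhat / n));
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}


// ---------------------------------------------------------------------------
// Training session: the full optimization step (forward, backward, ADAM)
// lives behind an external pointer so per-batch work allocates nothing on
// the R heap. Activations are kept "stacked": a (L*B, C) float matrix whose
// row s*L + l is position l of batch element s. Layer parameters mirror the
// R parameter list; nn_session_params() exports them back (deep copy) for
// validation, snapshotting and prediction through the R forward pass.

namespace {

struct SLayer {
  int type;  // 0 conv, 1 bn, 2 pool, 3 out
  // conv / out
  fcube W; fvec b; int dilation = 1; bool relu = false;
  fcube mW, vW; fvec mb, vb;
  // bn
  fvec gamma, beta, rmean, rvar, mean, var;
  fvec mg, vg, mbe, vbe;
  double eps = 1e-5, momentum = 0.9;
  // pool
  int width = 2;
  umat amax;   // (Lout*B, C) winning source rows
  // caches
  fmat Xin;    // stacked input
  fmat Yout;   // stacked output (post-activation for conv)
};

struct Session {
  std::vector<SLayer> layers;
  int L0 = 0;      // input length
  long step = 0;   // ADAM step count
};

inline fmat stack_sexp(const NumericVector& Xv, int L, int C, int B) {
  fmat X2(size_t(L) * B, C);
  const double* x = Xv.begin();
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* src = x + (size_t(s) * C + c) * L;
      float* dst = X2.colptr(c) + size_t(s) * L;
      for (int l = 0; l < L; ++l) dst[l] = float(src[l]);
    }
  return X2;
}

void adam_update(fmat& th, fmat& m, fmat& v, const fmat& g, double lr,
                 double c1, double c2) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  for (uword i = 0; i < th.n_elem; ++i) {
    m(i) = b1 * m(i) + (1.0f - b1) * g(i);
    v(i) = b2 * v(i) + (1.0f - b2) * g(i) * g(i);
    th(i) -= float(lr) * (m(i) / float(c1)) /
             (std::sqrt(v(i) / float(c2)) + eps);
  }
}

void adam_update(fvec& th, fvec& m, fvec& v, const fvec& g, double lr,
                 double c1, double c2) {
  fmat thm(th.memptr(), th.n_elem, 1, false, true);
  fmat mm(m.memptr(), m.n_elem, 1, false, true);
  fmat vm(v.memptr(), v.n_elem, 1, false, true);
  const fmat gm(const_cast<float*>(g.memptr()), g.n_elem, 1, false, true);
  adam_update(thm, mm, vm, gm, lr, c1, c2);
}

// conv forward on stacked input; returns stacked output.
fmat sconv_fw(SLayer& ly, const fmat& X2, int L, int B) {
  const uword k = ly.W.n_rows, Cout = ly.W.n_slices, Cin = ly.W.n_cols;
  const int center = (int(k) - 1) / 2;
  fmat Wb(Cin, k * Cout);
  for (uword o = 0; o < Cout; ++o)
    for (uword t = 0; t < k; ++t)
      for (uword c = 0; c < Cin; ++c) Wb(c, t * Cout + o) = ly.W(t, c, o);
  fmat P = X2 * Wb;
  fmat Y2(size_t(L) * B, Cout, fill::zeros);
  int y0, y1;
  for (uword t = 0; t < k; ++t) {
    const int off = (int(t) - center) * ly.dilation;
    if (!tap_range(off, L, y0, y1)) continue;
    for (int s = 0; s < B; ++s)
      Y2.submat(size_t(s) * L + y0, 0, size_t(s) * L + y1, Cout - 1) +=
        P.submat(size_t(s) * L + y0 + off, t * Cout,
                 size_t(s) * L + y1 + off, t * Cout + Cout - 1);
  }
  Y2.each_row() += ly.b.t();
  if (ly.relu) Y2.for_each([](float& v) { if (v < 0) v = 0; });
  return Y2;
}

// conv backward on stacked gradients; applies ADAM to W and b in place.
fmat sconv_bw(SLayer& ly, fmat dY2, int L, int B, double lr, double c1,
              double c2) {
  const uword k = ly.W.n_rows, Cout = ly.W.n_slices, Cin = ly.W.n_cols;
  const int center = (int(k) - 1) / 2;
  if (ly.relu) {
    for (uword j = 0; j < dY2.n_cols; ++j) {
      float* d = dY2.colptr(j);
      const float* y = ly.Yout.colptr(j);
      for (uword i = 0; i < dY2.n_rows; ++i)
        if (y[i] <= 0) d[i] = 0.0f;
    }
  }
  fmat Wc(Cout, k * Cin);
  for (uword o = 0; o < Cout; ++o)
    for (uword t = 0; t < k; ++t)
      for (uword c = 0; c < Cin; ++c) Wc(o, t * Cin + c) = ly.W(t, c, o);
  fmat Q = dY2 * Wc;
  fmat dX2(size_t(L) * B, Cin, fill::zeros);
  fmat D(size_t(L) * B, k * Cout, fill::zeros);
  int y0, y1;
  for (uword t = 0; t < k; ++t) {
    const int off = (int(t) - center) * ly.dilation;
    if (!tap_range(off, L, y0, y1)) continue;
    for (int s = 0; s < B; ++s) {
      dX2.submat(size_t(s) * L + y0 + off, 0,
                 size_t(s) * L + y1 + off, Cin - 1) +=
        Q.submat(size_t(s) * L + y0, t * Cin,
                 size_t(s) * L + y1, t * Cin + Cin - 1);
      D.submat(size_t(s) * L + y0 + off, t * Cout,
               size_t(s) * L + y1 + off, t * Cout + Cout - 1) =
        dY2.submat(size_t(s) * L + y0, 0, size_t(s) * L + y1, Cout - 1);
    }
  }
  fmat dWall = ly.Xin.t() * D;  // (Cin, k*Cout)
  fcube dW(k, Cin, Cout);
  for (uword o = 0; o < Cout; ++o)
    for (uword t = 0; t < k; ++t)
      for (uword c = 0; c < Cin; ++c) dW(t, c, o) = dWall(c, t * Cout + o);
  fvec db = sum(dY2, 0).t();
  fmat thW(ly.W.memptr(), ly.W.n_elem, 1, false, true);
  fmat mW(ly.mW.memptr(), ly.mW.n_elem, 1, false, true);
  fmat vW(ly.vW.memptr(), ly.vW.n_elem, 1, false, true);
  fmat gW(dW.memptr(), dW.n_elem, 1, false, true);
  adam_update(thW, mW, vW, gW, lr, c1, c2);
  adam_update(ly.b, ly.mb, ly.vb, db, lr, c1, c2);
  return dX2;
}

}  // namespace

// [[Rcpp::export]]
SEXP nn_session_new(Rcpp::List params) {
  Session* s = new Session();
  for (int i = 0; i < params.size(); ++i) {
    Rcpp::List l = params[i];
    std::string type = Rcpp::as<std::string>(l["type"]);
    SLayer ly;
    if (type == "conv" || type == "out") {
      ly.type = (type == "conv") ? 0 : 3;
      NumericVector Wv = l["W"];
      Rcpp::IntegerVector d = Wv.attr("dim");
      ly.W.set_size(d[0], d[1], d[2]);
      for (uword j = 0; j < ly.W.n_elem; ++j) ly.W(j) = float(Wv[j]);
      ly.b = conv_to<fvec>::from(Rcpp::as<vec>(l["b"]));
      if (type == "conv") {
        ly.dilation = Rcpp::as<int>(l["dilation"]);
        ly.relu = Rcpp::as<std::string>(l["act"]) == "relu";
      }
      ly.mW.zeros(size(ly.W)); ly.vW.zeros(size(ly.W));
      ly.mb.zeros(ly.b.n_elem); ly.vb.zeros(ly.b.n_elem);
    } else if (type == "bn") {
      ly.type = 1;
      ly.gamma = conv_to<fvec>::from(Rcpp::as<vec>(l["gamma"]));
      ly.beta = conv_to<fvec>::from(Rcpp::as<vec>(l["beta"]));
      ly.rmean = conv_to<fvec>::from(Rcpp::as<vec>(l["rmean"]));
      ly.rvar = conv_to<fvec>::from(Rcpp::as<vec>(l["rvar"]));
      ly.mg.zeros(ly.gamma.n_elem); ly.vg.zeros(ly.gamma.n_elem);
      ly.mbe.zeros(ly.beta.n_elem); ly.vbe.zeros(ly.beta.n_elem);
    } else if (type == "pool") {
      ly.type = 2;
      ly.width = Rcpp::as<int>(l["width"]);
    }
    s->layers.push_back(std::move(ly));
  }
  return Rcpp::XPtr<Session>(s, true);
}

// [[Rcpp::export]]
double nn_session_train_batch(SEXP ptr, Rcpp::NumericVector X,
                              Rcpp::NumericMatrix Y, double lr) {
  Rcpp::XPtr<Session> sp(ptr);
  Session& ss = *sp;
  Rcpp::IntegerVector dims = X.attr("dim");
  int L = dims[0], C = dims[1], B = dims[2];
  fmat A = stack_sexp(X, L, C, B);
  // ---- forward
  for (auto& ly : ss.layers) {
    if (ly.type == 0) {            // conv
      ly.Xin = A;
      A = sconv_fw(ly, A, L, B);
      ly.Yout = A;
    } else if (ly.type == 1) {     // bn: batch stats over rows per channel
      ly.Xin = A;
      const uword Cc = A.n_cols;
      ly.mean.set_size(Cc); ly.var.set_size(Cc);
      const float n = float(A.n_rows);
      for (uword c = 0; c < Cc; ++c) {
        const float mu = accu(A.col(c)) / n;
        float v = dot(A.col(c), A.col(c)) / n - mu * mu;
        if (v < 0) v = 0;
        ly.mean(c) = mu; ly.var(c) = v;
        const float inv = 1.0f / std::sqrt(v + float(ly.eps));
        A.col(c) = ly.gamma(c) * (A.col(c) - mu) * inv + ly.beta(c);
        ly.rmean(c) = float(ly.momentum) * ly.rmean(c) +
                      (1.0f - float(ly.momentum)) * mu;
        ly.rvar(c) = float(ly.momentum) * ly.rvar(c) +
                     (1.0f - float(ly.momentum)) * v;
      }
      ly.Yout = A;
    } else if (ly.type == 2) {     // pool
      const int Lout = L / ly.width;
      const uword Cc = A.n_cols;
      fmat P(size_t(Lout) * B, Cc);
      ly.amax.set_size(size_t(Lout) * B, Cc);
      for (uword c = 0; c < Cc; ++c) {
        const float* src = A.colptr(c);
        float* dst = P.colptr(c);
        uword* am = ly.amax.colptr(c);
        for (int s = 0; s < B; ++s)
          for (int j = 0; j < Lout; ++j) {
            size_t base = size_t(s) * L + size_t(j) * ly.width;
            size_t best = base;
            float bv = src[base];
            for (int t = 1; t < ly.width; ++t)
              if (src[base + t] > bv) { bv = src[base + t]; best = base + t; }
            dst[size_t(s) * Lout + j] = bv;
            am[size_t(s) * Lout + j] = best;
          }
      }
      ly.Xin.reset();
      A = std::move(P);
      L = Lout;
    } else {                        // out: 1x1 conv + sigmoid
      ly.Xin = A;
      fvec wv(ly.W.n_cols);
      for (uword c = 0; c < ly.W.n_cols; ++c) wv(c) = ly.W(0, c, 0);
      fvec z = A * wv + ly.b(0);
      A = 1.0f / (1.0f + exp(-z));
      ly.Yout = A;
    }
  }
  // ---- loss and output gradient (A is (bins*B, 1) probabilities)
  Rcpp::IntegerVector ydim(2); ydim[0] = Y.nrow(); ydim[1] = Y.ncol();
  const double* yv = Y.begin();
  const size_t n = A.n_rows;
  double loss = 0;
  fmat dz(n, 1);
  for (size_t i = 0; i < n; ++i) {
    double p = std::min(std::max(double(A(i, 0)), 1e-7), 1.0 - 1e-7);
    const double t = yv[i];
    loss += -(t * std::log(p) + (1 - t) * std::log(1 - p));
    dz(i, 0) = float((double(A(i, 0)) - t) / double(n));
  }
  loss /= double(n);
  // ---- backward + ADAM
  ss.step += 1;
  const double c1 = 1.0 - std::pow(0.9, double(ss.step));
  const double c2 = 1.0 - std::pow(0.999, double(ss.step));
  fmat G = dz;  // gradient wrt presigmoid handled at out layer
  for (int i = int(ss.layers.size()) - 1; i >= 0; --i) {
    SLayer& ly = ss.layers[i];
    if (ly.type == 3) {
      // G currently d(loss)/d(presigmoid z), shape (bins*B, 1)
      fvec wv(ly.W.n_cols);
      for (uword c = 0; c < ly.W.n_cols; ++c) wv(c) = ly.W(0, c, 0);
      fmat dX = G * wv.t();              // (bins*B, Cin)
      fmat dwm = ly.Xin.t() * G;
      fvec dw = dwm.col(0);              // (Cin)
      fvec db(1); db(0) = accu(G);
      fcube dW(1, ly.W.n_cols, 1);
      for (uword c = 0; c < ly.W.n_cols; ++c) dW(0, c, 0) = dw(c);
      fmat thW(ly.W.memptr(), ly.W.n_elem, 1, false, true);
      fmat mW(ly.mW.memptr(), ly.mW.n_elem, 1, false, true);
      fmat vW(ly.vW.memptr(), ly.vW.n_elem, 1, false, true);
      fmat gW(dW.memptr(), dW.n_elem, 1, false, true);
      adam_update(thW, mW, vW, gW, lr, c1, c2);
      adam_update(ly.b, ly.mb, ly.vb, db, lr, c1, c2);
      G = dX;
      L = int(G.n_rows) / B;
    } else if (ly.type == 1) {
      const uword Cc = G.n_cols;
      const float nn = float(G.n_rows);
      fmat dX(G.n_rows, Cc);
      fvec dgamma(Cc), dbeta(Cc);
      for (uword c = 0; c < Cc; ++c) {
        const float inv = 1.0f / std::sqrt(ly.var(c) + float(ly.eps));
        fvec xhat = (ly.Xin.col(c) - ly.mean(c)) * inv;
        const float sdy = accu(G.col(c));
        const float sdyx = dot(G.col(c), xhat);
        dgamma(c) = sdyx;
        dbeta(c) = sdy;
        dX.col(c) = ly.gamma(c) * inv *
                    (G.col(c) - sdy / nn - xhat * (sdyx / nn));
      }
      adam_update(ly.gamma, ly.mg, ly.vg, dgamma, lr, c1, c2);
      adam_update(ly.beta, ly.mbe, ly.vbe, dbeta, lr, c1, c2);
      G = dX;
    } else if (ly.type == 2) {
      const int Lin = L * ly.width;
      const uword Cc = G.n_cols;
      fmat dX(size_t(Lin) * B, Cc, fill::zeros);
      for (uword c = 0; c < Cc; ++c) {
        const uword* am = ly.amax.colptr(c);
        const float* g = G.colptr(c);
        float* d = dX.colptr(c);
        for (size_t j = 0; j < G.n_rows; ++j) d[am[j]] += g[j];
      }
      G = std::move(dX);
      L = Lin;
    } else {
      G = sconv_bw(ly, std::move(G), L, B, lr, c1, c2);
    }
  }
  return loss;
}

// [[Rcpp::export]]
Rcpp::List nn_session_params(SEXP ptr) {
  Rcpp::XPtr<Session> sp(ptr);
  Rcpp::List out(sp->layers.size());
  for (size_t i = 0; i < sp->layers.size(); ++i) {
    SLayer& ly = sp->layers[i];
    if (ly.type == 0 || ly.type == 3) {
      NumericVector W(ly.W.n_elem);
      for (uword j = 0; j < ly.W.n_elem; ++j) W[j] = double(ly.W(j));
      W.attr("dim") = Rcpp::IntegerVector::create(ly.W.n_rows, ly.W.n_cols,
                                                  ly.W.n_slices);
      Rcpp::List l = Rcpp::List::create(
        Rcpp::_["type"] = (ly.type == 0) ? "conv" : "out",
        Rcpp::_["W"] = W,
        Rcpp::_["b"] = Rcpp::wrap(conv_to<vec>::from(ly.b)),
        Rcpp::_["dilation"] = ly.dilation);
      if (ly.type == 0) l["act"] = ly.relu ? "relu" : "linear";
      out[i] = l;
    } else if (ly.type == 1) {
      out[i] = Rcpp::List::create(
        Rcpp::_["type"] = "bn",
        Rcpp::_["gamma"] = Rcpp::wrap(conv_to<vec>::from(ly.gamma)),
        Rcpp::_["beta"] = Rcpp::wrap(conv_to<vec>::from(ly.beta)),
        Rcpp::_["rmean"] = Rcpp::wrap(conv_to<vec>::from(ly.rmean)),
        Rcpp::_["rvar"] = Rcpp::wrap(conv_to<vec>::from(ly.rvar)));
    } else {
      out[i] = Rcpp::List::create(Rcpp::_["type"] = "pool",
                                  Rcpp::_["width"] = ly.width);
    }
  }
  return out;
}
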