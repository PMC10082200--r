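// Convolutional network core for the per-axis slice classifiers.
//
// Fixed architecture (census: 2 conv, 3 batch-norm, 3 ReLU, 2 max-pool,
// 1 fully connected + softmax):
//   input (H x W x 1)
//   conv 3x3 x nf (same padding) - BN - ReLU - maxpool 2x2 stride 2
//   conv 3x3 x nf (same padding) - BN - ReLU - maxpool 2x2 stride 2
//   BN - ReLU - fully connected (2) - softmax
//
// A chunk of nc images is processed as one flattened (npix*nc x channels)
// matrix, pixel p of image i at row i*npix + p with p = r + c*H
// (column-major in-image).  Convolution is im2col + one GEMM per chunk;
// batch-norm statistics are single-pass column moments.  Training is SGD
// with momentum; BN statistics are computed over memory-bounded sub-batches
// ("ghost" batch norm) so a 512x512 input fits in memory while the SGD
// minibatch keeps its configured size.  All randomness (init, shuffling)
// lives on the R side: given the same parameter list and visit order this
// code is deterministic.
//
// The core runs in single precision (sgemm + halved memory traffic);
// gradient and moment accumulators that span many elements use double.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
typedef arma::fmat mat;
typedef arma::fvec vec;
typedef arma::frowvec rowvec;
using arma::uword;

static const float BN_EPS = 1e-5f;

struct Dims {
  int H, W, nf, Hp, Wp, Hq, Wq;
  uword npix, npp, npq, D;
};

static Dims get_dims(const List &par) {
  Dims d;
  d.H = as<int>(par["H"]); d.W = as<int>(par["W"]); d.nf = as<int>(par["nf"]);
  d.Hp = d.H / 2; d.Wp = d.W / 2; d.Hq = d.Hp / 2; d.Wq = d.Wp / 2;
  d.npix = (uword)d.H * d.W; d.npp = (uword)d.Hp * d.Wp;
  d.npq = (uword)d.Hq * d.Wq;
  d.D = d.npq * d.nf;
  return d;
}

// im2col for 3x3 kernels with zero 'same' padding over a flattened chunk.
// A: (h*w*nc x C), out resized to (h*w*nc x 9C); no bleed across images.
// Only the padding cells are zeroed explicitly — the interior is fully
// overwritten, and a full-buffer fill costs real time at 512x512.
static void im2col3(const mat &A, int h, int w, int nc, mat &out) {
  int C = A.n_cols;
  uword npix = (uword)h * w;
  out.set_size(A.n_rows, 9 * C);
  for (int ch = 0; ch < C; ++ch)
    for (int dx = -1; dx <= 1; ++dx) {
      int c0 = std::max(0, -dx), c1 = w - 1 - std::max(0, dx);
      for (int dy = -1; dy <= 1; ++dy) {
        int r0 = std::max(0, -dy), r1 = h - 1 - std::max(0, dy);
        int len = (r1 >= r0) ? (r1 - r0 + 1) : 0;
        float *dst0 = out.colptr(ch * 9 + (dy + 1) + 3 * (dx + 1));
        const float *src0 = A.colptr(ch);
        for (int i = 0; i < nc; ++i) {
          const float *src = src0 + (uword)i * npix;
          float *dst = dst0 + (uword)i * npix;
          for (int c = 0; c < w; ++c) {
            float *dc = dst + (uword)c * h;
            if (c < c0 || c > c1 || len == 0) {
              std::fill(dc, dc + h, 0.0f);        // padded column
              continue;
            }
            if (r0 > 0) std::fill(dc, dc + r0, 0.0f);
            std::copy(src + (uword)(c + dx) * h + (r0 + dy),
                      src + (uword)(c + dx) * h + (r0 + dy) + len,
                      dc + r0);
            if (r1 < h - 1) std::fill(dc + r1 + 1, dc + h, 0.0f);
          }
        }
      }
    }
}

// 2x2 stride-2 max pooling over a flattened chunk, with absolute argmax
// row capture.
static void pool2x2(const mat &A, int h, int w, int nc, mat &out,
                    arma::umat &idx) {
  int hp = h / 2, wp = w / 2, C = A.n_cols;
  uword npix = (uword)h * w, npo = (uword)hp * wp;
  out.set_size(npo * nc, C);
  idx.set_size(npo * nc, C);
  for (int ch = 0; ch < C; ++ch) {
    const float *src0 = A.colptr(ch);
    float *o0 = out.colptr(ch);
    uword *ix0 = idx.colptr(ch);
    for (int i = 0; i < nc; ++i) {
      const float *src = src0 + (uword)i * npix;
      float *o = o0 + (uword)i * npo;
      uword *ix = ix0 + (uword)i * npo;
      for (int cp = 0; cp < wp; ++cp)
        for (int rp = 0; rp < hp; ++rp) {
          uword p00 = (uword)(2 * cp) * h + 2 * rp;
          uword cand[4] = {p00, p00 + 1, p00 + h, p00 + h + 1};
          float best = src[cand[0]]; uword bi = cand[0];
          for (int t = 1; t < 4; ++t)
            if (src[cand[t]] > best) { best = src[cand[t]]; bi = cand[t]; }
          uword q = (uword)cp * hp + rp;
          o[q] = best; ix[q] = bi + (uword)i * npix;
        }
    }
  }
}

struct BNStats { rowvec mu, sd; };

// Chunk batch-norm statistics (double accumulation) + running update.
static BNStats bn_stats_train(const mat &Z, rowvec &rmean, rowvec &rvar,
                              double bn_mom) {
  double n = (double)Z.n_rows;
  arma::rowvec s = arma::conv_to<arma::rowvec>::from(arma::sum(Z, 0));
  arma::rowvec q =
    arma::conv_to<arma::rowvec>::from(arma::sum(arma::square(Z), 0));
  arma::rowvec mu = s / n;
  arma::rowvec var = arma::clamp(q / n - arma::square(mu), 0.0,
                                 arma::datum::inf);
  rowvec muf = arma::conv_to<rowvec>::from(mu);
  rowvec varf = arma::conv_to<rowvec>::from(var);
  rmean = (float)(1.0 - bn_mom) * rmean + (float)bn_mom * muf;
  rvar = (float)(1.0 - bn_mom) * rvar + (float)bn_mom * varf;
  BNStats st; st.mu = muf; st.sd = arma::sqrt(varf + BN_EPS);
  return st;
}

// A = relu(gamma * (Z - mu)/sd + beta)
static void bn_relu_forward(const mat &Z, mat &A, const BNStats &st,
                            const rowvec &g, const rowvec &b) {
  rowvec scale = g / st.sd;
  rowvec shift = b - st.mu % scale;
  A = Z;
  A.each_row() %= scale;
  A.each_row() += shift;
  A.for_each([](float &x) { if (x < 0) x = 0; });
}

static void bn_relu_infer(mat &M, const rowvec &g, const rowvec &b,
                          const rowvec &rmean, const rowvec &rvar) {
  rowvec sd = arma::sqrt(rvar + BN_EPS);
  rowvec scale = g / sd;
  rowvec shift = b - rmean % scale;
  M.each_row() %= scale;
  M.each_row() += shift;
  M.for_each([](float &x) { if (x < 0) x = 0; });
}

// In-place BN backward: dY (already ReLU-masked) -> dZ; accumulates
// dgamma/dbeta into double accumulators owned by the caller.
static void bn_backward(mat &dY, const mat &Z, const BNStats &st,
                        const rowvec &g, arma::rowvec &dg, arma::rowvec &db) {
  double n = (double)dY.n_rows;
  static mat xhat;            // persistent scratch: avoids cold-page refill
  xhat = Z;
  xhat.each_row() -= st.mu;
  xhat.each_row() /= st.sd;
  arma::rowvec sum_dy = arma::conv_to<arma::rowvec>::from(arma::sum(dY, 0));
  arma::rowvec sum_dy_xhat =
    arma::conv_to<arma::rowvec>::from(arma::sum(dY % xhat, 0));
  dg += sum_dy_xhat;
  db += sum_dy;
  rowvec m_dy = arma::conv_to<rowvec>::from(sum_dy / n);
  rowvec m_dy_xhat = arma::conv_to<rowvec>::from(sum_dy_xhat / n);
  rowvec scale = g / st.sd;
  dY.each_row() -= m_dy;
  xhat.each_row() %= m_dy_xhat;
  dY -= xhat;
  dY.each_row() %= scale;
}

// Data gradient of a 3x3 'same' convolution, decomposed per kernel offset:
// out += shift_k(dZ * W_k^T) for the 9 offsets.  One huge (M x 9C) GEMM
// here hits a slow BLAS kernel shape; nine (M x C)(C x C) GEMMs run at
// full speed and avoid materializing the 9C-wide column buffer.
static void conv_bwd_data(const mat &dZ, const mat &W, int h, int w, int nc,
                          mat &out) {
  int C = W.n_rows / 9, nf = W.n_cols;
  uword npix = (uword)h * w;
  out.zeros(dZ.n_rows, C);
  static mat Wk, contrib;     // persistent scratch
  Wk.set_size(C, nf);
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy) {
      int k = (dy + 1) + 3 * (dx + 1);
      for (int ch = 0; ch < C; ++ch) Wk.row(ch) = W.row(ch * 9 + k);
      contrib = dZ * Wk.t();                  // (npix*nc x C)
      int c0 = std::max(0, -dx), c1 = w - 1 - std::max(0, dx);
      int r0 = std::max(0, -dy), r1 = h - 1 - std::max(0, dy);
      if (c1 < c0 || r1 < r0) continue;
      int len = r1 - r0 + 1;
      for (int ch = 0; ch < C; ++ch) {
        const float *src0 = contrib.colptr(ch);
        float *dst0 = out.colptr(ch);
        for (int i = 0; i < nc; ++i) {
          const float *src = src0 + (uword)i * npix;
          float *dst = dst0 + (uword)i * npix;
          for (int c = c0; c <= c1; ++c) {
            const float *s = src + (uword)c * h + r0;
            float *d = dst + (uword)(c + dx) * h + (r0 + dy);
            for (int t = 0; t < len; ++t) d[t] += s[t];
          }
        }
      }
    }
}

static void relu_mask(mat &dY, const mat &A) {
  const float *a = A.memptr();
  float *d = dY.memptr();
  for (uword i = 0; i < A.n_elem; ++i)
    if (a[i] <= 0) d[i] = 0;
}

// gather a flattened float chunk from the converted input buffer
static void gather_chunk(const float *xp, uword npix,
                         const std::vector<int> &ids, mat &A) {
  int nc = ids.size();
  A.set_size(npix * nc, 1);
  for (int i = 0; i < nc; ++i)
    std::copy(xp + (uword)ids[i] * npix, xp + (uword)(ids[i] + 1) * npix,
              A.colptr(0) + (uword)i * npix);
}

static arma::fvec to_float(const NumericVector &x) {
  arma::fvec xf(x.size());
  const double *p0 = x.begin();
  for (R_xlen_t t = 0; t < x.size(); ++t) xf[t] = (float)p0[t];
  return xf;
}

#define LOAD_PARAMS                                                   \
  mat W1 = as<mat>(par["W1"]); rowvec b1 = as<rowvec>(par["b1"]);     \
  mat W2 = as<mat>(par["W2"]); rowvec b2 = as<rowvec>(par["b2"]);     \
  mat Wf = as<mat>(par["Wf"]); vec bf = as<vec>(par["bf"]);           \
  rowvec g1 = as<rowvec>(par["g1"]), be1 = as<rowvec>(par["be1"]);    \
  rowvec g2 = as<rowvec>(par["g2"]), be2 = as<rowvec>(par["be2"]);    \
  rowvec g3 = as<rowvec>(par["g3"]), be3 = as<rowvec>(par["be3"]);    \
  rowvec rm1 = as<rowvec>(par["rm1"]), rv1 = as<rowvec>(par["rv1"]);  \
  rowvec rm2 = as<rowvec>(par["rm2"]), rv2 = as<rowvec>(par["rv2"]);  \
  rowvec rm3 = as<rowvec>(par["rm3"]), rv3 = as<rowvec>(par["rv3"]);

// chunk size keeping the large intermediates around ~1.5 GB
static int auto_chunk(const Dims &dm, int cap) {
  double per_image = (double)dm.npix * dm.nf * 4.0 * 5.0;
  int nc = (int)std::floor(1.5e9 / per_image);
  return std::max(1, std::min(cap, nc));
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(List par, NumericVector x) {
  Dims dm = get_dims(par);
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3 || xd[0] != dm.H || xd[1] != dm.W)
    stop("input shape does not match network input layer");
  int N = xd[2];
  LOAD_PARAMS
  arma::fvec xf = to_float(x);
  const float *xp = xf.memptr();
  NumericMatrix probs(N, 2);
  int chunk = auto_chunk(dm, 32);
  mat A, cols, Z, P;
  arma::umat idx;
  for (int i0 = 0; i0 < N; i0 += chunk) {
    std::vector<int> ids;
    for (int i = i0; i < std::min(N, i0 + chunk); ++i) ids.push_back(i);
    int nc = ids.size();
    gather_chunk(xp, dm.npix, ids, A);
    im2col3(A, dm.H, dm.W, nc, cols);
    Z = cols * W1;
    Z.each_row() += b1;
    bn_relu_infer(Z, g1, be1, rm1, rv1);
    pool2x2(Z, dm.H, dm.W, nc, P, idx);
    im2col3(P, dm.Hp, dm.Wp, nc, cols);
    Z = cols * W2;
    Z.each_row() += b2;
    bn_relu_infer(Z, g2, be2, rm2, rv2);
    pool2x2(Z, dm.Hp, dm.Wp, nc, P, idx);
    bn_relu_infer(P, g3, be3, rm3, rv3);
    for (int i = 0; i < nc; ++i) {
      mat f = P.rows((uword)i * dm.npq, (uword)(i + 1) * dm.npq - 1);
      vec fv = arma::vectorise(f);
      vec logit = Wf.t() * fv + bf;
      float mx = logit.max();
      vec e = arma::exp(logit - mx);
      e /= arma::accu(e);
      probs(ids[i], 0) = e(0);
      probs(ids[i], 1) = e(1);
    }
    Rcpp::checkUserInterrupt();
  }
  return probs;
}

// One SGDM epoch.  par/vel are returned updated together with the
// per-iteration training log.  y: 0 = background, 1 = organ; order: 1-based
// visit order (an R permutation); classw: per-class loss weights; l2:
// weight decay applied to W1/W2/Wf only.
// [[Rcpp::export]]
List cnn_train_epoch_cpp(List par, List vel, NumericVector x, IntegerVector y,
                         IntegerVector order, int minibatch, int bn_chunk,
                         double lr, double momentum, double bn_mom,
                         NumericVector classw, double l2) {
  Dims dm = get_dims(par);
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3 || xd[0] != dm.H || xd[1] != dm.W)
    stop("input shape does not match network input layer");
  int N = xd[2];
  if (order.size() != N) stop("order length mismatch");
  LOAD_PARAMS

  mat vW1 = as<mat>(vel["W1"]); rowvec vb1 = as<rowvec>(vel["b1"]);
  mat vW2 = as<mat>(vel["W2"]); rowvec vb2 = as<rowvec>(vel["b2"]);
  mat vWf = as<mat>(vel["Wf"]); vec vbf = as<vec>(vel["bf"]);
  rowvec vg1 = as<rowvec>(vel["g1"]), vbe1 = as<rowvec>(vel["be1"]);
  rowvec vg2 = as<rowvec>(vel["g2"]), vbe2 = as<rowvec>(vel["be2"]);
  rowvec vg3 = as<rowvec>(vel["g3"]), vbe3 = as<rowvec>(vel["be3"]);

  arma::fvec xf = to_float(x);
  const float *xp = xf.memptr();

  int niter = (N + minibatch - 1) / minibatch;
  NumericVector it_loss(niter), it_acc(niter);
  // workspace reused across chunks and iterations: fresh large allocations
  // fault in cold pages each time and dominate runtime otherwise
  mat cols, X, Z1, A1, P1, Z2, A2, P2, A3, dA3, dA2, dA1, dP1;
  arma::umat I1, I2;

  for (int it = 0; it < niter; ++it) {
    int i0 = it * minibatch;
    int bsz = std::min(minibatch, N - i0);
    mat dW1(arma::size(W1), arma::fill::zeros);
    mat dW2(arma::size(W2), arma::fill::zeros);
    mat dWf(arma::size(Wf), arma::fill::zeros);
    arma::rowvec db1(dm.nf, arma::fill::zeros), db2(dm.nf, arma::fill::zeros);
    arma::vec dbf(2, arma::fill::zeros);
    arma::rowvec dg1(dm.nf, arma::fill::zeros), dbe1(dm.nf, arma::fill::zeros);
    arma::rowvec dg2(dm.nf, arma::fill::zeros), dbe2(dm.nf, arma::fill::zeros);
    arma::rowvec dg3(dm.nf, arma::fill::zeros), dbe3(dm.nf, arma::fill::zeros);

    double wsum = 0.0;
    for (int i = 0; i < bsz; ++i) wsum += classw[y[order[i0 + i] - 1]];
    double loss = 0.0; int ncorrect = 0;

    for (int c0 = 0; c0 < bsz; c0 += bn_chunk) {
      int nc = std::min(bn_chunk, bsz - c0);
      std::vector<int> ids(nc);
      for (int i = 0; i < nc; ++i) ids[i] = order[i0 + c0 + i] - 1;
      // ---------- forward ----------
      gather_chunk(xp, dm.npix, ids, X);
      im2col3(X, dm.H, dm.W, nc, cols);
      Z1 = cols * W1;
      Z1.each_row() += b1;
      BNStats st1 = bn_stats_train(Z1, rm1, rv1, bn_mom);
      bn_relu_forward(Z1, A1, st1, g1, be1);
      pool2x2(A1, dm.H, dm.W, nc, P1, I1);
      im2col3(P1, dm.Hp, dm.Wp, nc, cols);
      Z2 = cols * W2;
      Z2.each_row() += b2;
      BNStats st2 = bn_stats_train(Z2, rm2, rv2, bn_mom);
      bn_relu_forward(Z2, A2, st2, g2, be2);
      pool2x2(A2, dm.Hp, dm.Wp, nc, P2, I2);
      BNStats st3 = bn_stats_train(P2, rm3, rv3, bn_mom);
      bn_relu_forward(P2, A3, st3, g3, be3);

      mat dlogits(2, nc);
      for (int i = 0; i < nc; ++i) {
        int yi = y[ids[i]];
        mat f = A3.rows((uword)i * dm.npq, (uword)(i + 1) * dm.npq - 1);
        vec fv = arma::vectorise(f);
        vec logit = Wf.t() * fv + bf;
        float mx = logit.max();
        vec e = arma::exp(logit - mx);
        vec p = e / arma::accu(e);
        double w = classw[yi];
        loss += -w * std::log(std::max((double)p(yi), 1e-30));
        if ((p(1) > p(0) ? 1 : 0) == yi) ++ncorrect;
        vec dl = p; dl(yi) -= 1.0f;
        dl *= (float)(w / wsum);
        dlogits.col(i) = dl;
        dWf += fv * dl.t();
        dbf += arma::conv_to<arma::vec>::from(dl);
      }
      // ---------- backward ----------
      dA3.set_size(arma::size(A3));
      for (int i = 0; i < nc; ++i) {
        vec df = Wf * dlogits.col(i);
        dA3.rows((uword)i * dm.npq, (uword)(i + 1) * dm.npq - 1) =
          mat(df.memptr(), dm.npq, dm.nf);
      }
      relu_mask(dA3, A3);
      bn_backward(dA3, P2, st3, g3, dg3, dbe3);          // dA3 -> dP2
      dA2.zeros(A2.n_rows, dm.nf);                       // pool2 backward
      for (int ch = 0; ch < dm.nf; ++ch) {
        const float *s = dA3.colptr(ch);
        const uword *ix = I2.colptr(ch);
        float *d = dA2.colptr(ch);
        for (uword q = 0; q < dA3.n_rows; ++q) d[ix[q]] += s[q];
      }
      relu_mask(dA2, A2);
      bn_backward(dA2, Z2, st2, g2, dg2, dbe2);          // dA2 -> dZ2
      im2col3(P1, dm.Hp, dm.Wp, nc, cols);               // conv2 backward
      dW2 += cols.t() * dA2;
      db2 += arma::conv_to<arma::rowvec>::from(arma::sum(dA2, 0));
      conv_bwd_data(dA2, W2, dm.Hp, dm.Wp, nc, dP1);
      dA1.zeros(A1.n_rows, dm.nf);                       // pool1 backward
      for (int ch = 0; ch < dm.nf; ++ch) {
        const float *s = dP1.colptr(ch);
        const uword *ix = I1.colptr(ch);
        float *d = dA1.colptr(ch);
        for (uword q = 0; q < dP1.n_rows; ++q) d[ix[q]] += s[q];
      }
      relu_mask(dA1, A1);
      bn_backward(dA1, Z1, st1, g1, dg1, dbe1);          // dA1 -> dZ1
      im2col3(X, dm.H, dm.W, nc, cols);                  // conv1 backward
      dW1 += cols.t() * dA1;
      db1 += arma::conv_to<arma::rowvec>::from(arma::sum(dA1, 0));
      Rcpp::checkUserInterrupt();
    }
    // ---------- SGDM update (L2 decay on weights, not biases/BN) --------
    if (l2 > 0) {
      dW1 += (float)l2 * W1; dW2 += (float)l2 * W2; dWf += (float)l2 * Wf;
    }
    vW1 = (float)momentum * vW1 - (float)lr * dW1;  W1 += vW1;
    vb1 = (float)momentum * vb1 - (float)lr * arma::conv_to<rowvec>::from(db1);
    b1 += vb1;
    vW2 = (float)momentum * vW2 - (float)lr * dW2;  W2 += vW2;
    vb2 = (float)momentum * vb2 - (float)lr * arma::conv_to<rowvec>::from(db2);
    b2 += vb2;
    vWf = (float)momentum * vWf - (float)lr * dWf;  Wf += vWf;
    vbf = (float)momentum * vbf - (float)lr * arma::conv_to<vec>::from(dbf);
    bf += vbf;
    vg1 = (float)momentum * vg1 - (float)lr * arma::conv_to<rowvec>::from(dg1);
    g1 += vg1;
    vbe1 = (float)momentum * vbe1 - (float)lr * arma::conv_to<rowvec>::from(dbe1);
    be1 += vbe1;
    vg2 = (float)momentum * vg2 - (float)lr * arma::conv_to<rowvec>::from(dg2);
    g2 += vg2;
    vbe2 = (float)momentum * vbe2 - (float)lr * arma::conv_to<rowvec>::from(dbe2);
    be2 += vbe2;
    vg3 = (float)momentum * vg3 - (float)lr * arma::conv_to<rowvec>::from(dg3);
    g3 += vg3;
    vbe3 = (float)momentum * vbe3 - (float)lr * arma::conv_to<rowvec>::from(dbe3);
    be3 += vbe3;

    it_loss[it] = loss / wsum;
    it_acc[it] = (double)ncorrect / bsz;
  }

  List outp = clone(par);
  outp["W1"] = W1; outp["b1"] = b1; outp["W2"] = W2; outp["b2"] = b2;
  outp["Wf"] = Wf; outp["bf"] = bf;
  outp["g1"] = g1; outp["be1"] = be1; outp["g2"] = g2; outp["be2"] = be2;
  outp["g3"] = g3; outp["be3"] = be3;
  outp["rm1"] = rm1; outp["rv1"] = rv1; outp["rm2"] = rm2; outp["rv2"] = rv2;
  outp["rm3"] = rm3; outp["rv3"] = rv3;
  List outv = clone(vel);
  outv["W1"] = vW1; outv["b1"] = vb1; outv["W2"] = vW2; outv["b2"] = vb2;
  outv["Wf"] = vWf; outv["bf"] = vbf;
  outv["g1"] = vg1; outv["be1"] = vbe1; outv["g2"] = vg2; outv["be2"] = vbe2;
  outv["g3"] = vg3; outv["be3"] = vbe3;
  return List::create(_["par"] = outp, _["vel"] = outv,
                      _["loss"] = it_loss, _["acc"] = it_acc);
}

// Recompute BN population statistics with frozen weights (three passes:
// each BN layer's statistics are estimated over the whole set using the
// already-finalized statistics of the layers before it).  Standard
// post-training recalibration: running averages lag the weights when
// training saturates in few iterations, which breaks inference-mode
// normalization.
// [[Rcpp::export]]
List cnn_bn_recalibrate_cpp(List par, NumericVector x) {
  Dims dm = get_dims(par);
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3 || xd[0] != dm.H || xd[1] != dm.W)
    stop("input shape does not match network input layer");
  int N = xd[2];
  if (N < 1) stop("recalibration needs at least one image");
  LOAD_PARAMS
  arma::fvec xf = to_float(x);
  const float *xp = xf.memptr();
  int chunk = auto_chunk(dm, 32);

  mat X, cols, Z, P;
  arma::umat idx;
  for (int pass = 1; pass <= 3; ++pass) {
    arma::rowvec s(dm.nf, arma::fill::zeros), q(dm.nf, arma::fill::zeros);
    double n = 0;
    for (int i0 = 0; i0 < N; i0 += chunk) {
      std::vector<int> ids;
      for (int i = i0; i < std::min(N, i0 + chunk); ++i) ids.push_back(i);
      int nc = ids.size();
      gather_chunk(xp, dm.npix, ids, X);
      im2col3(X, dm.H, dm.W, nc, cols);
      Z = cols * W1;
      Z.each_row() += b1;
      if (pass == 1) {
        s += arma::conv_to<arma::rowvec>::from(arma::sum(Z, 0));
        q += arma::conv_to<arma::rowvec>::from(arma::sum(arma::square(Z), 0));
        n += Z.n_rows;
        continue;
      }
      bn_relu_infer(Z, g1, be1, rm1, rv1);
      pool2x2(Z, dm.H, dm.W, nc, P, idx);
      im2col3(P, dm.Hp, dm.Wp, nc, cols);
      Z = cols * W2;
      Z.each_row() += b2;
      if (pass == 2) {
        s += arma::conv_to<arma::rowvec>::from(arma::sum(Z, 0));
        q += arma::conv_to<arma::rowvec>::from(arma::sum(arma::square(Z), 0));
        n += Z.n_rows;
        continue;
      }
      bn_relu_infer(Z, g2, be2, rm2, rv2);
      pool2x2(Z, dm.Hp, dm.Wp, nc, P, idx);
      s += arma::conv_to<arma::rowvec>::from(arma::sum(P, 0));
      q += arma::conv_to<arma::rowvec>::from(arma::sum(arma::square(P), 0));
      n += P.n_rows;
    }
    arma::rowvec mu = s / n;
    arma::rowvec var = arma::clamp(q / n - arma::square(mu), 0.0,
                                   arma::datum::inf);
    if (pass == 1) {
      rm1 = arma::conv_to<rowvec>::from(mu);
      rv1 = arma::conv_to<rowvec>::from(var);
    } else if (pass == 2) {
      rm2 = arma::conv_to<rowvec>::from(mu);
      rv2 = arma::conv_to<rowvec>::from(var);
    } else {
      rm3 = arma::conv_to<rowvec>::from(mu);
      rv3 = arma::conv_to<rowvec>::from(var);
    }
    Rcpp::checkUserInterrupt();
  }
  List outp = clone(par);
  outp["rm1"] = rm1; outp["rv1"] = rv1;
  outp["rm2"] = rm2; outp["rv2"] = rv2;
  outp["rm3"] = rm3; outp["rv3"] = rv3;
  return outp;
}
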