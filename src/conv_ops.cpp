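// Low-level convolution / pooling primitives for the detector's small
// convolutional networks. All convolutions are stride-1, zero-padded
// ("same"), odd square kernels; pooling is non-overlapping.
//
// Weight layout contract (shared with the R layer): a conv weight is a
// (C_in * k * k) x C_out matrix whose rows are ordered as
//   for c in 0..C_in-1: for dj in -p..p: for di in -p..p
// i.e. input channel slowest, then kernel column offset, then row offset.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col_same(const arma::cube& X, const int k) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices, p = k / 2;
  arma::mat out(H * (arma::uword)W, C * k * k, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        // valid destination window for shift (di, dj)
        const int r0 = std::max(0, -di), r1 = std::min(H - 1, H - 1 - di);
        const int c0 = std::max(0, -dj), c1 = std::min(W - 1, W - 1 - dj);
        arma::mat tmp(H, W, arma::fill::zeros);
        tmp.submat(r0, c0, r1, c1) =
          X.slice(c).submat(r0 + di, c0 + dj, r1 + di, c1 + dj);
        out.col(col++) = arma::vectorise(tmp);
      }
    }
  }
  return out;
}

static void col2im_same_add(arma::cube& acc, const arma::mat& M, const int k) {
  const int H = acc.n_rows, W = acc.n_cols, C = acc.n_slices, p = k / 2;
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const int r0 = std::max(0, -di), r1 = std::min(H - 1, H - 1 - di);
        const int c0 = std::max(0, -dj), c1 = std::min(W - 1, W - 1 - dj);
        arma::mat tmp(M.colptr(col), H, W);
        acc.slice(c).submat(r0 + di, c0 + dj, r1 + di, c1 + dj) +=
          tmp.submat(r0, c0, r1, c1);
        ++col;
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& X, const arma::mat& W,
                      const arma::vec& b, const int k) {
  const int H = X.n_rows, Wd = X.n_cols, Cout = W.n_cols;
  arma::mat cols = im2col_same(X, k);
  arma::mat Y = cols * W;          // (H*W) x Cout
  Y.each_row() += b.t();
  arma::cube out(H, Wd, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(Y.col(c), H, Wd);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::cube& X, const arma::mat& W,
                         const arma::cube& dY, const int k) {
  const int H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices;
  const int Cout = dY.n_slices;
  arma::mat G(H * (arma::uword)Wd, Cout);
  for (int c = 0; c < Cout; ++c) G.col(c) = arma::vectorise(dY.slice(c));
  arma::mat cols = im2col_same(X, k);
  arma::mat dW = cols.t() * G;                 // (Cin*k*k) x Cout
  arma::vec db = arma::sum(G, 0).t();
  arma::mat M = G * W.t();                     // (H*W) x (Cin*k*k)
  arma::cube dX(H, Wd, Cin, arma::fill::zeros);
  col2im_same_add(dX, M, k);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int h = H / 2, w = W / 2;
  arma::cube Y(h, w, C);
  arma::cube idx(h, w, C);  // linear index (0-based, i + H*j) of the argmax
  for (int c = 0; c < C; ++c) {
    const arma::mat& S = X.slice(c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        double best = S(i0, j0);
        int bi = i0, bj = j0;
        if (S(i0 + 1, j0) > best) { best = S(i0 + 1, j0); bi = i0 + 1; bj = j0; }
        if (S(i0, j0 + 1) > best) { best = S(i0, j0 + 1); bi = i0; bj = j0 + 1; }
        if (S(i0 + 1, j0 + 1) > best) { best = S(i0 + 1, j0 + 1); bi = i0 + 1; bj = j0 + 1; }
        Y(i, j, c) = best;
        idx(i, j, c) = bi + H * (double)bj;
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const arma::cube& dY, const arma::cube& idx,
                                 const int H, const int W) {
  const int h = dY.n_rows, w = dY.n_cols, C = dY.n_slices;
  arma::cube dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const int lin = (int)idx(i, j, c);
        dX(lin % H, lin / H, c) += dY(i, j, c);
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool(const arma::cube& X, const int f) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int h = H / f, w = W / f;
  arma::cube Y(h, w, C, arma::fill::zeros);
  const double inv = 1.0 / (f * (double)f);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        Y(i, j, c) = inv * arma::accu(
          X.slice(c).submat(f * i, f * j, f * i + f - 1, f * j + f - 1));
  return Y;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool_backward(const arma::cube& dY, const int f) {
  const int h = dY.n_rows, w = dY.n_cols, C = dY.n_slices;
  arma::cube dX(h * f, w * f, C);
  const double inv = 1.0 / (f * (double)f);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        dX.slice(c).submat(f * i, f * j, f * i + f - 1, f * j + f - 1)
          .fill(inv * dY(i, j, c));
  return dX;
}

// ---- fused pass for the 3-conv-block + 2-FC classifier ----------------
// One call per image: forward (and, when y_idx > 0, backward) through
// stem avg-pool, three conv/ReLU/max-pool blocks and the FC head.
// y_idx is the 1-based true-class index (0 = forward only); want_dx
// additionally returns the input-pixel gradient.

static arma::cube mat_to_cube(const arma::mat& M, int H, int W) {
  arma::cube out(H, W, M.n_cols);
  for (arma::uword c = 0; c < M.n_cols; ++c)
    out.slice(c) = arma::reshape(M.col(c), H, W);
  return out;
}

static arma::mat cube_to_mat(const arma::cube& X) {
  arma::mat out(X.n_rows * X.n_cols, X.n_slices);
  for (arma::uword c = 0; c < X.n_slices; ++c)
    out.col(c) = arma::vectorise(X.slice(c));
  return out;
}

// [[Rcpp::export]]
List cpp_cnn_pass(const arma::cube& X0, const int stem,
                  const arma::mat& W1, const arma::vec& b1,
                  const arma::mat& W2, const arma::vec& b2,
                  const arma::mat& W3, const arma::vec& b3,
                  const arma::mat& W4, const arma::vec& b4,
                  const arma::mat& W5, const arma::vec& b5,
                  const int y_idx, const bool want_dx) {
  arma::cube s0 = stem > 1 ? cpp_avgpool(X0, stem) : X0;

  arma::mat cols1 = im2col_same(s0, 3);
  arma::mat A1 = cols1 * W1; A1.each_row() += b1.t();
  arma::cube r1 = mat_to_cube(A1, s0.n_rows, s0.n_cols);
  r1.transform([](double v) { return v > 0 ? v : 0.0; });
  List p1 = cpp_maxpool2(r1);
  arma::cube p1y = p1["y"], p1i = p1["idx"];

  arma::mat cols2 = im2col_same(p1y, 3);
  arma::mat A2 = cols2 * W2; A2.each_row() += b2.t();
  arma::cube r2 = mat_to_cube(A2, p1y.n_rows, p1y.n_cols);
  r2.transform([](double v) { return v > 0 ? v : 0.0; });
  List p2 = cpp_maxpool2(r2);
  arma::cube p2y = p2["y"], p2i = p2["idx"];

  arma::mat cols3 = im2col_same(p2y, 3);
  arma::mat A3 = cols3 * W3; A3.each_row() += b3.t();
  arma::cube r3 = mat_to_cube(A3, p2y.n_rows, p2y.n_cols);
  r3.transform([](double v) { return v > 0 ? v : 0.0; });
  List p3 = cpp_maxpool2(r3);
  arma::cube p3y = p3["y"], p3i = p3["idx"];

  arma::vec f = arma::vectorise(cube_to_mat(p3y));
  arma::vec hpre = W4 * f + b4;
  arma::vec h = arma::clamp(hpre, 0.0, arma::datum::inf);
  arma::vec z = W5 * h + b5;
  z -= z.max();
  arma::vec p = arma::exp(z);
  p /= arma::accu(p);
  if (y_idx == 0) return List::create(_["p"] = p);

  const double loss = -std::log(p(y_idx - 1) + 1e-12);
  arma::vec dz = p; dz(y_idx - 1) -= 1.0;
  arma::mat dW5 = dz * h.t();
  arma::vec dh = W5.t() * dz;
  dh.elem(arma::find(hpre <= 0)).zeros();
  arma::mat dW4 = dh * f.t();
  arma::vec df = W4.t() * dh;

  arma::cube dp3 = arma::cube(df.memptr(), p3y.n_rows, p3y.n_cols,
                              p3y.n_slices);
  arma::cube d3c = cpp_maxpool2_backward(dp3, p3i, r3.n_rows, r3.n_cols);
  arma::mat G3 = cube_to_mat(d3c);
  G3.elem(arma::find(A3 <= 0)).zeros();
  arma::mat dW3 = cols3.t() * G3;
  arma::vec db3 = arma::sum(G3, 0).t();
  arma::cube dp2(p2y.n_rows, p2y.n_cols, p2y.n_slices, arma::fill::zeros);
  col2im_same_add(dp2, G3 * W3.t(), 3);

  arma::cube d2c = cpp_maxpool2_backward(dp2, p2i, r2.n_rows, r2.n_cols);
  arma::mat G2 = cube_to_mat(d2c);
  G2.elem(arma::find(A2 <= 0)).zeros();
  arma::mat dW2 = cols2.t() * G2;
  arma::vec db2 = arma::sum(G2, 0).t();
  arma::cube dp1(p1y.n_rows, p1y.n_cols, p1y.n_slices, arma::fill::zeros);
  col2im_same_add(dp1, G2 * W2.t(), 3);

  arma::cube d1c = cpp_maxpool2_backward(dp1, p1i, r1.n_rows, r1.n_cols);
  arma::mat G1 = cube_to_mat(d1c);
  G1.elem(arma::find(A1 <= 0)).zeros();
  arma::mat dW1 = cols1.t() * G1;
  arma::vec db1 = arma::sum(G1, 0).t();

  List out = List::create(
    _["p"] = p, _["loss"] = loss,
    _["dW1"] = dW1, _["db1"] = db1, _["dW2"] = dW2, _["db2"] = db2,
    _["dW3"] = dW3, _["db3"] = db3, _["dW4"] = dW4, _["db4"] = dh,
    _["dW5"] = dW5, _["db5"] = dz);
  if (want_dx) {
    arma::cube ds0(s0.n_rows, s0.n_cols, s0.n_slices, arma::fill::zeros);
    col2im_same_add(ds0, G1 * W1.t(), 3);
    out["dx"] = stem > 1 ? cpp_avgpool_backward(ds0, stem) : ds0;
  }
  return out;
}

// ---- batched training/inference steps ---------------------------------
// Process a whole minibatch per call: forward/backward for every image,
// accumulating parameter gradients in place. Xs stacks the (centered)
// single-channel images as an H x W x B cube; y is 1-based class indices.

// [[Rcpp::export]]
List cpp_cnn_batch_train(const arma::cube& Xs, const int stem,
                         const arma::mat& W1, const arma::vec& b1,
                         const arma::mat& W2, const arma::vec& b2,
                         const arma::mat& W3, const arma::vec& b3,
                         const arma::mat& W4, const arma::vec& b4,
                         const arma::mat& W5, const arma::vec& b5,
                         const arma::ivec& y) {
  const int B = Xs.n_slices;
  arma::mat gW1(arma::size(W1), arma::fill::zeros);
  arma::vec gb1(b1.n_elem, arma::fill::zeros);
  arma::mat gW2(arma::size(W2), arma::fill::zeros);
  arma::vec gb2(b2.n_elem, arma::fill::zeros);
  arma::mat gW3(arma::size(W3), arma::fill::zeros);
  arma::vec gb3(b3.n_elem, arma::fill::zeros);
  arma::mat gW4(arma::size(W4), arma::fill::zeros);
  arma::vec gb4(b4.n_elem, arma::fill::zeros);
  arma::mat gW5(arma::size(W5), arma::fill::zeros);
  arma::vec gb5(b5.n_elem, arma::fill::zeros);
  double loss_sum = 0.0;

  for (int bimg = 0; bimg < B; ++bimg) {
    arma::cube X0(const_cast<double*>(Xs.slice(bimg).memptr()),
                  Xs.n_rows, Xs.n_cols, 1, false, true);
    arma::cube s0 = stem > 1 ? cpp_avgpool(X0, stem) : X0;

    arma::mat cols1 = im2col_same(s0, 3);
    arma::mat A1 = cols1 * W1; A1.each_row() += b1.t();
    arma::cube r1 = mat_to_cube(A1, s0.n_rows, s0.n_cols);
    r1.transform([](double v) { return v > 0 ? v : 0.0; });
    List p1 = cpp_maxpool2(r1);
    arma::cube p1y = p1["y"], p1i = p1["idx"];

    arma::mat cols2 = im2col_same(p1y, 3);
    arma::mat A2 = cols2 * W2; A2.each_row() += b2.t();
    arma::cube r2 = mat_to_cube(A2, p1y.n_rows, p1y.n_cols);
    r2.transform([](double v) { return v > 0 ? v : 0.0; });
    List p2 = cpp_maxpool2(r2);
    arma::cube p2y = p2["y"], p2i = p2["idx"];

    arma::mat cols3 = im2col_same(p2y, 3);
    arma::mat A3 = cols3 * W3; A3.each_row() += b3.t();
    arma::cube r3 = mat_to_cube(A3, p2y.n_rows, p2y.n_cols);
    r3.transform([](double v) { return v > 0 ? v : 0.0; });
    List p3 = cpp_maxpool2(r3);
    arma::cube p3y = p3["y"], p3i = p3["idx"];

    arma::vec f = arma::vectorise(cube_to_mat(p3y));
    arma::vec hpre = W4 * f + b4;
    arma::vec h = arma::clamp(hpre, 0.0, arma::datum::inf);
    arma::vec z = W5 * h + b5;
    z -= z.max();
    arma::vec p = arma::exp(z);
    p /= arma::accu(p);
    const int yi = y(bimg);
    loss_sum += -std::log(p(yi - 1) + 1e-12);

    arma::vec dz = p; dz(yi - 1) -= 1.0;
    gW5 += dz * h.t(); gb5 += dz;
    arma::vec dh = W5.t() * dz;
    dh.elem(arma::find(hpre <= 0)).zeros();
    gW4 += dh * f.t(); gb4 += dh;
    arma::vec df = W4.t() * dh;

    arma::cube dp3(df.memptr(), p3y.n_rows, p3y.n_cols, p3y.n_slices);
    arma::cube d3c = cpp_maxpool2_backward(dp3, p3i, r3.n_rows, r3.n_cols);
    arma::mat G3 = cube_to_mat(d3c);
    G3.elem(arma::find(A3 <= 0)).zeros();
    gW3 += cols3.t() * G3; gb3 += arma::sum(G3, 0).t();
    arma::cube dp2(p2y.n_rows, p2y.n_cols, p2y.n_slices, arma::fill::zeros);
    col2im_same_add(dp2, G3 * W3.t(), 3);

    arma::cube d2c = cpp_maxpool2_backward(dp2, p2i, r2.n_rows, r2.n_cols);
    arma::mat G2 = cube_to_mat(d2c);
    G2.elem(arma::find(A2 <= 0)).zeros();
    gW2 += cols2.t() * G2; gb2 += arma::sum(G2, 0).t();
    arma::cube dp1(p1y.n_rows, p1y.n_cols, p1y.n_slices, arma::fill::zeros);
    col2im_same_add(dp1, G2 * W2.t(), 3);

    arma::cube d1c = cpp_maxpool2_backward(dp1, p1i, r1.n_rows, r1.n_cols);
    arma::mat G1 = cube_to_mat(d1c);
    G1.elem(arma::find(A1 <= 0)).zeros();
    gW1 += cols1.t() * G1; gb1 += arma::sum(G1, 0).t();
  }
  return List::create(
    _["loss_sum"] = loss_sum,
    _["dW1"] = gW1, _["db1"] = gb1, _["dW2"] = gW2, _["db2"] = gb2,
    _["dW3"] = gW3, _["db3"] = gb3, _["dW4"] = gW4, _["db4"] = gb4,
    _["dW5"] = gW5, _["db5"] = gb5);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_batch_prob(const arma::cube& Xs, const int stem,
                             const arma::mat& W1, const arma::vec& b1,
                             const arma::mat& W2, const arma::vec& b2,
                             const arma::mat& W3, const arma::vec& b3,
                             const arma::mat& W4, const arma::vec& b4,
                             const arma::mat& W5, const arma::vec& b5) {
  const int B = Xs.n_slices;
  arma::mat out(B, 2);
  for (int bimg = 0; bimg < B; ++bimg) {
    arma::cube X0(const_cast<double*>(Xs.slice(bimg).memptr()),
                  Xs.n_rows, Xs.n_cols, 1, false, true);
    arma::cube s0 = stem > 1 ? cpp_avgpool(X0, stem) : X0;
    arma::mat cols1 = im2col_same(s0, 3);
    arma::mat A1 = cols1 * W1; A1.each_row() += b1.t();
    arma::cube r1 = mat_to_cube(A1, s0.n_rows, s0.n_cols);
    r1.transform([](double v) { return v > 0 ? v : 0.0; });
    arma::cube p1y = cpp_maxpool2(r1)["y"];
    arma::mat cols2 = im2col_same(p1y, 3);
    arma::mat A2 = cols2 * W2; A2.each_row() += b2.t();
    arma::cube r2 = mat_to_cube(A2, p1y.n_rows, p1y.n_cols);
    r2.transform([](double v) { return v > 0 ? v : 0.0; });
    arma::cube p2y = cpp_maxpool2(r2)["y"];
    arma::mat cols3 = im2col_same(p2y, 3);
    arma::mat A3 = cols3 * W3; A3.each_row() += b3.t();
    arma::cube r3 = mat_to_cube(A3, p2y.n_rows, p2y.n_cols);
    r3.transform([](double v) { return v > 0 ? v : 0.0; });
    arma::cube p3y = cpp_maxpool2(r3)["y"];
    arma::vec f = arma::vectorise(cube_to_mat(p3y));
    arma::vec h = arma::clamp(W4 * f + b4, 0.0, arma::datum::inf);
    arma::vec z = W5 * h + b5;
    z -= z.max();
    arma::vec p = arma::exp(z);
    p /= arma::accu(p);
    out(bimg, 0) = p(0); out(bimg, 1) = p(1);
  }
  return out;
}
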