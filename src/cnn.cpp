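// Small convolutional reference classifier, trained with Adam on binary
// cross-entropy.  Topology: 64x64 single-channel input (the 128x128 frame
// mean-pooled 2x2 in R), a stack of 3x3
// conv blocks (conv -> batch norm -> ReLU -> 2x2 max pool) whose channel
// counts are read from the weight shapes, one hidden dense layer, sigmoid
// output.  Forward/backward run batched (one GEMM per layer per batch);
// batch norm uses batch statistics during training and accumulated running
// statistics at inference.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const int IN_H = 64;
static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

// batched im2col for 3x3/pad-1 kernels: input activations for sample b,
// channel c live in slice b*C + c; output column j*H + i + b*H*W holds the
// 9*C patch values centred at (i, j) of sample b.
static mat im2col3(const cube &a, int C) {
  const int H = a.n_rows, W = a.n_cols;
  const int B = a.n_slices / C;
  mat cols(9 * C, (size_t)H * W * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * H * W;
    for (int c = 0; c < C; ++c) {
      const mat &s = a.slice(b * C + c);
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int row = c * 9 + (dj + 1) * 3 + (di + 1);
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int j = j0; j < j1; ++j) {
            const double *src = s.colptr(j + dj);
            double *dst = cols.colptr(off + (size_t)j * H) + row;
            for (int i = i0; i < i1; ++i)
              dst[(size_t)i * cols.n_rows] = src[i + di];
          }
        }
      }
    }
  }
  return cols;
}

static void col2im3(const mat &dcols, cube &da, int C) {
  const int H = da.n_rows, W = da.n_cols;
  const int B = da.n_slices / C;
  da.zeros();
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * H * W;
    for (int c = 0; c < C; ++c) {
      mat &s = da.slice(b * C + c);
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int row = c * 9 + (dj + 1) * 3 + (di + 1);
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int j = j0; j < j1; ++j) {
            double *dst = s.colptr(j + dj);
            const double *src = dcols.colptr(off + (size_t)j * H) + row;
            for (int i = i0; i < i1; ++i)
              dst[i + di] += src[(size_t)i * dcols.n_rows];
          }
        }
      }
    }
  }
}

// batched 2x2 max pool with argmax bookkeeping
static cube maxpool2(const cube &a, ucube &idx) {
  const int H = a.n_rows, W = a.n_cols, S = a.n_slices;
  cube out(H / 2, W / 2, S);
  idx.set_size(H / 2, W / 2, S);
  for (int s = 0; s < S; ++s) {
    const mat &m = a.slice(s);
    for (int j = 0; j < W / 2; ++j) {
      for (int i = 0; i < H / 2; ++i) {
        double best = m(2 * i, 2 * j);
        unsigned bi = (2 * j) * H + 2 * i;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = m(2 * i + di, 2 * j + dj);
            if (v > best) { best = v; bi = (2 * j + dj) * H + 2 * i + di; }
          }
        out(i, j, s) = best;
        idx(i, j, s) = bi;
      }
    }
  }
  return out;
}

struct Params {
  std::vector<mat> Wc;              // conv weights (C_out x 9*C_in)
  std::vector<vec> bn_gamma, bn_beta, bn_rmean, bn_rvar;
  mat W_fc1, W_fc2;
  vec b_fc1, b_fc2;
};

static Params params_from_list(const Rcpp::List &w) {
  Params p;
  Rcpp::List conv_w = w["conv_w"], gam = w["bn_gamma"], bet = w["bn_beta"],
             rme = w["bn_rmean"], rva = w["bn_rvar"];
  for (int i = 0; i < conv_w.size(); ++i) {
    p.Wc.push_back(Rcpp::as<mat>(conv_w[i]));
    p.bn_gamma.push_back(Rcpp::as<vec>(gam[i]));
    p.bn_beta.push_back(Rcpp::as<vec>(bet[i]));
    p.bn_rmean.push_back(Rcpp::as<vec>(rme[i]));
    p.bn_rvar.push_back(Rcpp::as<vec>(rva[i]));
  }
  p.W_fc1 = Rcpp::as<mat>(w["W_fc1"]); p.b_fc1 = Rcpp::as<vec>(w["b_fc1"]);
  p.W_fc2 = Rcpp::as<mat>(w["W_fc2"]); p.b_fc2 = Rcpp::as<vec>(w["b_fc2"]);
  return p;
}

static Rcpp::List params_to_list(const Params &p) {
  const size_t L = p.Wc.size();
  Rcpp::List conv_w(L), gam(L), bet(L), rme(L), rva(L);
  for (size_t i = 0; i < L; ++i) {
    conv_w[i] = p.Wc[i];
    gam[i] = p.bn_gamma[i]; bet[i] = p.bn_beta[i];
    rme[i] = p.bn_rmean[i]; rva[i] = p.bn_rvar[i];
  }
  return Rcpp::List::create(
      Rcpp::Named("conv_w") = conv_w,
      Rcpp::Named("bn_gamma") = gam, Rcpp::Named("bn_beta") = bet,
      Rcpp::Named("bn_rmean") = rme, Rcpp::Named("bn_rvar") = rva,
      Rcpp::Named("W_fc1") = p.W_fc1, Rcpp::Named("b_fc1") = p.b_fc1,
      Rcpp::Named("W_fc2") = p.W_fc2, Rcpp::Named("b_fc2") = p.b_fc2);
}

struct BlockCache {
  mat cols;          // im2col of the block input
  mat z;             // conv output before BN   (F x B*H*W)
  mat zhat;          // normalized              (F x B*H*W)
  vec mu, var;       // batch statistics per channel
  cube post;         // after BN + ReLU, shaped (H, W, B*F)
  ucube idx;         // pool argmax
  cube pool;
};

struct Cache {
  std::vector<BlockCache> blocks;
  mat flat, z1, a1;  // dense head (columns = samples)
  rowvec z2, p;
};

// rows of `m` are channels; columns are batch*spatial positions
static void bn_forward(const mat &z, const vec &gamma, const vec &beta,
                       bool train, const vec &rmean, const vec &rvar,
                       mat &zhat, vec &mu, vec &var_out, mat &out) {
  const int F = z.n_rows;
  zhat.set_size(size(z));
  out.set_size(size(z));
  mu.set_size(F); var_out.set_size(F);
  for (int f = 0; f < F; ++f) {
    double m, v;
    if (train) {
      m = mean(z.row(f));
      v = mean(square(z.row(f) - m));
    } else {
      m = rmean(f); v = rvar(f);
    }
    mu(f) = m; var_out(f) = v;
    zhat.row(f) = (z.row(f) - m) / std::sqrt(v + BN_EPS);
    out.row(f) = gamma(f) * zhat.row(f) + beta(f);
  }
}

// forward a batch; X columns are samples (IN_H*IN_H each)
static rowvec forward_batch(Params &p, const mat &X, bool train, Cache *cache) {
  Cache local;
  Cache &c = cache ? *cache : local;
  const int B = X.n_cols;
  const int L = (int)p.Wc.size();
  c.blocks.resize(L);

  // input channel count from the first conv weight (9 taps per channel)
  const int C0 = p.Wc[0].n_cols / 9;
  cube act(IN_H, IN_H, (size_t)B * C0);
  for (int b = 0; b < B; ++b)
    for (int c0 = 0; c0 < C0; ++c0)
      act.slice((size_t)b * C0 + c0) =
          reshape(X.col(b).subvec((size_t)c0 * IN_H * IN_H,
                                  (size_t)(c0 + 1) * IN_H * IN_H - 1),
                  IN_H, IN_H);

  int C_in = C0;
  for (int l = 0; l < L; ++l) {
    BlockCache &bc = c.blocks[l];
    const int H = act.n_rows, W = act.n_cols;
    const int F = p.Wc[l].n_rows;
    bc.cols = im2col3(act, C_in);
    bc.z = p.Wc[l] * bc.cols;
    mat normed;
    bn_forward(bc.z, p.bn_gamma[l], p.bn_beta[l], train,
               p.bn_rmean[l], p.bn_rvar[l], bc.zhat, bc.mu, bc.var, normed);
    if (train) {
      p.bn_rmean[l] = BN_MOMENTUM * p.bn_rmean[l] + (1 - BN_MOMENTUM) * bc.mu;
      p.bn_rvar[l] = BN_MOMENTUM * p.bn_rvar[l] + (1 - BN_MOMENTUM) * bc.var;
    }
    normed.transform([](double v) { return v > 0.0 ? v : 0.0; });
    // reshape (F x B*H*W) into cube slices (b*F + f)
    bc.post.set_size(H, W, (size_t)B * F);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F; ++f)
        bc.post.slice((size_t)b * F + f) =
            reshape(normed.row(f).subvec((size_t)b * H * W,
                                         (size_t)(b + 1) * H * W - 1), H, W);
    bc.pool = maxpool2(bc.post, bc.idx);
    act = bc.pool;
    C_in = F;
  }

  const int feat = act.n_rows * act.n_cols * C_in;
  c.flat.set_size(feat, B);
  for (int b = 0; b < B; ++b) {
    const cube sub = act.slices((size_t)b * C_in, (size_t)(b + 1) * C_in - 1);
    c.flat.col(b) = vectorise(sub);
  }
  c.z1 = p.W_fc1 * c.flat;
  c.z1.each_col() += p.b_fc1;
  c.a1 = c.z1;
  c.a1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  c.z2 = p.W_fc2 * c.a1 + p.b_fc2(0);
  c.p = 1.0 / (1.0 + exp(-c.z2));
  return c.p;
}

struct Grads {
  std::vector<mat> Wc;
  std::vector<vec> gamma, beta;
  mat W_fc1, W_fc2;
  vec b_fc1, b_fc2;
};

static Grads zeros_grads(const Params &p) {
  Grads g;
  for (size_t l = 0; l < p.Wc.size(); ++l) {
    g.Wc.push_back(zeros<mat>(size(p.Wc[l])));
    g.gamma.push_back(zeros<vec>(p.bn_gamma[l].n_elem));
    g.beta.push_back(zeros<vec>(p.bn_gamma[l].n_elem));
  }
  g.W_fc1 = zeros<mat>(size(p.W_fc1)); g.b_fc1 = zeros<vec>(p.b_fc1.n_elem);
  g.W_fc2 = zeros<mat>(size(p.W_fc2)); g.b_fc2 = zeros<vec>(p.b_fc2.n_elem);
  return g;
}

// dz2 = dL/dz2 per sample (rowvec)
static void backward_batch(const Params &p, const Cache &c, const rowvec &dz2,
                           Grads &g) {
  const int B = dz2.n_elem;
  const int L = (int)p.Wc.size();

  g.W_fc2 = dz2 * c.a1.t();
  g.b_fc2(0) = accu(dz2);
  mat da1 = p.W_fc2.t() * dz2;
  mat dz1 = da1 % conv_to<mat>::from(c.z1 > 0.0);
  g.W_fc1 = dz1 * c.flat.t();
  g.b_fc1 = sum(dz1, 1);
  mat dflat = p.W_fc1.t() * dz1;

  // unflatten into pooled-activation gradient of the last block
  const BlockCache &last = c.blocks[L - 1];
  cube dpool(last.pool.n_rows, last.pool.n_cols, last.pool.n_slices,
             fill::zeros);
  {
    const int C = p.Wc[L - 1].n_rows;
    const int per = dpool.n_rows * dpool.n_cols * C;
    for (int b = 0; b < B; ++b) {
      cube sub(dflat.colptr(b), dpool.n_rows, dpool.n_cols, C, false, true);
      (void)per;
      for (int f = 0; f < C; ++f)
        dpool.slice((size_t)b * C + f) = sub.slice(f);
    }
  }

  for (int l = L - 1; l >= 0; --l) {
    const BlockCache &bc = c.blocks[l];
    const int F = p.Wc[l].n_rows;
    const int H = bc.post.n_rows, W = bc.post.n_cols;
    // pool + ReLU backward into dnormed (F x B*H*W)
    mat dnormed(F, (size_t)B * H * W, fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F; ++f) {
        const size_t s = (size_t)b * F + f;
        const mat &post = bc.post.slice(s);
        for (unsigned j = 0; j < bc.pool.n_cols; ++j)
          for (unsigned i = 0; i < bc.pool.n_rows; ++i) {
            const unsigned fl = bc.idx(i, j, s);
            if (post(fl % H, fl / H) > 0.0)
              dnormed(f, (size_t)b * H * W + fl) += dpool(i, j, s);
          }
      }
    // batch-norm backward per channel
    mat dz(F, dnormed.n_cols);
    const double N = (double)dnormed.n_cols;
    for (int f = 0; f < F; ++f) {
      const rowvec dy = dnormed.row(f);
      g.gamma[l](f) += dot(dy, bc.zhat.row(f));
      g.beta[l](f) += accu(dy);
      const double inv_sd = 1.0 / std::sqrt(bc.var(f) + BN_EPS);
      const rowvec dzh = dy * p.bn_gamma[l](f);
      const double m_dzh = mean(dzh);
      const double m_dzh_zh = mean(dzh % bc.zhat.row(f));
      dz.row(f) = inv_sd * (dzh - m_dzh - bc.zhat.row(f) * m_dzh_zh);
      (void)N;
    }
    g.Wc[l] += dz * bc.cols.t();
    if (l > 0) {
      mat dcols = p.Wc[l].t() * dz;
      const BlockCache &prev = c.blocks[l - 1];
      dpool.set_size(prev.pool.n_rows, prev.pool.n_cols, prev.pool.n_slices);
      col2im3(dcols, dpool, p.Wc[l - 1].n_rows);
    }
  }
}

template <typename T>
static void adam_step(T &w, const T &g, T &m, T &v, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  T mh = m / (1.0 - std::pow(b1, t));
  T vh = v / (1.0 - std::pow(b2, t));
  w -= lr * mh / (sqrt(vh) + eps);
}

struct AdamState { Grads m, v; };

static void adam_all(Params &p, const Grads &g, AdamState &st, double lr,
                     double t) {
  for (size_t l = 0; l < p.Wc.size(); ++l) {
    adam_step(p.Wc[l], g.Wc[l], st.m.Wc[l], st.v.Wc[l], lr, t);
    adam_step(p.bn_gamma[l], g.gamma[l], st.m.gamma[l], st.v.gamma[l], lr, t);
    adam_step(p.bn_beta[l], g.beta[l], st.m.beta[l], st.v.beta[l], lr, t);
  }
  adam_step(p.W_fc1, g.W_fc1, st.m.W_fc1, st.v.W_fc1, lr, t);
  adam_step(p.b_fc1, g.b_fc1, st.m.b_fc1, st.v.b_fc1, lr, t);
  adam_step(p.W_fc2, g.W_fc2, st.m.W_fc2, st.v.W_fc2, lr, t);
  adam_step(p.b_fc2, g.b_fc2, st.m.b_fc2, st.v.b_fc2, lr, t);
}

static vec predict_all(Params p, const mat &X, int chunk = 32) {
  vec out(X.n_cols);
  for (unsigned s = 0; s < X.n_cols; s += chunk) {
    const unsigned e = std::min((unsigned)X.n_cols, s + chunk) - 1;
    rowvec pr = forward_batch(p, X.cols(s, e), false, nullptr);
    out.subvec(s, e) = pr.t();
  }
  return out;
}

static double accuracy(const vec &probs, const vec &y) {
  uvec pred = conv_to<uvec>::from(probs > 0.5);
  uvec lab = conv_to<uvec>::from(y > 0.5);
  return (double)accu(pred == lab) / (double)y.n_elem;
}

// [[Rcpp::export]]
arma::vec cpp_cnn_predict(const Rcpp::List &weights, const arma::mat &X) {
  Params p = params_from_list(weights);
  return predict_all(p, X);
}

// Mini-batch training.  `batches` is a (batch_size x iterations) matrix of
// 0-based column indices into Xtr (drawn in R so all randomness flows from
// the R RNG).  `lrs` holds the per-update learning rate.  Validation
// accuracy is computed every `eval_every` updates and at the final update;
// the strictly-best (earliest on ties) checkpoint is returned.
// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(const Rcpp::List &weights,
                         const arma::mat &Xtr, const arma::vec &ytr,
                         const arma::mat &Xval, const arma::vec &yval,
                         const arma::imat &batches,
                         int eval_every, const arma::vec &lrs) {
  Params p = params_from_list(weights);
  AdamState st{zeros_grads(p), zeros_grads(p)};
  const int iterations = batches.n_cols;
  const int batch_size = batches.n_rows;

  Params best = p;
  double best_acc = -1.0;
  int best_iter = 0;
  std::vector<double> tr_iter, tr_loss, tr_acc;

  mat Xb(Xtr.n_rows, batch_size);
  vec yb(batch_size);
  for (int it = 1; it <= iterations; ++it) {
    for (int b = 0; b < batch_size; ++b) {
      Xb.col(b) = Xtr.col(batches(b, it - 1));
      yb(b) = ytr(batches(b, it - 1));
    }
    Cache c;
    rowvec probs = forward_batch(p, Xb, true, &c);
    double loss = 0.0;
    rowvec dz2(batch_size);
    for (int b = 0; b < batch_size; ++b) {
      const double pr = std::min(std::max(probs(b), 1e-12), 1.0 - 1e-12);
      loss += -(yb(b) * std::log(pr) + (1.0 - yb(b)) * std::log(1.0 - pr));
      dz2(b) = (probs(b) - yb(b)) / batch_size;
    }
    loss /= batch_size;
    Grads g = zeros_grads(p);
    backward_batch(p, c, dz2, g);
    adam_all(p, g, st, lrs(it - 1), (double)it);

    if (it % eval_every == 0 || it == iterations) {
      const double acc = accuracy(predict_all(p, Xval), yval);
      tr_iter.push_back((double)it); tr_loss.push_back(loss); tr_acc.push_back(acc);
      if (acc > best_acc) { best_acc = acc; best = p; best_iter = it; }
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("best_weights") = params_to_list(best),
      Rcpp::Named("final_weights") = params_to_list(p),
      Rcpp::Named("best_val_accuracy") = best_acc,
      Rcpp::Named("best_iteration") = best_iter,
      Rcpp::Named("n_updates") = iterations,
      Rcpp::Named("trace") = Rcpp::DataFrame::create(
          Rcpp::Named("iteration") = tr_iter,
          Rcpp::Named("loss") = tr_loss,
          Rcpp::Named("val_accuracy") = tr_acc));
}
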