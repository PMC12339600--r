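// Sequence-to-last LSTM networks for variable-length designs.
// Input: 5-channel sequences (scaled payoffs/delays + signed choice).
// Architecture: LSTM(H) -> dense ReLU chain -> linear or softmax head.
// Training: Adam with global-norm gradient clipping and step decay of
// the learning rate; sequences are sorted by length and packed so each
// batch processes only the columns still active at a timestep, with
// batch composition reshuffled every epoch inside length buckets.
// Single precision; the gate GEMM is fused over the stacked [x; h]
// input and writes activations in place into the BPTT trace.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

struct LstmNet {
  fmat W;               // (4H x (C+H)), gate order i, f, g, o
  fvec b;               // (4H)
  std::vector<fmat> Wd; // dense chain incl. head: (d_out x d_in)
  std::vector<fvec> bd;
  int H = 0, C = 0;
};

template <typename M>
void rand_init(M& A, float lim, std::mt19937& rng) {
  std::uniform_real_distribution<float> U(-lim, lim);
  for (arma::uword i = 0; i < A.n_elem; ++i) A(i) = U(rng);
}

LstmNet init_lstm(int C, int H, const arma::ivec& dense, int d_out,
                  std::mt19937& rng) {
  LstmNet net;
  net.H = H;
  net.C = C;
  net.W.set_size(4 * H, C + H);
  rand_init(net.W, std::sqrt(6.0f / (C + 2 * H)), rng);
  net.b.zeros(4 * H);
  net.b.subvec(H, 2 * H - 1).fill(3.0f);  // forget-gate bias: start near open so early trials persist to the final state
  int d_in = H;
  std::vector<int> outs;
  for (arma::uword l = 0; l < dense.n_elem; ++l) outs.push_back(dense[l]);
  outs.push_back(d_out);
  for (int o : outs) {
    fmat Wl(o, d_in);
    rand_init(Wl, std::sqrt(6.0f / (d_in + o)), rng);
    net.Wd.push_back(Wl);
    net.bd.push_back(fvec(o, arma::fill::zeros));
    d_in = o;
  }
  return net;
}

// Padé(7,6) rational tanh, clamped where tanh is 1 to float precision;
// ~1e-6 accurate on the active range and several times cheaper than
// libm, which dominates the cost of the gate nonlinearities otherwise.
inline float fast_tanh(float x) {
  if (x > 7.9f) return 1.0f;
  if (x < -7.9f) return -1.0f;
  const float x2 = x * x;
  const float p = x * (135135.0f + x2 * (17325.0f + x2 * (378.0f + x2)));
  const float q = 135135.0f + x2 * (62370.0f + x2 * (3150.0f + x2 * 28.0f));
  return p / q;
}
inline float fast_sigmoid(float x) {
  return 0.5f * (1.0f + fast_tanh(0.5f * x));
}
inline void sigmoid_inplace(fmat& A) {
  A.transform([](float x) { return fast_sigmoid(x); });
}
inline void tanh_inplace(fmat& A) {
  A.transform([](float x) { return fast_tanh(x); });
}
inline fmat fast_tanh_mat(const fmat& A) {
  fmat B = A;
  tanh_inplace(B);
  return B;
}

// workspace reused across batches
struct Work {
  arma::fcube G;       // 4H x B x T, activated gates (i,f,g,o)
  arma::fcube Cc, Hc;  // H x B x T
  fmat XH;             // (C+H) x B, stacked input for the fused GEMM
  fmat Hlast;
  std::vector<int> active;
};

// forward through one packed batch; seq columns sorted by decreasing
// length; when trace is false only Hlast is produced
void lstm_forward(const LstmNet& net, const std::vector<fmat>& seqs,
                  const std::vector<int>& idx, int Tmax, bool trace,
                  Work& wk) {
  const int B = idx.size();
  const int H = net.H, C = net.C;
  wk.active.assign(Tmax, 0);
  for (int j = 0; j < B; ++j) {
    const int len = seqs[idx[j]].n_cols;
    for (int t = 0; t < len; ++t)
      if (wk.active[t] < j + 1) wk.active[t] = j + 1;
  }
  wk.Hlast.zeros(H, B);
  fmat Hbuf(H, B, arma::fill::zeros), Cbuf(H, B, arma::fill::zeros);
  fmat Z;
  for (int t = 0; t < Tmax; ++t) {
    const int a = wk.active[t];
    if (a == 0) break;
    wk.XH.set_size(C + H, a);
    for (int j = 0; j < a; ++j)
      wk.XH.submat(0, j, C - 1, j) = seqs[idx[j]].col(t);
    wk.XH.rows(C, C + H - 1) = Hbuf.cols(0, a - 1);
    Z = net.W * wk.XH;
    Z.each_col() += net.b;
    fmat I = Z.rows(0, H - 1);
    fmat F = Z.rows(H, 2 * H - 1);
    fmat G = Z.rows(2 * H, 3 * H - 1);
    fmat O = Z.rows(3 * H, 4 * H - 1);
    sigmoid_inplace(I);
    sigmoid_inplace(F);
    tanh_inplace(G);
    sigmoid_inplace(O);
    fmat Cn = F % Cbuf.cols(0, a - 1) + I % G;
    fmat Hn = O % fast_tanh_mat(Cn);
    if (trace) {
      wk.G.slice(t).cols(0, a - 1) =
        arma::join_cols(arma::join_cols(I, F), arma::join_cols(G, O));
      wk.Cc.slice(t).cols(0, a - 1) = Cn;
      wk.Hc.slice(t).cols(0, a - 1) = Hn;
    }
    for (int j = 0; j < a; ++j)
      if ((int)seqs[idx[j]].n_cols == t + 1) wk.Hlast.col(j) = Hn.col(j);
    Hbuf.cols(0, a - 1) = Hn;
    Cbuf.cols(0, a - 1) = Cn;
  }
}

void dense_forward(const LstmNet& net, const fmat& Hlast, int task,
                   std::vector<fmat>& acts, fmat& out) {
  const size_t L = net.Wd.size();
  acts.assign(L, fmat());
  fmat A = Hlast;
  for (size_t l = 0; l < L; ++l) {
    acts[l] = A;
    A = net.Wd[l] * A;
    A.each_col() += net.bd[l];
    if (l + 1 < L)
      A.transform([](float x) { return x > 0.0f ? x : 0.0f; });
  }
  if (task == 1) {  // softmax per column
    A.each_row() -= arma::max(A, 0);
    A = arma::exp(A);
    A.each_row() /= arma::sum(A, 0);
  }
  out = A;
}

struct Grads {
  fmat gW;
  fvec gb;
  std::vector<fmat> gWd;
  std::vector<fvec> gbd;
};

}  // namespace

// [[Rcpp::export]]
List lstm_train_cpp(const List& seqs_r, const arma::mat& Y_r,
                    const List& vseqs_r, const arma::mat& Yval_r,
                    int H, const arma::ivec& dense, int task, int epochs,
                    int batch, double lr, double l2, double clip,
                    int seed, int crop_len, double crop_frac) {
  const int n = seqs_r.size();
  std::vector<fmat> seqs(n);
  int C = 0;
  for (int i = 0; i < n; ++i) {
    seqs[i] = arma::conv_to<fmat>::from(as<arma::mat>(seqs_r[i]));
    C = seqs[i].n_rows;
  }
  fmat Y = arma::conv_to<fmat>::from(Y_r).t();  // d_out x n
  const int nval = vseqs_r.size();
  std::vector<fmat> vseqs(nval);
  for (int i = 0; i < nval; ++i)
    vseqs[i] = arma::conv_to<fmat>::from(as<arma::mat>(vseqs_r[i]));
  fmat Yval;
  if (nval > 0) Yval = arma::conv_to<fmat>::from(Yval_r).t();
  const int d_out = Y.n_rows;

  std::seed_seq ss{seed, 101};
  std::mt19937 rng(ss);
  LstmNet net = init_lstm(C, H, dense, d_out, rng);
  const size_t LD = net.Wd.size();

  // sort by decreasing length; length buckets for epoch reshuffling
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return seqs[a].n_cols > seqs[b].n_cols;
  });
  const int bucket = std::max(1, 8 * batch);

  Grads m, v;
  m.gW.zeros(arma::size(net.W)); v.gW = m.gW;
  m.gb.zeros(arma::size(net.b)); v.gb = m.gb;
  for (size_t l = 0; l < LD; ++l) {
    m.gWd.push_back(fmat(arma::size(net.Wd[l]), arma::fill::zeros));
    v.gWd.push_back(m.gWd[l]);
    m.gbd.push_back(fvec(arma::size(net.bd[l]), arma::fill::zeros));
    v.gbd.push_back(m.gbd[l]);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long step = 0;

  int Tcap = 0;
  for (int i = 0; i < n; ++i) Tcap = std::max(Tcap, (int)seqs[i].n_cols);
  Work wk;
  wk.G.set_size(4 * H, batch, Tcap);
  wk.Cc.set_size(H, batch, Tcap);
  wk.Hc.set_size(H, batch, Tcap);

  arma::vec train_loss(epochs), val_loss(epochs);
  fmat out;
  std::vector<fmat> acts;

  // Crop-curriculum epochs: trials are exchangeable within a
  // participant, so a random contiguous window of a session is itself
  // a valid (shorter) session from the same generative model. Early
  // epochs train on cheap short windows; final epochs use the full
  // sequences so the recurrent state dynamics cover test-time lengths.
  const int n_crop = (crop_len > 0)
    ? (int)std::floor(crop_frac * epochs) : 0;
  std::vector<fmat> crops(crop_len > 0 ? n : 0);
  std::uniform_int_distribution<int> ULen(20, std::max(20, crop_len));

  for (int ep = 0; ep < epochs; ++ep) {
    const bool cropped = ep < n_crop;
    if (cropped) {
      for (int i = 0; i < n; ++i) {
        const int len = seqs[i].n_cols;
        const int L = std::min(len, ULen(rng));
        std::uniform_int_distribution<int> UStart(0, len - L);
        const int s0 = UStart(rng);
        crops[i] = seqs[i].cols(s0, s0 + L - 1);
      }
    }
    const std::vector<fmat>& train_seqs = cropped ? crops : seqs;
    // reshuffle inside length buckets, then rebuild the batch list
    for (int start = 0; start < n; start += bucket) {
      const int end = std::min(n, start + bucket);
      std::shuffle(order.begin() + start, order.begin() + end, rng);
    }
    std::vector<std::vector<int>> batches;
    for (int start = 0; start < n; start += batch) {
      std::vector<int> bidx(order.begin() + start,
                            order.begin() + std::min(n, start + batch));
      std::stable_sort(bidx.begin(), bidx.end(), [&](int a, int b) {
        return train_seqs[a].n_cols > train_seqs[b].n_cols;
      });
      batches.push_back(bidx);
    }
    std::shuffle(batches.begin(), batches.end(), rng);

    // learning rate decays in two steps over the run
    double lr_ep = lr;
    if (ep >= (4 * epochs) / 5) lr_ep = lr * 0.25;
    else if (ep >= (3 * epochs) / 5) lr_ep = lr * 0.5;

    double ep_loss = 0.0;
    long ep_count = 0;
    for (auto& bidx : batches) {
      const int B = bidx.size();
      int Tmax = 0;
      for (int j : bidx) Tmax = std::max(Tmax, (int)train_seqs[j].n_cols);
      lstm_forward(net, train_seqs, bidx, Tmax, true, wk);
      dense_forward(net, wk.Hlast, task, acts, out);

      fmat Yb(d_out, B);
      for (int j = 0; j < B; ++j) Yb.col(j) = Y.col(bidx[j]);
      fmat delta;
      if (task == 1) {
        ep_loss += -arma::accu(Yb % arma::log(out + 1e-30f));
        delta = (out - Yb) / (float)B;
      } else {
        ep_loss += arma::accu(arma::square(out - Yb));
        delta = 2.0f * (out - Yb) / (float)(B * d_out);
      }
      ep_count += B;

      Grads g;
      g.gWd.resize(LD); g.gbd.resize(LD);
      for (int l = (int)LD - 1; l >= 0; --l) {
        g.gWd[l] = delta * acts[l].t() + (float)l2 * net.Wd[l];
        g.gbd[l] = arma::sum(delta, 1);
        fmat dh = net.Wd[l].t() * delta;
        if (l > 0)
          delta = dh % arma::conv_to<fmat>::from(acts[l] > 0.0f);
        else
          delta = dh;  // gradient into Hlast
      }
      const fmat& dHlast = delta;  // H x B

      g.gW.zeros(arma::size(net.W));
      g.gb.zeros(arma::size(net.b));
      fmat dH(H, B, arma::fill::zeros), dC(H, B, arma::fill::zeros);
      fmat dZ, XH;
      for (int t = Tmax - 1; t >= 0; --t) {
        const int a = wk.active[t];
        if (a == 0) continue;
        for (int j = 0; j < a; ++j)
          if ((int)train_seqs[bidx[j]].n_cols == t + 1)
            dH.col(j) += dHlast.col(j);
        const fmat dHa = dH.cols(0, a - 1);
        const fmat I = wk.G.slice(t).submat(0, 0, H - 1, a - 1);
        const fmat F = wk.G.slice(t).submat(H, 0, 2 * H - 1, a - 1);
        const fmat G = wk.G.slice(t).submat(2 * H, 0, 3 * H - 1, a - 1);
        const fmat O = wk.G.slice(t).submat(3 * H, 0, 4 * H - 1, a - 1);
        const fmat tC = fast_tanh_mat(wk.Cc.slice(t).cols(0, a - 1));
        const fmat dCa = dC.cols(0, a - 1) +
          dHa % O % (1.0f - arma::square(tC));
        fmat Cprev(H, a, arma::fill::zeros);
        if (t > 0) Cprev = wk.Cc.slice(t - 1).cols(0, a - 1);
        dZ.set_size(4 * H, a);
        dZ.rows(0, H - 1) = (dCa % G) % I % (1.0f - I);
        dZ.rows(H, 2 * H - 1) = (dCa % Cprev) % F % (1.0f - F);
        dZ.rows(2 * H, 3 * H - 1) = (dCa % I) % (1.0f - arma::square(G));
        dZ.rows(3 * H, 4 * H - 1) = (dHa % tC) % O % (1.0f - O);
        XH.set_size(C + H, a);
        for (int j = 0; j < a; ++j)
          XH.submat(0, j, C - 1, j) = train_seqs[bidx[j]].col(t);
        if (t > 0)
          XH.rows(C, C + H - 1) = wk.Hc.slice(t - 1).cols(0, a - 1);
        else
          XH.rows(C, C + H - 1).zeros();
        g.gW += dZ * XH.t();
        g.gb += arma::sum(dZ, 1);
        const fmat dXH = net.W.t() * dZ;
        dH.cols(0, a - 1) = dXH.rows(C, C + H - 1);
        dC.cols(0, a - 1) = dCa % F;
      }
      g.gW /= (float)B; g.gb /= (float)B;
      for (size_t l = 0; l < LD; ++l) {
        g.gWd[l] /= (float)B;
        g.gbd[l] /= (float)B;
      }
      g.gW += (float)l2 * net.W;

      double nrm2 = arma::accu(arma::square(g.gW)) +
        arma::accu(arma::square(g.gb));
      for (size_t l = 0; l < LD; ++l)
        nrm2 += arma::accu(arma::square(g.gWd[l])) +
          arma::accu(arma::square(g.gbd[l]));
      const double nrm = std::sqrt(nrm2);
      if (clip > 0 && nrm > clip) {
        const float sc = (float)(clip / nrm);
        g.gW *= sc; g.gb *= sc;
        for (size_t l = 0; l < LD; ++l) { g.gWd[l] *= sc; g.gbd[l] *= sc; }
      }

      ++step;
      const float corr = (float)(lr_ep *
        std::sqrt(1.0 - std::pow(b2, step)) / (1.0 - std::pow(b1, step)));
      auto adam = [&](fmat& W, fmat& mW, fmat& vW, const fmat& gW) {
        mW = b1 * mW + (1 - b1) * gW;
        vW = b2 * vW + (1 - b2) * arma::square(gW);
        W -= corr * mW / (arma::sqrt(vW) + eps);
      };
      auto adamv = [&](fvec& W, fvec& mW, fvec& vW, const fvec& gW) {
        mW = b1 * mW + (1 - b1) * gW;
        vW = b2 * vW + (1 - b2) * arma::square(gW);
        W -= corr * mW / (arma::sqrt(vW) + eps);
      };
      adam(net.W, m.gW, v.gW, g.gW);
      adamv(net.b, m.gb, v.gb, g.gb);
      for (size_t l = 0; l < LD; ++l) {
        adam(net.Wd[l], m.gWd[l], v.gWd[l], g.gWd[l]);
        adamv(net.bd[l], m.gbd[l], v.gbd[l], g.gbd[l]);
      }
    }
    train_loss[ep] = ep_loss / (task == 1 ? (double)ep_count
                                          : (double)(ep_count * d_out));

    if (nval > 0) {
      double vl = 0.0;
      std::vector<int> vorder(nval);
      for (int i = 0; i < nval; ++i) vorder[i] = i;
      std::stable_sort(vorder.begin(), vorder.end(), [&](int a, int b) {
        return vseqs[a].n_cols > vseqs[b].n_cols;
      });
      for (int start = 0; start < nval; start += batch) {
        std::vector<int> bidx(vorder.begin() + start,
                              vorder.begin() + std::min(nval, start + batch));
        int Tmax = 0;
        for (int j : bidx) Tmax = std::max(Tmax, (int)vseqs[j].n_cols);
        lstm_forward(net, vseqs, bidx, Tmax, false, wk);
        dense_forward(net, wk.Hlast, task, acts, out);
        fmat Yb(d_out, bidx.size());
        for (size_t j = 0; j < bidx.size(); ++j) Yb.col(j) = Yval.col(bidx[j]);
        if (task == 1)
          vl += -arma::accu(Yb % arma::log(out + 1e-30f));
        else
          vl += arma::accu(arma::square(out - Yb));
      }
      val_loss[ep] = vl / (task == 1 ? (double)nval
                                     : (double)(nval * d_out));
    } else {
      val_loss[ep] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }

  List Wd(LD), bd(LD);
  for (size_t l = 0; l < LD; ++l) {
    Wd[l] = arma::conv_to<arma::mat>::from(net.Wd[l]);
    bd[l] = arma::conv_to<arma::vec>::from(net.bd[l]);
  }
  return List::create(
    _["W"] = arma::conv_to<arma::mat>::from(net.W),
    _["b"] = arma::conv_to<arma::vec>::from(net.b),
    _["Wd"] = Wd, _["bd"] = bd,
    _["train_loss"] = train_loss, _["val_loss"] = val_loss);
}

// [[Rcpp::export]]
arma::mat lstm_predict_cpp(const List& params, const List& seqs_r,
                           int task, int batch) {
  LstmNet net;
  net.W = arma::conv_to<fmat>::from(as<arma::mat>(params["W"]));
  net.b = arma::conv_to<fvec>::from(as<arma::vec>(params["b"]));
  List Wd = params["Wd"], bd = params["bd"];
  for (int l = 0; l < Wd.size(); ++l) {
    net.Wd.push_back(arma::conv_to<fmat>::from(as<arma::mat>(Wd[l])));
    net.bd.push_back(arma::conv_to<fvec>::from(as<arma::vec>(bd[l])));
  }
  net.H = net.Wd[0].n_cols;
  net.C = net.W.n_cols - net.H;

  const int n = seqs_r.size();
  std::vector<fmat> seqs(n);
  for (int i = 0; i < n; ++i)
    seqs[i] = arma::conv_to<fmat>::from(as<arma::mat>(seqs_r[i]));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return seqs[a].n_cols > seqs[b].n_cols;
  });
  const int d_out = net.Wd.back().n_rows;
  arma::mat out(n, d_out);
  Work wk;
  fmat o;
  std::vector<fmat> acts;
  for (int start = 0; start < n; start += batch) {
    std::vector<int> bidx(order.begin() + start,
                          order.begin() + std::min(n, start + batch));
    int Tmax = 0;
    for (int j : bidx) Tmax = std::max(Tmax, (int)seqs[j].n_cols);
    lstm_forward(net, seqs, bidx, Tmax, false, wk);
    dense_forward(net, wk.Hlast, task, acts, o);
    for (size_t j = 0; j < bidx.size(); ++j)
      out.row(bidx[j]) = arma::conv_to<arma::rowvec>::from(o.col(j).t());
  }
  return out;
}
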