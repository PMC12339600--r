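// Feed-forward simulation-inversion networks: fully connected tanh
// hidden layers, linear (regression) or softmax (classification) head,
// Adam updates with L2 weight penalty, optional dropout on the last
// hidden layer (used both during training and, at inference, for
// Monte-Carlo-dropout posterior sampling).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> W;  // layer l: (d_in x d_out)
  std::vector<arma::rowvec> b;
};

Net init_net(int d_in, const arma::ivec& hidden, int d_out,
             std::mt19937& rng) {
  Net net;
  std::vector<int> sizes;
  sizes.push_back(d_in);
  for (arma::uword l = 0; l < hidden.n_elem; ++l) sizes.push_back(hidden[l]);
  sizes.push_back(d_out);
  for (size_t l = 0; l + 1 < sizes.size(); ++l) {
    const double lim = std::sqrt(6.0 / (sizes[l] + sizes[l + 1]));
    std::uniform_real_distribution<double> U(-lim, lim);
    arma::mat W(sizes[l], sizes[l + 1]);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = U(rng);
    net.W.push_back(W);
    net.b.push_back(arma::rowvec(sizes[l + 1], arma::fill::zeros));
  }
  return net;
}

// forward pass; activations[l] holds the input to layer l
void forward(const Net& net, const arma::mat& X, int task,
             std::vector<arma::mat>& act, arma::mat& out,
             const arma::rowvec* drop_mask = nullptr) {
  const size_t L = net.W.size();
  act.assign(L, arma::mat());
  arma::mat A = X;
  for (size_t l = 0; l < L; ++l) {
    act[l] = A;
    A = A * net.W[l];
    A.each_row() += net.b[l];
    if (l + 1 < L) {
      A = arma::tanh(A);
      if (drop_mask && l == L - 2) A.each_row() %= *drop_mask;
    }
  }
  if (task == 1) {  // softmax rows
    A.each_col() -= arma::max(A, 1);
    A = arma::exp(A);
    A.each_col() /= arma::sum(A, 1);
  }
  out = A;
}

}  // namespace

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::mat& Y,
                   const arma::mat& Xval, const arma::mat& Yval,
                   const arma::ivec& hidden, int task, int epochs,
                   int batch, double lr, double l2, double dropout,
                   int seed) {
  const int n = X.n_rows;
  const int d_out = Y.n_cols;
  std::seed_seq ss{seed, 17};
  std::mt19937 rng(ss);
  Net net = init_net(X.n_cols, hidden, d_out, rng);
  const size_t L = net.W.size();

  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::rowvec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
    vW[l] = mW[l];
    mb[l].zeros(net.b[l].n_elem);
    vb[l] = mb[l];
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  arma::vec train_loss(epochs), val_loss(epochs);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::uniform_real_distribution<double> U(0.0, 1.0);
  std::vector<arma::mat> act;
  arma::mat out;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    long ep_count = 0;
    for (int start = 0; start < n; start += batch) {
      const int bsz = std::min(batch, n - start);
      arma::uvec idx(bsz);
      for (int i = 0; i < bsz; ++i) idx[i] = order[start + i];
      arma::mat Xb = X.rows(idx), Yb = Y.rows(idx);

      // per-sample dropout mask on the last hidden layer
      arma::mat dmask;
      if (dropout > 0) {
        dmask.set_size(bsz, hidden[hidden.n_elem - 1]);
        for (arma::uword i = 0; i < dmask.n_elem; ++i)
          dmask(i) = (U(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      }

      // forward with stored activations
      act.assign(L, arma::mat());
      arma::mat A = Xb;
      for (size_t l = 0; l < L; ++l) {
        act[l] = A;
        A = A * net.W[l];
        A.each_row() += net.b[l];
        if (l + 1 < L) {
          A = arma::tanh(A);
          if (dropout > 0 && l == L - 2) A %= dmask;
        }
      }
      arma::mat delta;  // dLoss/dPreact of output layer
      if (task == 1) {
        A.each_col() -= arma::max(A, 1);
        A = arma::exp(A);
        A.each_col() /= arma::sum(A, 1);
        ep_loss += -arma::accu(Yb % arma::log(A + 1e-30));
        delta = (A - Yb) / bsz;
      } else {
        ep_loss += arma::accu(arma::square(A - Yb));
        delta = 2.0 * (A - Yb) / (bsz * d_out);
      }
      ep_count += bsz;

      ++step;
      const double corr =
        lr * std::sqrt(1.0 - std::pow(b2, step)) / (1.0 - std::pow(b1, step));
      for (int l = (int)L - 1; l >= 0; --l) {
        arma::mat gW = act[l].t() * delta + l2 * net.W[l];
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          arma::mat dh = delta * net.W[l].t();
          arma::mat h = act[l];  // tanh output (post-dropout)
          if (dropout > 0 && (size_t)l == L - 1) {
            dh %= dmask;
            h /= dmask.replace(0.0, 1.0);  // undo scaling for tanh'
          }
          delta = dh % (1.0 - arma::square(h));
        }
        mW[l] = b1 * mW[l] + (1 - b1) * gW;
        vW[l] = b2 * vW[l] + (1 - b2) * arma::square(gW);
        net.W[l] -= corr * mW[l] / (arma::sqrt(vW[l]) + eps);
        mb[l] = b1 * mb[l] + (1 - b1) * gb;
        vb[l] = b2 * vb[l] + (1 - b2) * arma::square(gb);
        net.b[l] -= corr * mb[l] / (arma::sqrt(vb[l]) + eps);
      }
    }
    train_loss[ep] = ep_loss / (task == 1 ? (double)ep_count
                                          : (double)(ep_count * d_out));
    if (Xval.n_rows > 0) {
      forward(net, Xval, task, act, out);
      if (task == 1)
        val_loss[ep] = -arma::accu(Yval % arma::log(out + 1e-30)) /
          (double)Xval.n_rows;
      else
        val_loss[ep] = arma::accu(arma::square(out - Yval)) /
          (double)(Xval.n_rows * d_out);
    } else {
      val_loss[ep] = NA_REAL;
    }
  }

  List Ws(L), bs(L);
  for (size_t l = 0; l < L; ++l) {
    Ws[l] = net.W[l];
    bs[l] = arma::vec(net.b[l].t());
  }
  return List::create(_["W"] = Ws, _["b"] = bs,
                      _["train_loss"] = train_loss,
                      _["val_loss"] = val_loss);
}

static Net net_from_lists(const List& Ws, const List& bs) {
  Net net;
  for (int l = 0; l < Ws.size(); ++l) {
    net.W.push_back(as<arma::mat>(Ws[l]));
    arma::vec bv = as<arma::vec>(bs[l]);
    net.b.push_back(bv.t());
  }
  return net;
}

// [[Rcpp::export]]
arma::mat mlp_predict_cpp(const List& Ws, const List& bs,
                          const arma::mat& X, int task) {
  Net net = net_from_lists(Ws, bs);
  std::vector<arma::mat> act;
  arma::mat out;
  forward(net, X, task, act, out);
  return out;
}

// Monte-Carlo-dropout forward passes. Each draw instantiates one
// thinned network (a single mask on the last hidden layer) and applies
// it to every row of X, so a draw is one coherent network applied to
// the whole dataset. Returns a cube: draws x rows(X) x outputs.
// [[Rcpp::export]]
arma::cube mlp_dropout_predict_cpp(const List& Ws, const List& bs,
                                   const arma::mat& X, int task,
                                   double dropout, int n_draws, int seed) {
  Net net = net_from_lists(Ws, bs);
  const size_t L = net.W.size();
  const int H = net.W[L - 1].n_rows;
  std::seed_seq ss{seed, 29};
  std::mt19937 rng(ss);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  arma::cube out(n_draws, X.n_rows, net.W[L - 1].n_cols);
  std::vector<arma::mat> act;
  arma::mat o;
  for (int s = 0; s < n_draws; ++s) {
    arma::rowvec mask(H);
    for (int h = 0; h < H; ++h)
      mask[h] = (U(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
    forward(net, X, task, act, o, &mask);
    out.row(s) = o;
  }
  return out;
}
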