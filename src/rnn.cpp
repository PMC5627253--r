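#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Elman recurrence, no bias terms:
//   h_t = tanh(W_in x_t + W_rec h_{t-1}),  h_0 = 0,  y = sigmoid(W_out h_T)
// X is a cube with dims (n_in, n_seq, T) so X.slice(t) is the contiguous
// n_in x n_seq input matrix at step t.

static mat forward_hidden(const cube& X, const mat& W_in, const mat& W_rec,
                          cube* H_store) {
  const uword T = X.n_slices, N = X.n_cols, nh = W_in.n_rows;
  mat h(nh, N, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    h = tanh(W_in * X.slice(t) + W_rec * h);
    if (H_store) H_store->slice(t) = h;
  }
  return h;
}

static rowvec sigmoid_row(const rowvec& z) {
  return 1.0 / (1.0 + exp(-z));
}

// [[Rcpp::export]]
arma::vec rnn_forward_cpp(const arma::cube& X, const arma::mat& W_in,
                          const arma::mat& W_rec, const arma::rowvec& W_out) {
  mat hT = forward_hidden(X, W_in, W_rec, nullptr);
  rowvec y = sigmoid_row(W_out * hT);
  return y.t();
}

static double wbce(const rowvec& yhat, const rowvec& y, const rowvec& w) {
  rowvec p = clamp(yhat, 1e-12, 1.0 - 1e-12);
  return accu(w % (-y % log(p) - (1.0 - y) % log(1.0 - p))) / accu(w);
}

// Full-batch gradient descent (with classical momentum) and
// backpropagation through time; optional early stopping on a held-out
// validation subset (best-validation weights kept). With an empty
// validation set the loss is monitored on the training data and the final
// weights are returned when patience never triggers.
// [[Rcpp::export]]
Rcpp::List rnn_train_cpp(const arma::cube& X, const arma::vec& y,
                         const arma::uvec& train_idx, const arma::uvec& val_idx,
                         arma::mat W_in, arma::mat W_rec, arma::rowvec W_out,
                         double lr, int max_epochs, int patience,
                         double pos_weight, double clip,
                         double momentum = 0.9,
                         double weight_decay = 0.0,
                         bool rank_loss = false) {
  const uword T = X.n_slices, nh = W_in.n_rows;
  const uword Ntr = train_idx.n_elem, Nva = val_idx.n_elem;

  cube Xtr(X.n_rows, Ntr, T), Xva(X.n_rows, Nva, T);
  for (uword t = 0; t < T; ++t) {
    Xtr.slice(t) = X.slice(t).cols(train_idx);
    if (Nva > 0) Xva.slice(t) = X.slice(t).cols(val_idx);
  }
  rowvec ytr = conv_to<rowvec>::from(y(train_idx));
  rowvec yva = Nva > 0 ? conv_to<rowvec>::from(y(val_idx)) : rowvec();
  rowvec wtr = ytr * (pos_weight - 1.0) + 1.0;
  rowvec wva = Nva > 0 ? rowvec(yva * (pos_weight - 1.0) + 1.0) : rowvec();
  double wsum = accu(wtr);

  mat bW_in = W_in, bW_rec = W_rec;
  rowvec bW_out = W_out;
  double best_val = datum::inf;
  int best_epoch = 0, stall = 0, epochs_run = 0;
  std::vector<double> val_hist;

  cube H(nh, Ntr, T);
  mat vW_in(size(W_in), fill::zeros), vW_rec(size(W_rec), fill::zeros);
  rowvec vW_out(size(W_out), fill::zeros);
  for (int ep = 1; ep <= max_epochs; ++ep) {
    epochs_run = ep;
    mat hT = forward_hidden(Xtr, W_in, W_rec, &H);
    rowvec zt = W_out * hT;
    rowvec yhat = sigmoid_row(zt);
    rowvec dz;
    if (rank_loss) {
      // pairwise logistic ranking loss over event/non-event pairs:
      // L = mean_{i in pos, j in neg} log(1 + exp(-(z_i - z_j)))
      uvec pos = find(ytr > 0.5), neg = find(ytr < 0.5);
      dz = rowvec(zt.n_elem, fill::zeros);
      double np = (double)(pos.n_elem * neg.n_elem);
      for (uword a = 0; a < pos.n_elem; ++a) {
        for (uword b = 0; b < neg.n_elem; ++b) {
          double s = 1.0 / (1.0 + std::exp(zt(pos(a)) - zt(neg(b))));
          dz(pos(a)) -= s / np;
          dz(neg(b)) += s / np;
        }
      }
    } else {
      dz = (yhat - ytr) % wtr / wsum;  // dL/d(logit), weighted mean BCE
    }

    mat gW_in(size(W_in), fill::zeros), gW_rec(size(W_rec), fill::zeros);
    rowvec gW_out = dz * hT.t();
    mat delta = (W_out.t() * dz) % (1.0 - square(hT));
    for (uword t = T; t-- > 0;) {
      gW_in += delta * Xtr.slice(t).t();
      if (t > 0) {
        gW_rec += delta * H.slice(t - 1).t();
        delta = (W_rec.t() * delta) % (1.0 - square(H.slice(t - 1)));
      }
    }
    if (weight_decay > 0) {
      gW_in += weight_decay * W_in;
      gW_rec += weight_decay * W_rec;
      gW_out += weight_decay * W_out;
    }
    double gn = std::sqrt(accu(square(gW_in)) + accu(square(gW_rec)) +
                          accu(square(gW_out)));
    double sc = (clip > 0 && gn > clip) ? clip / gn : 1.0;
    vW_in = momentum * vW_in - lr * sc * gW_in;
    vW_rec = momentum * vW_rec - lr * sc * gW_rec;
    vW_out = momentum * vW_out - lr * sc * gW_out;
    W_in += vW_in;
    W_rec += vW_rec;
    W_out += vW_out;

    if (Nva > 0) {
      mat hV = forward_hidden(Xva, W_in, W_rec, nullptr);
      double vloss = wbce(sigmoid_row(W_out * hV), yva, wva);
      val_hist.push_back(vloss);
      if (vloss < best_val - 1e-10) {
        best_val = vloss;
        best_epoch = ep;
        bW_in = W_in; bW_rec = W_rec; bW_out = W_out;
        stall = 0;
      } else if (++stall >= patience) break;
    } else {
      double tloss = wbce(yhat, ytr, wtr);  // pre-update, but free
      val_hist.push_back(tloss);
      best_val = tloss;
      best_epoch = ep;
      bW_in = W_in; bW_rec = W_rec; bW_out = W_out;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("W_in") = bW_in, Rcpp::Named("W_rec") = bW_rec,
      Rcpp::Named("W_out") = bW_out, Rcpp::Named("val_loss") = best_val,
      Rcpp::Named("epochs") = epochs_run,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("val_history") = val_hist);
}
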