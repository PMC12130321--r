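// Mini-batch SGD training loop for the matched linear/nonlinear multilayer
// perceptrons. Architecture per hidden layer: affine -> batch norm ->
// activation (softplus when nonlinear, identity otherwise) -> dropout;
// a single affine output unit. All randomness (initialisation, shuffling,
// dropout masks, oversampling draws) comes from R's RNG stream so that
// set.seed() in R makes training bit-reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

static arma::mat softplus_mat(const arma::mat& z) {
  // log(1 + exp(z)), stable for large |z|
  arma::mat out = z;
  out.transform([](double v) {
    if (v > 30.0) return v;
    if (v < -30.0) return std::exp(v);
    return std::log1p(std::exp(v));
  });
  return out;
}

static arma::mat sigmoid_mat(const arma::mat& z) {
  arma::mat out = z;
  out.transform([](double v) {
    if (v >= 0) return 1.0 / (1.0 + std::exp(-v));
    double e = std::exp(v);
    return e / (1.0 + e);
  });
  return out;
}

struct Layer {
  arma::mat W;      // fan_in x fan_out
  arma::rowvec b;
  arma::rowvec gamma, beta, run_mean, run_var; // batch norm
};

struct Net {
  std::vector<Layer> hidden;
  arma::vec w_out;   // last hidden width x 1
  double b_out;
  bool batch_norm;
  bool nonlinear;
};

// Forward pass in inference mode (running BN stats, no dropout).
static arma::vec net_infer(const Net& net, const arma::mat& X) {
  arma::mat A = X;
  for (size_t l = 0; l < net.hidden.size(); ++l) {
    const Layer& L = net.hidden[l];
    arma::mat Z = A * L.W;
    Z.each_row() += L.b;
    if (net.batch_norm) {
      arma::rowvec inv_sd = 1.0 / arma::sqrt(L.run_var + BN_EPS);
      Z.each_row() -= L.run_mean;
      Z.each_row() %= inv_sd % L.gamma;
      Z.each_row() += L.beta;
    }
    A = net.nonlinear ? softplus_mat(Z) : Z;
  }
  arma::vec out = A * net.w_out + net.b_out;
  return out;
}

static double squared_pearson(const arma::vec& a, const arma::vec& b) {
  double sa = arma::stddev(a), sb = arma::stddev(b);
  if (!std::isfinite(sa) || !std::isfinite(sb) || sa == 0 || sb == 0) return 0.0;
  double r = arma::as_scalar(arma::cor(a, b));
  if (!std::isfinite(r)) return 0.0;
  return r * r;
}

// Fisher-Yates shuffle driven by R's RNG
static void shuffle_uvec(arma::uvec& v) {
  for (arma::uword i = v.n_elem; i > 1; --i) {
    arma::uword j = static_cast<arma::uword>(unif_rand() * i);
    if (j >= i) j = i - 1;
    std::swap(v[i - 1], v[j]);
  }
}

// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(const arma::mat& X,
                   const arma::vec& y,
                   const arma::uvec& train_idx,  // 0-based
                   const arma::uvec& val_idx,    // 0-based
                   const IntegerVector& hidden_sizes,
                   const bool nonlinear,
                   const double dropout_rate,
                   const double learning_rate,
                   const int batch_size,
                   const bool batch_norm,
                   const int patience,
                   const int max_epochs,
                   const bool binary,
                   const bool oversample) {
  const arma::uword p = X.n_cols;
  const arma::uword n_train = train_idx.n_elem;
  const int k = hidden_sizes.size();

  Net net;
  net.batch_norm = batch_norm;
  net.nonlinear = nonlinear;
  net.hidden.resize(k);
  arma::uword fan_in = p;
  for (int l = 0; l < k; ++l) {
    arma::uword fan_out = hidden_sizes[l];
    Layer& L = net.hidden[l];
    double sd = std::sqrt(2.0 / (double)(fan_in + fan_out));
    L.W.set_size(fan_in, fan_out);
    for (arma::uword j = 0; j < fan_out; ++j)
      for (arma::uword i = 0; i < fan_in; ++i)
        L.W(i, j) = norm_rand() * sd;
    L.b = arma::rowvec(fan_out, arma::fill::zeros);
    L.gamma = arma::rowvec(fan_out, arma::fill::ones);
    L.beta = arma::rowvec(fan_out, arma::fill::zeros);
    L.run_mean = arma::rowvec(fan_out, arma::fill::zeros);
    L.run_var = arma::rowvec(fan_out, arma::fill::ones);
    fan_in = fan_out;
  }
  {
    double sd = std::sqrt(2.0 / (double)(fan_in + 1));
    net.w_out.set_size(fan_in);
    for (arma::uword i = 0; i < fan_in; ++i) net.w_out[i] = norm_rand() * sd;
    net.b_out = 0.0;
  }

  // case/control index pools for oversampling
  arma::uvec case_pool, control_pool;
  if (binary && oversample) {
    std::vector<arma::uword> cs, ct;
    for (arma::uword i = 0; i < n_train; ++i) {
      if (y[train_idx[i]] > 0.5) cs.push_back(train_idx[i]);
      else ct.push_back(train_idx[i]);
    }
    case_pool = arma::uvec(cs);
    control_pool = arma::uvec(ct);
    if (case_pool.n_elem == 0 || control_pool.n_elem == 0)
      stop("oversampling requires at least one case and one control in the training set");
  }

  arma::mat Xval = X.rows(val_idx);
  arma::vec yval = y.elem(val_idx);

  const arma::uword n_batches = std::max<arma::uword>(1, n_train / batch_size);

  std::vector<double> val_traj, train_loss_traj, case_frac_traj;
  Net best = net;
  double best_metric = -1.0;
  int best_epoch = 0;
  bool diverged = false;

  arma::uvec order = train_idx; // copy for shuffling

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    if (!oversample || !binary) shuffle_uvec(order);
    double epoch_loss = 0.0;
    arma::uword epoch_n = 0, epoch_cases = 0;

    for (arma::uword bi = 0; bi < n_batches; ++bi) {
      arma::uvec idx;
      if (binary && oversample) {
        idx.set_size(batch_size);
        for (int s = 0; s < batch_size; ++s) {
          if (unif_rand() < 0.5) {
            arma::uword j = static_cast<arma::uword>(unif_rand() * case_pool.n_elem);
            if (j >= case_pool.n_elem) j = case_pool.n_elem - 1;
            idx[s] = case_pool[j];
          } else {
            arma::uword j = static_cast<arma::uword>(unif_rand() * control_pool.n_elem);
            if (j >= control_pool.n_elem) j = control_pool.n_elem - 1;
            idx[s] = control_pool[j];
          }
        }
      } else {
        arma::uword lo = bi * batch_size;
        arma::uword hi = std::min<arma::uword>(lo + batch_size, n_train);
        if (hi - lo < 2) continue; // batch norm needs >= 2 rows
        idx = order.subvec(lo, hi - 1);
      }
      const arma::uword m = idx.n_elem;

      arma::mat A = X.rows(idx);
      arma::vec yb = y.elem(idx);
      if (binary) epoch_cases += static_cast<arma::uword>(arma::accu(yb > 0.5));
      epoch_n += m;

      // ---- forward with caches ----
      std::vector<arma::mat> A_in(k), Zhat(k), Hpre(k), Mask(k);
      std::vector<arma::rowvec> inv_sd(k);
      for (int l = 0; l < k; ++l) {
        Layer& L = net.hidden[l];
        A_in[l] = A;
        arma::mat Z = A * L.W;
        Z.each_row() += L.b;
        arma::mat H;
        if (batch_norm) {
          arma::rowvec mu = arma::mean(Z, 0);
          arma::rowvec va = arma::var(Z, 1, 0); // biased batch variance
          inv_sd[l] = 1.0 / arma::sqrt(va + BN_EPS);
          arma::mat Zh = Z;
          Zh.each_row() -= mu;
          Zh.each_row() %= inv_sd[l];
          Zhat[l] = Zh;
          H = Zh;
          H.each_row() %= L.gamma;
          H.each_row() += L.beta;
          L.run_mean = (1.0 - BN_MOMENTUM) * L.run_mean + BN_MOMENTUM * mu;
          L.run_var = (1.0 - BN_MOMENTUM) * L.run_var + BN_MOMENTUM * va;
        } else {
          H = Z;
        }
        Hpre[l] = H;
        arma::mat Act = nonlinear ? softplus_mat(H) : H;
        if (dropout_rate > 0) {
          arma::mat Msk(m, Act.n_cols);
          const double keep = 1.0 - dropout_rate;
          for (arma::uword jj = 0; jj < Msk.n_elem; ++jj)
            Msk[jj] = (unif_rand() < keep) ? (1.0 / keep) : 0.0;
          Mask[l] = Msk;
          Act %= Msk;
        }
        A = Act;
      }
      arma::vec out = A * net.w_out + net.b_out;

      double loss;
      arma::vec dout(m);
      if (binary) {
        arma::vec pr = sigmoid_mat(out);
        loss = 0.0;
        for (arma::uword i = 0; i < m; ++i) {
          double pi = std::min(std::max(pr[i], 1e-12), 1.0 - 1e-12);
          loss += -(yb[i] * std::log(pi) + (1.0 - yb[i]) * std::log(1.0 - pi));
        }
        loss /= m;
        dout = (pr - yb) / m;
      } else {
        arma::vec res = out - yb;
        loss = arma::dot(res, res) / m;
        dout = 2.0 * res / m;
      }
      if (!std::isfinite(loss)) { diverged = true; break; }
      epoch_loss += loss * m;

      // ---- backward ----
      arma::vec dw_out = A.t() * dout;
      double db_out = arma::accu(dout);
      arma::mat dA = dout * net.w_out.t();

      for (int l = k - 1; l >= 0; --l) {
        Layer& L = net.hidden[l];
        if (dropout_rate > 0) dA %= Mask[l];
        arma::mat dH = nonlinear ? arma::mat(dA % sigmoid_mat(Hpre[l])) : dA;
        arma::mat dZ;
        if (batch_norm) {
          arma::rowvec dgamma = arma::sum(dH % Zhat[l], 0);
          arma::rowvec dbeta = arma::sum(dH, 0);
          arma::mat dZh = dH;
          dZh.each_row() %= L.gamma;
          arma::rowvec s1 = arma::sum(dZh, 0);
          arma::rowvec s2 = arma::sum(dZh % Zhat[l], 0);
          dZ = (double)m * dZh;
          dZ.each_row() -= s1;
          dZ -= Zhat[l] % arma::repmat(s2, m, 1);
          dZ.each_row() %= inv_sd[l] / (double)m;
          L.gamma -= learning_rate * dgamma;
          L.beta -= learning_rate * dbeta;
        } else {
          dZ = dH;
        }
        arma::mat dW = A_in[l].t() * dZ;
        arma::rowvec db = arma::sum(dZ, 0);
        if (l > 0) dA = dZ * L.W.t();
        L.W -= learning_rate * dW;
        L.b -= learning_rate * db;
      }
      net.w_out -= learning_rate * dw_out;
      net.b_out -= learning_rate * db_out;
    }
    if (diverged) break;

    train_loss_traj.push_back(epoch_n > 0 ? epoch_loss / epoch_n : NA_REAL);
    if (binary) case_frac_traj.push_back(epoch_n > 0 ? (double)epoch_cases / epoch_n : NA_REAL);

    arma::vec vp = net_infer(net, Xval);
    if (binary) vp = sigmoid_mat(vp);
    double metric = squared_pearson(vp, yval);
    val_traj.push_back(metric);

    if (metric > best_metric) {
      best_metric = metric;
      best_epoch = epoch;
      best = net;
    }
    if (epoch - best_epoch >= patience) break;
  }

  List hid(k);
  for (int l = 0; l < k; ++l) {
    hid[l] = List::create(
      _["W"] = best.hidden[l].W,
      _["b"] = best.hidden[l].b,
      _["gamma"] = best.hidden[l].gamma,
      _["beta"] = best.hidden[l].beta,
      _["run_mean"] = best.hidden[l].run_mean,
      _["run_var"] = best.hidden[l].run_var);
  }
  return List::create(
    _["hidden"] = hid,
    _["w_out"] = best.w_out,
    _["b_out"] = best.b_out,
    _["best_epoch"] = best_epoch,
    _["best_val_r2"] = best_metric,
    _["val_trajectory"] = val_traj,
    _["train_loss"] = train_loss_traj,
    _["case_fraction"] = case_frac_traj,
    _["epochs_run"] = (int)val_traj.size(),
    _["diverged"] = diverged);
}
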