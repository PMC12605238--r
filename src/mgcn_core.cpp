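// Full-batch Adam training loop for the three-branch spectral GCN.
//
// The R front end stacks all trials' node features into one
// (N*S) x f matrix per domain; the per-trial propagation matrices
// arrive as one S x (S*N) matrix of horizontally concatenated blocks
// and are assembled here into one sparse block-diagonal operator.
// Dropout masks are drawn from R's RNG so results are reproducible
// from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Assemble blockdiag(B_1 ... B_n) as a sparse matrix from the
// horizontally concatenated blocks (sparse-times-dense is the fastest
// batched application here: row blocks of the stacked feature matrix
// are not contiguous, so per-block GEMM would copy).
arma::sp_mat buildBlockDiag(const arma::mat& Bcat, arma::uword S) {
  const arma::uword n = Bcat.n_cols / S;
  arma::umat loc(2, n * S * S);
  arma::vec val(n * S * S);
  arma::uword k = 0;
  for (arma::uword t = 0; t < n; ++t) {
    for (arma::uword j = 0; j < S; ++j) {
      for (arma::uword i = 0; i < S; ++i, ++k) {
        loc(0, k) = t * S + i;
        loc(1, k) = t * S + j;
        val(k) = Bcat(i, t * S + j);
      }
    }
  }
  return arma::sp_mat(loc, val, n * S, n * S, false, true);
}

// act = relu-derivative of Z fused with an inverted dropout mask;
// H = Z % act. RNG draws happen only where Z > 0, from R's stream.
void reluDropout(const arma::mat& Z, double p, arma::mat& act,
                 arma::mat& H) {
  const arma::uword nel = Z.n_elem;
  act.set_size(Z.n_rows, Z.n_cols);
  H.set_size(Z.n_rows, Z.n_cols);
  const double* z = Z.memptr();
  double* a = act.memptr();
  double* h = H.memptr();
  if (p > 0) {
    const double scale = 1.0 / (1.0 - p);
    for (arma::uword i = 0; i < nel; ++i) {
      const double ai =
          (z[i] > 0 && unif_rand() >= p) ? scale : 0.0;
      a[i] = ai;
      h[i] = z[i] * ai;
    }
  } else {
    for (arma::uword i = 0; i < nel; ++i) {
      const double ai = z[i] > 0 ? 1.0 : 0.0;
      a[i] = ai;
      h[i] = z[i] * ai;
    }
  }
}

// Chebyshev layer forward over the stacked batch.
struct ConvCache {
  arma::mat T1, T2;  // K = 2
  arma::mat BH;      // K = 1
};

arma::mat convForward(const arma::mat& H, const std::vector<arma::mat>& W,
                      const arma::sp_mat& B, int K, ConvCache& cache) {
  if (K == 1) {
    cache.BH = B * H;
    return cache.BH * W[0];
  }
  cache.T1 = B * H;
  cache.T2 = 2.0 * (B * cache.T1) - H;
  return H * W[0] + cache.T1 * W[1] + cache.T2 * W[2];
}

void convBackward(const arma::mat& dZ, const arma::mat& H,
                  const std::vector<arma::mat>& W, const arma::sp_mat& B,
                  int K, const ConvCache& cache,
                  std::vector<arma::mat>& dW, arma::mat& dH) {
  if (K == 1) {
    dW[0] = cache.BH.t() * dZ;
    dH = B * (dZ * W[0].t());
    return;
  }
  dW[0] = H.t() * dZ;
  dW[1] = cache.T1.t() * dZ;
  dW[2] = cache.T2.t() * dZ;
  arma::mat g1 = dZ * W[1].t();
  arma::mat g2 = dZ * W[2].t();
  dH = dZ * W[0].t() - g2 + B * (g1 + 2.0 * (B * g2));
}

struct Adam {
  arma::mat m, v;
  void init(const arma::mat& p) {
    m.zeros(p.n_rows, p.n_cols);
    v.zeros(p.n_rows, p.n_cols);
  }
  void step(arma::mat& p, const arma::mat& g, double lr, int t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * (g % g);
    const double c1 = 1.0 - std::pow(0.9, t);
    const double c2 = 1.0 - std::pow(0.999, t);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8);
  }
};

}  // namespace

// [[Rcpp::export(name = ".mgcnTrainCore")]]
List mgcnTrainCore(List pxList, List bList, const arma::ivec& y,
                   const arma::vec& sampleWeight, List w1Init, List w2Init,
                   arma::vec gamma, arma::vec beta, arma::mat denseW,
                   arma::vec denseB, int epochs, double lr, double dropout,
                   int K, int S) {
  const int nd = pxList.size();
  const int norder = (K == 1) ? 1 : 3;
  const double eps = 1e-5;

  std::vector<std::vector<arma::mat>> PX(nd), W1(nd), W2(nd);
  std::vector<arma::sp_mat> B(nd);
  for (int d = 0; d < nd; ++d) {
    List px = pxList[d], w1 = w1Init[d], w2 = w2Init[d];
    for (int m = 0; m < norder; ++m) {
      PX[d].push_back(as<arma::mat>(px[m]));
      W1[d].push_back(as<arma::mat>(w1[m]));
      W2[d].push_back(as<arma::mat>(w2[m]));
    }
    B[d] = buildBlockDiag(as<arma::mat>(bList[d]), S);
  }
  const arma::uword n = PX[0][0].n_rows / S;

  arma::mat onehot(n, 2, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) onehot(i, y[i] - 1) = 1.0;

  std::vector<std::vector<Adam>> adW1(nd), adW2(nd);
  for (int d = 0; d < nd; ++d) {
    adW1[d].resize(norder);
    adW2[d].resize(norder);
    for (int m = 0; m < norder; ++m) {
      adW1[d][m].init(W1[d][m]);
      adW2[d][m].init(W2[d][m]);
    }
  }
  Adam adGamma, adBeta, adDw, adDb;
  adGamma.init(gamma);
  adBeta.init(beta);
  adDw.init(denseW);
  adDb.init(denseB);

  arma::vec runMean(16 * nd, arma::fill::zeros);
  arma::vec runVar(16 * nd, arma::fill::ones);
  arma::vec lossTrace(epochs);

  std::vector<arma::mat> act1(nd), H1d(nd), act2(nd);
  std::vector<ConvCache> c2cache(nd);

  for (int ep = 1; ep <= epochs; ++ep) {
    // ---- forward ----
    arma::mat u(n, 16 * nd);
    for (int d = 0; d < nd; ++d) {
      arma::mat z1 = PX[d][0] * W1[d][0];
      for (int m = 1; m < norder; ++m) z1 += PX[d][m] * W1[d][m];
      reluDropout(z1, dropout, act1[d], H1d[d]);
      arma::mat z2 = convForward(H1d[d], W2[d], B[d], K, c2cache[d]);
      arma::mat h2;
      reluDropout(z2, dropout, act2[d], h2);
      // global mean pool over the S nodes of each trial
      for (arma::uword t = 0; t < n; ++t) {
        u(t, arma::span(16 * d, 16 * d + 15)) =
            arma::mean(h2.rows(t * S, t * S + S - 1), 0);
      }
    }
    arma::rowvec mu = arma::mean(u, 0);
    arma::mat centred = u.each_row() - mu;
    arma::rowvec vr = arma::mean(centred % centred, 0);
    arma::rowvec istd = 1.0 / arma::sqrt(vr + eps);
    arma::mat xhat = centred.each_row() % istd;
    arma::mat yout = xhat.each_row() % gamma.t();
    yout.each_row() += beta.t();
    arma::mat logits = yout * denseW;
    logits.each_row() += denseB.t();
    logits.each_col() -= arma::max(logits, 1);
    arma::mat probs = arma::exp(logits);
    probs.each_col() /= arma::sum(probs, 1);

    double loss = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      loss -= sampleWeight[i] *
              std::log(std::max(probs(i, y[i] - 1), 1e-12));
    }
    lossTrace[ep - 1] = loss / n;
    runMean = 0.9 * runMean + 0.1 * mu.t();
    runVar = 0.9 * runVar + 0.1 * vr.t();

    // ---- backward ----
    arma::mat dlogits = probs - onehot;
    dlogits.each_col() %= sampleWeight / static_cast<double>(n);
    arma::mat gDw = yout.t() * dlogits;
    arma::vec gDb = arma::sum(dlogits, 0).t();
    arma::mat dy = dlogits * denseW.t();
    arma::vec gGamma = arma::sum(dy % xhat, 0).t();
    arma::vec gBeta = arma::sum(dy, 0).t();

    arma::mat dxhat = dy.each_row() % gamma.t();
    arma::rowvec dv = arma::sum(dxhat % centred, 0) %
                      (-0.5 * istd % istd % istd);
    arma::rowvec dmu = -arma::sum(dxhat, 0) % istd +
                       dv % arma::mean(-2.0 * centred, 0);
    arma::mat du = dxhat.each_row() % istd;
    du += centred.each_row() % (2.0 * dv / static_cast<double>(n));
    du.each_row() += dmu / static_cast<double>(n);

    for (int d = 0; d < nd; ++d) {
      // pool backward: each node of trial t receives dPool(t) / S
      arma::mat dH2(n * S, 16);
      for (arma::uword t = 0; t < n; ++t) {
        dH2.rows(t * S, t * S + S - 1) =
            arma::repmat(du(t, arma::span(16 * d, 16 * d + 15)) /
                             static_cast<double>(S),
                         S, 1);
      }
      arma::mat dZ2 = dH2 % act2[d];
      std::vector<arma::mat> dW2(norder);
      arma::mat dH1;
      convBackward(dZ2, H1d[d], W2[d], B[d], K, c2cache[d], dW2, dH1);
      arma::mat dZ1 = dH1 % act1[d];
      for (int m = 0; m < norder; ++m) {
        arma::mat gW1 = PX[d][m].t() * dZ1;
        adW1[d][m].step(W1[d][m], gW1, lr, ep);
        adW2[d][m].step(W2[d][m], dW2[m], lr, ep);
      }
    }
    adGamma.step(gamma, gGamma, lr, ep);
    adBeta.step(beta, gBeta, lr, ep);
    adDw.step(denseW, gDw, lr, ep);
    adDb.step(denseB, gDb, lr, ep);
  }

  List w1Out(nd), w2Out(nd);
  for (int d = 0; d < nd; ++d) {
    List a(norder), b2(norder);
    for (int m = 0; m < norder; ++m) {
      a[m] = W1[d][m];
      b2[m] = W2[d][m];
    }
    w1Out[d] = a;
    w2Out[d] = b2;
  }
  return List::create(_["W1"] = w1Out, _["W2"] = w2Out, _["gamma"] = gamma,
                      _["beta"] = beta, _["denseW"] = denseW,
                      _["denseB"] = denseB, _["runMean"] = runMean,
                      _["runVar"] = runVar, _["loss"] = lossTrace);
}
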