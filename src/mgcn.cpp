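// Training and inference core of the multi-graph convolutional classifier.
//
// Per band j the network computes
//   H1 = relu(P_j W0_j)          with P_j = A1hat_j X_j precomputed per
//                                 sample (layer-1 propagation is fixed
//                                 given the functional adjacency)
//   H2 = relu(A2hat H1 W1_j)     shared structural adjacency
// band outputs are flattened (column-major, N*L each), concatenated in
// band order, and passed through three fully connected layers with ReLU
// on the hidden ones; softmax cross-entropy loss, Adam updates.
//
// Minibatches are processed as stacked matrices so every product is a
// single BLAS call. Shuffling uses R's RNG (deterministic under set.seed).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::uvec;

namespace {

struct Params {
  std::vector<mat> W0, W1;   // per band (or length 1 if shared)
  std::vector<mat> b0, b1;   // 1 x K / 1 x L rows; empty unless gcnBias
  mat Wf1, Wf2, Wf3;
  mat bf1, bf2, bf3;         // 1 x width rows
  bool shared = false, bias = false;

  int bandSlot(int j) const { return shared ? 0 : j; }
};

Params unpack(const List& init, bool shared, bool bias) {
  Params p;
  p.shared = shared;
  p.bias = bias;
  List w0 = init["W0"], w1 = init["W1"];
  for (int j = 0; j < w0.size(); ++j) p.W0.push_back(as<mat>(w0[j]));
  for (int j = 0; j < w1.size(); ++j) p.W1.push_back(as<mat>(w1[j]));
  p.Wf1 = as<mat>(init["Wf1"]);
  p.Wf2 = as<mat>(init["Wf2"]);
  p.Wf3 = as<mat>(init["Wf3"]);
  p.bf1 = as<mat>(init["bf1"]);
  p.bf2 = as<mat>(init["bf2"]);
  p.bf3 = as<mat>(init["bf3"]);
  if (bias) {
    List g0 = init["b0"], g1 = init["b1"];
    for (int j = 0; j < g0.size(); ++j) p.b0.push_back(as<mat>(g0[j]));
    for (int j = 0; j < g1.size(); ++j) p.b1.push_back(as<mat>(g1[j]));
  }
  return p;
}

List pack(const Params& p) {
  List w0(p.W0.size()), w1(p.W1.size());
  for (size_t j = 0; j < p.W0.size(); ++j) w0[j] = p.W0[j];
  for (size_t j = 0; j < p.W1.size(); ++j) w1[j] = p.W1[j];
  List out = List::create(
      Named("W0") = w0, Named("W1") = w1,
      Named("Wf1") = p.Wf1, Named("Wf2") = p.Wf2, Named("Wf3") = p.Wf3,
      Named("bf1") = p.bf1, Named("bf2") = p.bf2, Named("bf3") = p.bf3);
  if (p.bias) {
    List g0(p.b0.size()), g1(p.b1.size());
    for (size_t j = 0; j < p.b0.size(); ++j) g0[j] = p.b0[j];
    for (size_t j = 0; j < p.b1.size(); ++j) g1[j] = p.b1[j];
    out["b0"] = g0;
    out["b1"] = g1;
  }
  return out;
}

// flat views over all parameter matrices, fixed order, for Adam
std::vector<mat*> flatten(Params& p) {
  std::vector<mat*> v;
  for (auto& m : p.W0) v.push_back(&m);
  for (auto& m : p.W1) v.push_back(&m);
  v.push_back(&p.Wf1); v.push_back(&p.Wf2); v.push_back(&p.Wf3);
  v.push_back(&p.bf1); v.push_back(&p.bf2); v.push_back(&p.bf3);
  for (auto& m : p.b0) v.push_back(&m);
  for (auto& m : p.b1) v.push_back(&m);
  return v;
}

Params zerosLike(const Params& p) {
  Params g = p;
  for (auto& m : g.W0) m.zeros();
  for (auto& m : g.W1) m.zeros();
  g.Wf1.zeros(); g.Wf2.zeros(); g.Wf3.zeros();
  g.bf1.zeros(); g.bf2.zeros(); g.bf3.zeros();
  for (auto& m : g.b0) m.zeros();
  for (auto& m : g.b1) m.zeros();
  return g;
}

inline mat relu(const mat& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

// Forward pass over the samples in idx; fills probs (B x Z). When grad is
// non-null, also backpropagates and accumulates gradients. Returns the
// mean cross-entropy over the batch.
double forwardBackward(const std::vector<cube>& P, const mat& A2,
                       const uvec& idx, const arma::ivec& y,
                       Params& prm, Params* grad, mat* probsOut) {
  const int J = P.size();
  const int N = P[0].n_rows, B = idx.n_elem;
  const int K = prm.W0[0].n_cols, L = prm.W1[0].n_cols;
  const int NL = N * L;

  std::vector<mat> Pstack(J), G1(J), Ustack(J), G2(J);
  mat Fmat(B, NL * J);

  for (int j = 0; j < J; ++j) {
    const int js = prm.bandSlot(j);
    mat& PS = Pstack[j];
    PS.set_size(B * N, P[0].n_cols);
    for (int s = 0; s < B; ++s)
      PS.rows(s * N, s * N + N - 1) = P[j].slice(idx[s]);
    G1[j] = PS * prm.W0[js];
    if (prm.bias) G1[j].each_row() += prm.b0[js];
    mat H1 = relu(G1[j]);
    // regroup to nodes x (B*K) so the shared structural propagation is one
    // product, then back
    mat Q(N, B * K);
    for (int s = 0; s < B; ++s)
      Q.cols(s * K, s * K + K - 1) = H1.rows(s * N, s * N + N - 1);
    mat U2 = A2 * Q;
    mat& US = Ustack[j];
    US.set_size(B * N, K);
    for (int s = 0; s < B; ++s)
      US.rows(s * N, s * N + N - 1) = U2.cols(s * K, s * K + K - 1);
    G2[j] = US * prm.W1[js];
    if (prm.bias) G2[j].each_row() += prm.b1[js];
    mat H2 = relu(G2[j]);
    for (int s = 0; s < B; ++s)
      Fmat(s, arma::span(j * NL, (j + 1) * NL - 1)) =
          arma::vectorise(H2.rows(s * N, s * N + N - 1)).t();
  }

  mat Z1g = Fmat * prm.Wf1; Z1g.each_row() += prm.bf1;
  mat Z1 = relu(Z1g);
  mat Z2g = Z1 * prm.Wf2; Z2g.each_row() += prm.bf2;
  mat Z2 = relu(Z2g);
  mat logits = Z2 * prm.Wf3; logits.each_row() += prm.bf3;

  mat shifted = logits;
  shifted.each_col() -= arma::max(logits, 1);
  mat probs = arma::exp(shifted);
  probs.each_col() /= arma::sum(probs, 1);
  if (probsOut) *probsOut = probs;

  double loss = 0.0;
  for (int s = 0; s < B; ++s)
    loss -= std::log(std::max(probs(s, y[idx[s]]), 1e-300));
  loss /= B;
  if (!grad) return loss;

  mat dLogit = probs;
  for (int s = 0; s < B; ++s) dLogit(s, y[idx[s]]) -= 1.0;
  dLogit /= B;

  grad->Wf3 += Z2.t() * dLogit;
  grad->bf3 += arma::sum(dLogit, 0);
  mat dZ2 = (dLogit * prm.Wf3.t()) % (Z2g > 0);
  grad->Wf2 += Z1.t() * dZ2;
  grad->bf2 += arma::sum(dZ2, 0);
  mat dZ1 = (dZ2 * prm.Wf2.t()) % (Z1g > 0);
  grad->Wf1 += Fmat.t() * dZ1;
  grad->bf1 += arma::sum(dZ1, 0);
  mat dF = dZ1 * prm.Wf1.t();

  for (int j = 0; j < J; ++j) {
    const int js = prm.bandSlot(j);
    mat dH2(B * N, L);
    for (int s = 0; s < B; ++s)
      dH2.rows(s * N, s * N + N - 1) = arma::reshape(
          dF(s, arma::span(j * NL, (j + 1) * NL - 1)), N, L);
    mat dG2 = dH2 % (G2[j] > 0);
    grad->W1[js] += Ustack[j].t() * dG2;
    if (prm.bias) grad->b1[js] += arma::sum(dG2, 0);
    mat dU = dG2 * prm.W1[js].t();
    mat dUQ(P[0].n_rows, B * K);
    for (int s = 0; s < B; ++s)
      dUQ.cols(s * K, s * K + K - 1) = dU.rows(s * N, s * N + N - 1);
    mat dQ = A2.t() * dUQ;
    mat dH1(B * N, K);
    for (int s = 0; s < B; ++s)
      dH1.rows(s * N, s * N + N - 1) = dQ.cols(s * K, s * K + K - 1);
    mat dG1 = dH1 % (G1[j] > 0);
    grad->W0[js] += Pstack[j].t() * dG1;
    if (prm.bias) grad->b0[js] += arma::sum(dG1, 0);
  }
  return loss;
}

std::vector<cube> asCubes(const List& Plist) {
  std::vector<cube> P;
  for (int j = 0; j < Plist.size(); ++j) P.push_back(as<cube>(Plist[j]));
  return P;
}

uvec zeroBased(const IntegerVector& idx) {
  uvec out(idx.size());
  for (int i = 0; i < idx.size(); ++i) out[i] = idx[i] - 1;
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_train(List Plist, arma::mat A2, IntegerVector y, List init,
               IntegerVector trainIdx, IntegerVector testIdx,
               double lr, int batchSize, int epochs,
               bool shared, bool gcnBias) {
  std::vector<cube> P = asCubes(Plist);
  arma::ivec yy(y.size());
  for (int i = 0; i < y.size(); ++i) yy[i] = y[i];
  uvec tr = zeroBased(trainIdx), te = zeroBased(testIdx);

  Params prm = unpack(init, shared, gcnBias);
  Params mAdam = zerosLike(prm), vAdam = zerosLike(prm);
  std::vector<mat*> pv = flatten(prm), mv = flatten(mAdam),
                    vv = flatten(vAdam);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t = 0;

  arma::vec trainLoss(epochs), testLoss(epochs);
  const int n = tr.n_elem;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    IntegerVector ord = sample(n, n);  // R RNG, 1-based
    double epLoss = 0.0;
    int covered = 0;
    for (int start = 0; start < n; start += batchSize) {
      int stop = std::min(start + batchSize, n);
      uvec batch(stop - start);
      for (int i = start; i < stop; ++i) batch[i - start] = tr[ord[i] - 1];
      Params grad = zerosLike(prm);
      double loss = forwardBackward(P, A2, batch, yy, prm, &grad, nullptr);
      epLoss += loss * batch.n_elem;
      covered += batch.n_elem;
      ++t;
      std::vector<mat*> gv = flatten(grad);
      const double c1 = 1.0 - std::pow(beta1, (double)t);
      const double c2 = 1.0 - std::pow(beta2, (double)t);
      for (size_t k = 0; k < pv.size(); ++k) {
        *mv[k] = beta1 * (*mv[k]) + (1 - beta1) * (*gv[k]);
        *vv[k] = beta2 * (*vv[k]) + (1 - beta2) * arma::square(*gv[k]);
        *pv[k] -= lr * ((*mv[k]) / c1) / (arma::sqrt((*vv[k]) / c2) + eps);
      }
    }
    trainLoss[epoch] = epLoss / covered;
    testLoss[epoch] = te.n_elem
        ? forwardBackward(P, A2, te, yy, prm, nullptr, nullptr)
        : NA_REAL;
  }

  return List::create(Named("params") = pack(prm),
                      Named("trainLoss") = trainLoss,
                      Named("testLoss") = testLoss);
}

// [[Rcpp::export]]
arma::mat cpp_forward(List Plist, arma::mat A2, List paramsList,
                      IntegerVector idx, bool shared, bool gcnBias) {
  std::vector<cube> P = asCubes(Plist);
  Params prm = unpack(paramsList, shared, gcnBias);
  uvec ii = zeroBased(idx);
  arma::ivec yy(P[0].n_slices, arma::fill::zeros);
  mat probs;
  forwardBackward(P, A2, ii, yy, prm, nullptr, &probs);
  return probs;
}
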