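#include <Rcpp.h>
using namespace Rcpp;

// E-step for the saturated polytomous latent-class model.
//
// X:      N x J integer responses, categories 0..C_j-1
// probs:  list of C_j x H_j conditional-probability matrices
// groups: L x J integer matrix, groups(l, j) = 1-based latent group of
//         class l on item j
// prior:  length-L structural distribution p(alpha_l)
//
// Returns the marginal log-likelihood, the N x L posterior, the raw
// N x L conditional likelihoods, and per-item expected counts
// R_jhc (C_j x H_j; N_jh are their column sums).
//
// The per-item probability lookups are staged into N x H_j buffers so
// the hot loops over examinees run with unit stride.
// [[Rcpp::export]]
List gpdm_estep_cpp(IntegerMatrix X, List probs, IntegerMatrix groups,
                    NumericVector prior) {
  const int N = X.nrow(), J = X.ncol(), L = prior.size();
  NumericMatrix lik(N, L);
  std::fill(lik.begin(), lik.end(), 1.0);

  // range-check responses once
  for (int j = 0; j < J; ++j) {
    NumericMatrix P = probs[j];
    const int C = P.nrow();
    const int* x = &X(0, j);
    for (int i = 0; i < N; ++i)
      if (x[i] < 0 || x[i] >= C)
        stop("Response out of category range for item %d.", j + 1);
  }

  std::vector<double> stage;  // N x H_j lookup buffer, reused across items
  for (int j = 0; j < J; ++j) {
    NumericMatrix P = probs[j];
    const int H = P.ncol();
    const int* x = &X(0, j);
    stage.assign((size_t)N * H, 0.0);
    for (int h = 0; h < H; ++h) {
      const double* pcol = &P(0, h);
      double* v = &stage[(size_t)N * h];
      for (int i = 0; i < N; ++i) v[i] = pcol[x[i]];
    }
    for (int l = 0; l < L; ++l) {
      const double* v = &stage[(size_t)N * (groups(l, j) - 1)];
      double* lcol = &lik(0, l);
      for (int i = 0; i < N; ++i) lcol[i] *= v[i];
    }
  }

  NumericMatrix post(N, L);
  std::vector<double> marg(N, 0.0);
  for (int l = 0; l < L; ++l) {
    const double pl = prior[l];
    const double* lcol = &lik(0, l);
    double* pcol = &post(0, l);
    for (int i = 0; i < N; ++i) {
      const double v = lcol[i] * pl;
      pcol[i] = v;
      marg[i] += v;
    }
  }
  double loglik = 0.0;
  for (int i = 0; i < N; ++i) {
    if (!(marg[i] > 0.0))
      stop("Examinee %d has zero marginal likelihood (degenerate posterior).", i + 1);
    loglik += std::log(marg[i]);
    marg[i] = 1.0 / marg[i];
  }
  for (int l = 0; l < L; ++l) {
    double* pcol = &post(0, l);
    for (int i = 0; i < N; ++i) pcol[i] *= marg[i];
  }

  List counts(J);
  for (int j = 0; j < J; ++j) {
    NumericMatrix P = probs[j];
    const int C = P.nrow(), H = P.ncol();
    // group-summed posterior, then bucket by observed category
    stage.assign((size_t)N * H, 0.0);
    for (int l = 0; l < L; ++l) {
      const int h = groups(l, j) - 1;
      const double* pcol = &post(0, l);
      double* v = &stage[(size_t)N * h];
      for (int i = 0; i < N; ++i) v[i] += pcol[i];
    }
    NumericMatrix R(C, H);
    const int* x = &X(0, j);
    for (int h = 0; h < H; ++h) {
      const double* v = &stage[(size_t)N * h];
      double* rcol = &R(0, h);
      for (int i = 0; i < N; ++i) rcol[x[i]] += v[i];
    }
    counts[j] = R;
  }

  return List::create(_["loglik"] = loglik, _["post"] = post,
                      _["lik"] = lik, _["counts"] = counts);
}

// Full EM loop for the saturated model with closed-form M-step and no
// monotonicity projection; returns the fitted tables, structural
// distribution and log-likelihood trace. Items with an empty latent
// group retain their previous probabilities for that group.
// [[Rcpp::export]]
List gpdm_em_cpp(IntegerMatrix X, List probs, IntegerMatrix groups,
                 NumericVector prior, int max_iter, double tol) {
  const int N = X.nrow(), J = X.ncol(), L = prior.size();
  List cur_probs = clone(probs);
  NumericVector cur_prior = clone(prior);
  std::vector<double> trace;
  trace.reserve(256);
  double prev = R_NegInf;
  bool converged = false;
  int iter = 0;
  List es;
  while (iter < max_iter) {
    ++iter;
    es = gpdm_estep_cpp(X, cur_probs, groups, cur_prior);
    const double ll = es["loglik"];
    trace.push_back(ll);
    if (R_finite(prev) && std::fabs(ll - prev) < tol) {
      converged = true;
      break;
    }
    prev = ll;
    // M-step
    List counts = es["counts"];
    for (int j = 0; j < J; ++j) {
      NumericMatrix R = counts[j];
      NumericMatrix P = cur_probs[j];
      const int C = R.nrow(), H = R.ncol();
      for (int h = 0; h < H; ++h) {
        double nh = 0.0;
        for (int c = 0; c < C; ++c) nh += R(c, h);
        if (nh > 0.0)
          for (int c = 0; c < C; ++c) P(c, h) = R(c, h) / nh;
      }
    }
    NumericMatrix post = es["post"];
    double tot = 0.0;
    for (int l = 0; l < L; ++l) {
      double s = 0.0;
      const double* pcol = &post(0, l);
      for (int i = 0; i < N; ++i) s += pcol[i];
      cur_prior[l] = s;
      tot += s;
    }
    for (int l = 0; l < L; ++l) cur_prior[l] /= tot;
  }
  return List::create(_["item_probs"] = cur_probs,
                      _["structural"] = cur_prior,
                      _["estep"] = es,
                      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["n_iter"] = iter, _["converged"] = converged);
}
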