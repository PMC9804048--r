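// Core numerics for the dFNC pipeline: graphical lasso (Friedman-style block
// coordinate descent), city-block k-means with median centroid updates, and
// the per-window tapered-covariance -> glasso -> Fisher-z loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Block coordinate descent for the graphical lasso.
// Returns the regularized covariance W and precision Theta.
// At rho = 0 the estimate is the (unpenalized) sample covariance itself.
static void glasso_core(const mat& S, double rho, int max_sweeps, double tol,
                        mat& W, mat& Theta) {
  const uword p = S.n_rows;
  if (rho <= 0.0) {
    W = S;
    Theta = pinv(symmatu(S));
    return;
  }
  W = S;
  W.diag() += rho;
  mat Beta(p - 1, p, fill::zeros);
  const double thr = tol * mean(abs(vectorise(S - diagmat(S.diag())))) + 1e-12;

  uvec all = regspace<uvec>(0, p - 1);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12 = s12(idx);
      vec beta = Beta.col(j);
      // inner lasso coordinate descent
      for (int it = 0; it < 200; ++it) {
        double delta = 0.0;
        for (uword q = 0; q < p - 1; ++q) {
          double grad = s12(q) - dot(W11.col(q), beta) + W11(q, q) * beta(q);
          double bnew = soft_threshold(grad, rho) / W11(q, q);
          delta = std::max(delta, std::abs(bnew - beta(q)));
          beta(q) = bnew;
        }
        if (delta < 1e-7) break;
      }
      Beta.col(j) = beta;
      vec w12 = W11 * beta;
      for (uword q = 0; q < p - 1; ++q) {
        double d = std::abs(W(idx(q), j) - w12(q));
        if (d > max_delta) max_delta = d;
        W(idx(q), j) = w12(q);
        W(j, idx(q)) = w12(q);
      }
    }
    if (max_delta < thr) break;
  }
  // Recover Theta from the final W and regression coefficients.
  Theta.set_size(p, p);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec beta = Beta.col(j);
    vec w12 = W(idx, uvec{j});
    double t22 = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = t22;
    for (uword q = 0; q < p - 1; ++q) {
      Theta(idx(q), j) = -beta(q) * t22;
      Theta(j, idx(q)) = -beta(q) * t22;
    }
  }
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho,
                      int max_sweeps = 100, double tol = 1e-4) {
  mat W, Theta;
  glasso_core(S, rho, max_sweeps, tol, W, Theta);
  return Rcpp::List::create(Rcpp::Named("w") = W, Rcpp::Named("theta") = Theta);
}

// Gaussian log-likelihood of a test covariance under precision Theta
// (up to constants): log det(Theta) - tr(S Theta).
// [[Rcpp::export]]
double gauss_loglik_cpp(const arma::mat& theta, const arma::mat& s_test) {
  double sign, ld;
  log_det(ld, sign, theta);
  if (sign <= 0) return -datum::inf;
  return ld - trace(s_test * theta);
}

// Tapered weighted covariance of X (T x p) for a window whose nominal span is
// [start, start+width), with taper weights w of length L applied at time
// indices start - pad + j (clipped at series boundaries).
static mat window_cov(const mat& X, int start, int pad, const vec& w) {
  const int T = X.n_rows;
  const int L = w.n_elem;
  int lo = std::max(0, start - pad);
  int hi = std::min(T - 1, start - pad + L - 1);
  vec ww(hi - lo + 1);
  for (int t = lo; t <= hi; ++t) ww(t - lo) = w(t - (start - pad));
  double wsum = accu(ww);
  mat Xw = X.rows(lo, hi);
  rowvec mu = (ww.t() * Xw) / wsum;
  Xw.each_row() -= mu;
  Xw.each_col() %= sqrt(ww / wsum);
  return Xw.t() * Xw;
}

// [[Rcpp::export]]
arma::mat window_cov_cpp(const arma::mat& X, int start1, int pad,
                         const arma::vec& taper) {
  return window_cov(X, start1 - 1, pad, taper);
}

// Full windowed-FC stack for one session: for every window, tapered
// covariance -> graphical lasso at `rho` -> correlation -> Fisher z of the
// upper triangle. Returns n_windows x n_pairs.
// [[Rcpp::export]]
arma::mat windowed_fc_cpp(const arma::mat& X, int width, int step, int pad,
                          const arma::vec& taper, double rho,
                          double clamp = 0.9999999,
                          int max_sweeps = 100, double tol = 1e-4) {
  const int T = X.n_rows;
  const uword p = X.n_cols;
  const int n_win = (T - width) / step + 1;
  const uword n_pairs = p * (p - 1) / 2;
  mat Z(n_win, n_pairs);
  mat W, Theta;
  for (int i = 0; i < n_win; ++i) {
    mat S = window_cov(X, i * step, pad, taper);
    if (rho > 0.0) {
      glasso_core(S, rho, max_sweeps, tol, W, Theta);
    } else {
      W = S;
    }
    vec d = sqrt(W.diag());
    uword idx = 0;
    for (uword a = 0; a < p - 1; ++a) {
      for (uword b = a + 1; b < p; ++b) {
        double r = W(a, b) / (d(a) * d(b));
        if (r > clamp) r = clamp;
        if (r < -clamp) r = -clamp;
        Z(i, idx++) = std::atanh(r);
      }
    }
  }
  return Z;
}

// City-block (L1) k-means: assignment by minimal L1 distance (ties -> lowest
// state index), centroid update by element-wise median. Multiple restarts with
// caller-supplied initial centroid rows; best total cost kept. Data are held
// transposed (features x points) so the inner distance loop is contiguous.
// [[Rcpp::export]]
Rcpp::List kmeans_l1_cpp(const arma::mat& X, int k, const arma::umat& init,
                         int max_iter = 200, double tol = 1e-6) {
  const uword n = X.n_rows;
  const uword d = X.n_cols;
  const mat Xt = X.t();                       // d x n
  double best_cost = datum::inf;
  uvec best_assign;
  mat best_cent;
  std::vector<double> best_trace;

  for (uword r = 0; r < init.n_rows; ++r) {
    mat cent(d, k);                            // d x k
    for (int c = 0; c < k; ++c) cent.col(c) = Xt.col(init(r, c));
    uvec assign(n, fill::zeros);
    double prev_cost = datum::inf;
    std::vector<double> trace;
    for (int it = 0; it < max_iter; ++it) {
      // assignment step: one pass over each point, accumulating all k
      // distances (centT is k x d so the inner accumulator loop is
      // contiguous over centroids)
      mat centT = cent.t();
      std::vector<double> dist(k);
      double cost = 0.0;
      for (uword i = 0; i < n; ++i) {
        const double* x = Xt.colptr(i);
        std::fill(dist.begin(), dist.end(), 0.0);
        const double* ct = centT.memptr();
        for (uword j = 0; j < d; ++j) {
          const double xv = x[j];
          const double* cj = ct + j * k;
          for (int c = 0; c < k; ++c) dist[c] += std::abs(xv - cj[c]);
        }
        double dmin = dist[0];
        uword amin = 0;
        for (int c = 1; c < k; ++c)
          if (dist[c] < dmin - 1e-15) { dmin = dist[c]; amin = c; }
        assign(i) = amin;
        cost += dmin;
      }
      trace.push_back(cost);
      if (prev_cost - cost < tol * (1.0 + std::abs(prev_cost)) &&
          prev_cost < datum::inf) {
        prev_cost = cost;
        break;
      }
      prev_cost = cost;
      // update step: element-wise median per cluster
      for (int c = 0; c < k; ++c) {
        uvec members = find(assign == c);
        if (members.n_elem == 0) {
          // re-seed empty cluster at the point farthest from its centroid
          double dmax = -1.0; uword imax = 0;
          for (uword i = 0; i < n; ++i) {
            const double* x = Xt.colptr(i);
            const double* ce = cent.colptr(assign(i));
            double dist = 0.0;
            for (uword j = 0; j < d; ++j) dist += std::abs(x[j] - ce[j]);
            if (dist > dmax) { dmax = dist; imax = i; }
          }
          cent.col(c) = Xt.col(imax);
          assign(imax) = c;
        } else {
          cent.col(c) = median(Xt.cols(members), 1);
        }
      }
    }
    if (prev_cost < best_cost) {
      best_cost = prev_cost;
      best_assign = assign;
      best_cent = cent;
      best_trace = trace;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("assignments") = best_assign + 1,
      Rcpp::Named("centroids") = best_cent.t(),
      Rcpp::Named("cost") = best_cost,
      Rcpp::Named("cost_trace") = best_trace);
}
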