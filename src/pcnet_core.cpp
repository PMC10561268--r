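// Core simulation loops of the hierarchical predictive-coding network.
// All dynamics are deterministic given weights, state and stimulus; every
// source of randomness lives on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

inline arma::vec sigm(const arma::vec& v) {
  return 1.0 / (1.0 + arma::exp(-v));
}

struct Net {
  std::vector<arma::mat> W;       // W[l]: (n_l x n_{l+1}), l = 0..L-1
  std::vector<arma::vec> x, y;    // per area 0..L
  std::vector<arma::vec> beta;    // per area 0..L-1
  double eps_inf, dx;
  int L;                          // number of weight matrices (= top area index)

  Net(List Wl, List xl, List yl, double eps_inf_, double dx_)
      : eps_inf(eps_inf_), dx(dx_) {
    L = Wl.size();
    for (int l = 0; l < L; ++l) W.push_back(as<arma::mat>(Wl[l]));
    for (int l = 0; l <= L; ++l) {
      x.push_back(as<arma::vec>(xl[l]));
      y.push_back(as<arma::vec>(yl[l]));
    }
    for (int l = 0; l < L; ++l) beta.push_back(arma::zeros<arma::vec>(W[l].n_rows));
  }

  // One synchronous inference step: errors from current rates, then all
  // activations, then rates. Area 0 stays clamped.
  void step() {
    for (int l = 0; l < L; ++l) beta[l] = y[l] - W[l] * y[l + 1];
    for (int l = 1; l <= L; ++l) {
      arma::vec drive = W[l - 1].t() * beta[l - 1];
      if (l < L) drive -= beta[l];
      x[l] += eps_inf * drive;
      y[l] = sigm(x[l] + dx);
    }
  }

  void learn(double eps_learn) {
    for (int l = 0; l < L; ++l) W[l] += eps_learn * beta[l] * y[l + 1].t();
  }

  double total_sq_err() const {
    double s = 0.0;
    for (int l = 0; l < L; ++l) s += arma::dot(beta[l], beta[l]);
    return s;
  }

  List state_out() const {
    List xl(L + 1), yl(L + 1), bl(L);
    for (int l = 0; l <= L; ++l) { xl[l] = x[l]; yl[l] = y[l]; }
    for (int l = 0; l < L; ++l) bl[l] = beta[l];
    return List::create(_["x"] = xl, _["y"] = yl, _["beta"] = bl);
  }

  List weights_out() const {
    List Wl(L);
    for (int l = 0; l < L; ++l) Wl[l] = W[l];
    return Wl;
  }
};

} // namespace

// Present a block of frames to the network with activity carry-over.
// frames: (n_pixels x n_frames), each column clamped to area 0 in turn.
// Per frame, `cycles` cycles of `steps` inference steps are run; when
// eps_learn > 0 a Hebbian update follows each cycle. Optionally records
// the cycle-averaged activity (rates or errors) of one area.
// [[Rcpp::export]]
List cpp_run_frames(List Wl, List xl, List yl, const arma::mat& frames,
                    double eps_inf, double eps_learn, double dx,
                    int steps, int cycles,
                    bool record = false, int record_area = 0,
                    bool record_error = false) {
  Net net(Wl, xl, yl, eps_inf, dx);
  const int n_frames = frames.n_cols;
  arma::mat rec;
  if (record) {
    int n = record_error ? net.W[record_area].n_rows
                         : net.y[record_area].n_elem;
    rec.zeros(n_frames * cycles, n);
  }
  double err_sum = 0.0;
  arma::vec err_area = arma::zeros<arma::vec>(net.L);
  long n_updates = 0;
  int row = 0;
  for (int f = 0; f < n_frames; ++f) {
    net.y[0] = frames.col(f);
    for (int c = 0; c < cycles; ++c) {
      if (record) {
        arma::rowvec acc(rec.n_cols, arma::fill::zeros);
        for (int s = 0; s < steps; ++s) {
          net.step();
          acc += (record_error ? net.beta[record_area].t() : net.y[record_area].t());
        }
        rec.row(row++) = acc / steps;
      } else {
        for (int s = 0; s < steps; ++s) net.step();
      }
      for (int l = 0; l < net.L; ++l)
        err_area[l] += arma::dot(net.beta[l], net.beta[l]);
      err_sum += net.total_sq_err();
      if (eps_learn > 0) { net.learn(eps_learn); ++n_updates; }
    }
  }
  return List::create(_["weights"] = net.weights_out(),
                      _["state"] = net.state_out(),
                      _["record"] = rec,
                      _["err_sum"] = err_sum,
                      _["err_area"] = err_area,
                      _["n_updates"] = n_updates);
}

// Run inference cycles on one clamped frame until the relative change of
// the total squared prediction error between consecutive cycles falls
// below tol, or max_cycles is reached. No learning.
// [[Rcpp::export]]
List cpp_run_to_convergence(List Wl, List xl, List yl, const arma::vec& frame,
                            double eps_inf, double dx, int steps,
                            double tol, int max_cycles) {
  Net net(Wl, xl, yl, eps_inf, dx);
  net.y[0] = frame;
  double prev = NA_REAL;
  bool converged = false;
  int c = 0;
  std::vector<double> trace;
  for (; c < max_cycles; ++c) {
    for (int s = 0; s < steps; ++s) net.step();
    double err = net.total_sq_err();
    trace.push_back(err);
    // relative change is taken as infinite before a second cycle exists,
    // so an infinite tolerance stops after a single cycle
    double rel = (c == 0) ? R_PosInf
                          : std::abs(err - prev) / std::max(prev, 1e-300);
    if (rel <= tol) { converged = true; ++c; break; }
    prev = err;
  }
  return List::create(_["state"] = net.state_out(),
                      _["converged"] = converged,
                      _["cycles"] = c,
                      _["err_trace"] = arma::vec(trace));
}
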