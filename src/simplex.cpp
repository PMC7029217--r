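// Bounded-variable two-phase primal simplex.
//
// Dense revised simplex with an explicitly maintained basis inverse
// (product-form eta updates, periodic refactorisation). Pivoting is
// deterministic: Dantzig pricing with a switch to Bland's rule after a fixed
// iteration budget guarantees termination without cycling; ties in the ratio
// test are broken by smallest variable index.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Work {
  arma::mat A;          // m x N (structurals + artificials)
  arma::vec b, lo, up, cost;
  arma::uvec basis;     // m basic column indices
  std::vector<int> where;   // -1 basic, 0 at lower/value, 1 at upper
  arma::vec nbval;      // value of nonbasic variables
  arma::mat Binv;
  int m, N;
  double tol;
};

void refactor(Work& w) {
  arma::mat B = w.A.cols(w.basis);
  w.Binv = arma::inv(B);
}

arma::vec basic_values(const Work& w) {
  arma::vec r = w.b;
  for (int j = 0; j < w.N; ++j) {
    if (w.where[j] >= 0 && w.nbval[j] != 0.0) r -= w.A.col(j) * w.nbval[j];
  }
  return w.Binv * r;
}

// returns: 0 optimal, 1 unbounded, 2 iteration limit, 3 numeric failure
int run_phase(Work& w, const arma::vec& cost, const std::vector<bool>& frozen,
              long max_iter, arma::vec& xb_out, arma::vec& y_out) {
  const double tol = w.tol;
  long it = 0, bland_after = 4L * (w.N + w.m);
  int since_refactor = 0;
  arma::vec xb = basic_values(w);
  for (;;) {
    if (++it > max_iter) return 2;
    bool bland = it > bland_after;
    arma::vec cb(w.m);
    for (int i = 0; i < w.m; ++i) cb(i) = cost(w.basis(i));
    arma::vec y = w.Binv.t() * cb;

    int enter = -1, dir = 0;
    double best = tol;
    for (int j = 0; j < w.N; ++j) {
      if (w.where[j] < 0 || frozen[j]) continue;
      bool lfin = std::isfinite(w.lo(j)), ufin = std::isfinite(w.up(j));
      if (lfin && ufin && w.up(j) - w.lo(j) <= tol) continue; // fixed
      double d = cost(j) - arma::dot(y, w.A.col(j));
      int dj = 0;
      if (!lfin && !ufin) {
        if (d < -tol) dj = 1; else if (d > tol) dj = -1;
      } else if (w.where[j] == 0 && d < -tol) dj = 1;
      else if (w.where[j] == 1 && d > tol) dj = -1;
      if (dj != 0) {
        if (bland) { enter = j; dir = dj; break; }
        double score = std::fabs(d);
        if (score > best) { best = score; enter = j; dir = dj; }
      }
    }
    if (enter < 0) { xb_out = xb; y_out = y; return 0; }

    arma::vec wv = w.Binv * w.A.col(enter);  // x_B changes by -wv*dir*theta
    double theta = std::numeric_limits<double>::infinity();
    int leave = -1; bool leave_up = false;
    for (int i = 0; i < w.m; ++i) {
      double wi = wv(i) * dir;
      int bi = (int)w.basis(i);
      double th; bool to_up;
      if (wi > tol) {
        if (!std::isfinite(w.lo(bi))) continue;
        th = (xb(i) - w.lo(bi)) / wi; to_up = false;
      } else if (wi < -tol) {
        if (!std::isfinite(w.up(bi))) continue;
        th = (xb(i) - w.up(bi)) / wi; to_up = true;
      } else continue;
      if (th < 0) th = 0;
      if (th < theta - tol ||
          (th < theta + tol && leave >= 0 && bi < (int)w.basis(leave))) {
        if (th < theta) theta = th;
        leave = i; leave_up = to_up;
      } else if (leave < 0 && th < theta + tol) {
        if (th < theta) theta = th;
        leave = i; leave_up = to_up;
      }
    }
    double span = w.up(enter) - w.lo(enter);
    if (std::isfinite(span) && span <= theta + tol) {
      // bound flip: entering variable jumps to its opposite bound
      w.where[enter] = 1 - w.where[enter];
      double old = w.nbval[enter];
      w.nbval[enter] = (w.where[enter] == 1) ? w.up(enter) : w.lo(enter);
      xb -= w.Binv * (w.A.col(enter) * (w.nbval[enter] - old));
      continue;
    }
    if (leave < 0 || !std::isfinite(theta)) return 1;  // unbounded

    int out = (int)w.basis(leave);
    double enter_old = w.nbval[enter];
    double enter_new = enter_old + dir * theta;
    // update basic values
    xb -= wv * (dir * theta);
    xb(leave) = enter_new;
    // statuses
    w.where[out] = leave_up ? 1 : 0;
    w.nbval[out] = leave_up ? w.up(out) : w.lo(out);
    w.basis(leave) = (arma::uword)enter;
    w.where[enter] = -1;
    w.nbval[enter] = 0.0;
    // eta update of Binv
    double piv = wv(leave);
    if (std::fabs(piv) < 1e-11 || ++since_refactor >= 80) {
      refactor(w);
      since_refactor = 0;
      xb = basic_values(w);
    } else {
      arma::rowvec br = w.Binv.row(leave) / piv;
      for (int i = 0; i < w.m; ++i) {
        if (i == leave) continue;
        double f = wv(i);
        if (f != 0.0) w.Binv.row(i) -= f * br;
      }
      w.Binv.row(leave) = br;
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_simplex")]]
List cpp_simplex(const arma::mat& A, const arma::vec& b, const arma::vec& cc,
                 const arma::vec& lo, const arma::vec& up,
                 double tol, long max_iter) {
  int m = (int)A.n_rows, n = (int)A.n_cols;
  Work w;
  w.m = m; w.N = n + m; w.tol = tol;
  w.A.set_size(m, w.N);
  w.A.cols(0, n - 1) = A;
  w.b = b;
  w.lo.set_size(w.N); w.up.set_size(w.N);
  w.lo.subvec(0, n - 1) = lo; w.up.subvec(0, n - 1) = up;
  w.nbval.set_size(w.N); w.nbval.zeros();
  w.where.assign(w.N, 0);

  // nonbasic start at the finite bound nearest zero
  for (int j = 0; j < n; ++j) {
    bool lf = std::isfinite(lo(j)), uf = std::isfinite(up(j));
    if (lf && uf) {
      if (std::fabs(lo(j)) <= std::fabs(up(j))) { w.where[j] = 0; w.nbval[j] = lo(j); }
      else { w.where[j] = 1; w.nbval[j] = up(j); }
    } else if (lf) { w.where[j] = 0; w.nbval[j] = lo(j); }
    else if (uf) { w.where[j] = 1; w.nbval[j] = up(j); }
    else { w.where[j] = 0; w.nbval[j] = 0.0; }
  }
  // artificial columns, signed to make the start basic-feasible
  arma::vec r = b;
  for (int j = 0; j < n; ++j)
    if (w.nbval[j] != 0.0) r -= A.col(j) * w.nbval[j];
  w.basis.set_size(m);
  for (int i = 0; i < m; ++i) {
    int aj = n + i;
    w.A.col(aj).zeros();
    w.A(i, aj) = (r(i) >= 0) ? 1.0 : -1.0;
    w.lo(aj) = 0.0; w.up(aj) = std::numeric_limits<double>::infinity();
    w.basis(i) = (arma::uword)aj;
    w.where[aj] = -1;
  }
  refactor(w);

  std::vector<bool> frozen1(w.N, false);
  arma::vec cost1(w.N, arma::fill::zeros);
  for (int i = 0; i < m; ++i) cost1(n + i) = 1.0;
  arma::vec xb, y;
  int st = run_phase(w, cost1, frozen1, max_iter, xb, y);
  if (st == 1) return List::create(_["status"] = "infeasible");
  if (st != 0) return List::create(_["status"] = st == 2 ? "maxiter" : "singular");
  double p1 = 0;
  for (int i = 0; i < m; ++i) {
    int bi = (int)w.basis(i);
    if (bi >= n) p1 += xb(i);
  }
  for (int j = n; j < w.N; ++j)
    if (w.where[j] >= 0) p1 += w.nbval[j];
  if (p1 > 1e-7) return List::create(_["status"] = "infeasible");

  // pin artificials at zero, forbid re-entry
  std::vector<bool> frozen2(w.N, false);
  arma::vec cost2(w.N, arma::fill::zeros);
  cost2.subvec(0, n - 1) = cc;
  for (int j = n; j < w.N; ++j) {
    w.up(j) = 0.0;
    if (w.where[j] >= 0) { w.where[j] = 0; w.nbval[j] = 0.0; }
    frozen2[j] = true;
  }
  st = run_phase(w, cost2, frozen2, max_iter, xb, y);
  if (st == 1) return List::create(_["status"] = "unbounded");
  if (st != 0) return List::create(_["status"] = st == 2 ? "maxiter" : "singular");

  arma::vec x(n);
  for (int j = 0; j < n; ++j) x(j) = (w.where[j] >= 0) ? w.nbval[j] : 0.0;
  for (int i = 0; i < m; ++i) {
    int bi = (int)w.basis(i);
    if (bi < n) x(bi) = xb(i);
  }
  double obj = arma::dot(cc, x);
  return List::create(_["status"] = "optimal", _["x"] = x,
                      _["objective"] = obj,
                      _["y"] = arma::vec(y));
}
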