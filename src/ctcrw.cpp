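// Continuous-time correlated random walk (integrated Ornstein-Uhlenbeck
// velocity) Kalman filter and RTS smoother over irregular observation times.
//
// State alpha_t = (x, v_x, y, v_y) in a planar working projection (meters,
// m/s).  Velocity follows dv = -beta v dt + sigma dW independently in x and
// y; position integrates velocity.  Exact discretisation over a gap dt:
//   v' = phi v + eta_v,          phi = exp(-beta dt)
//   x' = x + v (1 - phi)/beta + eta_x
// with process covariance (per dimension)
//   Q_vv = s2 (1 - phi^2) / (2 beta)
//   Q_xv = s2 (1 - phi)^2 / (2 beta^2)
//   Q_xx = s2 (dt - 2(1-phi)/beta + (1-phi^2)/(2 beta)) / beta^2
// Observations are planar positions with a per-fix 2x2 error covariance
// (from the Argos error ellipse), optionally inflated by a factor psi.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static void trans_mats(double dt, double beta, double s2,
                       mat &T, mat &Q) {
  double b = beta * dt;
  double phi, ixv, qvv, qxv, qxx;
  if (b < 1e-4) {
    // integrated-random-walk limit: the exact expressions cancel
    // catastrophically as beta -> 0, so switch to their Taylor series
    phi = std::exp(-b);
    ixv = dt * (1.0 - b / 2.0 + b * b / 6.0);
    qvv = s2 * dt * (1.0 - b + 2.0 * b * b / 3.0);
    qxv = s2 * dt * dt / 2.0 * (1.0 - b + 7.0 * b * b / 12.0);
    qxx = s2 * dt * dt * dt / 3.0 * (1.0 - 3.0 * b / 4.0);
  } else {
    phi = std::exp(-b);
    ixv = (1.0 - phi) / beta;                 // integral of phi
    qvv = s2 * (1.0 - phi * phi) / (2.0 * beta);
    qxv = s2 * (1.0 - phi) * (1.0 - phi) / (2.0 * beta * beta);
    qxx = s2 * (dt - 2.0 * ixv + (1.0 - phi * phi) / (2.0 * beta)) /
          (beta * beta);
  }
  T.eye(4, 4);
  T(0, 1) = ixv;
  T(1, 1) = phi;
  T(2, 3) = ixv;
  T(3, 3) = phi;
  Q.zeros(4, 4);
  Q(0, 0) = qxx; Q(0, 1) = qxv; Q(1, 0) = qxv; Q(1, 1) = qvv;
  Q(2, 2) = qxx; Q(2, 3) = qxv; Q(3, 2) = qxv; Q(3, 3) = qvv;
}

// [[Rcpp::export(name = ".ctcrw_kalman_cpp")]]
Rcpp::List ctcrw_kalman(const arma::vec &tsec,
                        const arma::mat &z,      // n x 2, NaN = no obs
                        const arma::mat &Robs,   // n x 3: rxx, ryy, rxy
                        double beta, double s2, double psi,
                        const arma::vec &a0, const arma::vec &P0diag,
                        bool smooth) {
  const uword n = tsec.n_elem;
  mat H(2, 4, fill::zeros);
  H(0, 0) = 1.0; H(1, 2) = 1.0;

  cube Ppred(4, 4, n), Pfilt(4, 4, n);
  mat apred(4, n), afilt(4, n);
  double ll = 0.0;
  bool ok = true;

  vec a = a0;
  mat P = diagmat(P0diag);
  mat T(4, 4), Q(4, 4);

  for (uword i = 0; i < n; ++i) {
    if (i > 0) {
      double dt = tsec(i) - tsec(i - 1);
      if (dt > 0) {
        trans_mats(dt, beta, s2, T, Q);
        a = T * a;
        P = T * P * T.t() + Q;
      }
    }
    apred.col(i) = a;
    Ppred.slice(i) = P;

    bool has = std::isfinite(z(i, 0)) && std::isfinite(z(i, 1));
    if (has) {
      mat R(2, 2);
      R(0, 0) = psi * Robs(i, 0); R(1, 1) = psi * Robs(i, 1);
      R(0, 1) = psi * Robs(i, 2); R(1, 0) = psi * Robs(i, 2);
      vec v = z.row(i).t() - H * a;
      mat F = H * P * H.t() + R;
      F = 0.5 * (F + F.t());
      double detF = F(0, 0) * F(1, 1) - F(0, 1) * F(1, 0);
      if (!(detF > 0.0) || !F.is_finite()) { ok = false; break; }
      mat Fi(2, 2);
      Fi(0, 0) =  F(1, 1) / detF; Fi(1, 1) =  F(0, 0) / detF;
      Fi(0, 1) = -F(0, 1) / detF; Fi(1, 0) = -F(1, 0) / detF;
      ll += -std::log(2.0 * datum::pi) - 0.5 * std::log(detF) -
            0.5 * as_scalar(v.t() * Fi * v);
      mat K = P * H.t() * Fi;
      a = a + K * v;
      P = P - K * H * P;
      P = 0.5 * (P + P.t());
    }
    afilt.col(i) = a;
    Pfilt.slice(i) = P;
  }

  if (!ok) {
    return Rcpp::List::create(Rcpp::Named("loglik") = -1e10,
                              Rcpp::Named("ok") = false);
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("ok") = true,
      Rcpp::Named("filt_mean") = afilt.t(),
      Rcpp::Named("filt_cov") = Pfilt);

  if (smooth) {
    mat asm_(4, n);
    cube Psm(4, 4, n);
    cube Jg(4, 4, n);          // smoother gain J_t, t = 0..n-2
    Jg.slice(n - 1).eye();
    asm_.col(n - 1) = afilt.col(n - 1);
    Psm.slice(n - 1) = Pfilt.slice(n - 1);
    for (uword k = n - 1; k-- > 0;) {
      double dt = tsec(k + 1) - tsec(k);
      if (dt > 0) {
        trans_mats(dt, beta, s2, T, Q);
        mat Pp = Ppred.slice(k + 1);
        mat J = Pfilt.slice(k) * T.t() * pinv(Pp);
        asm_.col(k) = afilt.col(k) + J * (asm_.col(k + 1) - apred.col(k + 1));
        Psm.slice(k) = Pfilt.slice(k) +
                       J * (Psm.slice(k + 1) - Pp) * J.t();
        Jg.slice(k) = J;
      } else {
        asm_.col(k) = asm_.col(k + 1);
        Psm.slice(k) = Psm.slice(k + 1);
        Jg.slice(k).eye();
      }
    }
    out["smooth_mean"] = asm_.t();
    out["smooth_cov"] = Psm;
    out["smooth_gain"] = Jg;
  }
  return out;
}
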