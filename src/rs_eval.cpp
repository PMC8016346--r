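// Batched evaluation of the reduced muscle-redundancy transcription.
//
// Mirrors the reference R implementation (rs_batch_eval) exactly: 2-stage
// Radau IIA propagation of activation and tendon-force states with the
// collocation defects removed by inner Newton iterations, reserves
// eliminated through the moment balance, and the six-term objective
// accumulated by the Radau quadrature. Each column of `theta` is an
// independent decision vector, which is what makes cheap batched
// finite-difference gradients possible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// active force-length Gaussian-sum coefficients
static const double FL_B1[3] = {0.814483478343008, 0.433004984392647, 0.1};
static const double FL_B2[3] = {1.055033428970575, 0.716775413397760, 1.0};
static const double FL_B3[3] = {0.162384573599574, -0.029947116970696,
                                0.353553390593273762};
static const double FL_B4[3] = {0.063303448465465, 0.200356847296188, 0.0};

static double fl_raw_scalar(double x) {
  double out = 0.0;
  for (int i = 0; i < 3; ++i) {
    double w = FL_B3[i] + FL_B4[i] * x;
    double z = (x - FL_B2[i]) / w;
    out += FL_B1[i] * std::exp(-0.5 * z * z);
  }
  return out;
}
static const double FL_NORM = fl_raw_scalar(1.0);

static mat f_active_m(const mat& x) {
  mat out(size(x), fill::zeros);
  for (int i = 0; i < 3; ++i) {
    mat w = FL_B3[i] + FL_B4[i] * x;
    mat z = (x - FL_B2[i]) / w;
    out += FL_B1[i] * exp(-0.5 * square(z));
  }
  return out / FL_NORM;
}

// passive curve constants (see R/curves.R)
static const double FP_KPE = 4.0, FP_E0 = 0.6, FP_DELTA = 1e-6;
static mat f_passive_m(const mat& x) {
  mat d = x - 1.0;
  mat r = 0.5 * (d + sqrt(square(d) + FP_DELTA * FP_DELTA) - FP_DELTA);
  return (exp(FP_KPE * r / FP_E0) - 1.0) / std::expm1(FP_KPE);
}

// force-velocity constants; D4 re-solved so f_v(0) = 1
static const double FV_D1 = -0.318323436899127;
static const double FV_D2 = -8.149156043475250;
static const double FV_D3 = -0.374121508647863;
static const double FV_D4 = 1.0 - FV_D1 * std::asinh(FV_D3);

static mat f_velocity_m(const mat& v) {
  mat u = FV_D2 * v + FV_D3;
  return FV_D1 * log(u + sqrt(square(u) + 1.0)) + FV_D4;
}
static mat fv_slope_m(const mat& v) {
  mat u = FV_D2 * v + FV_D3;
  return (FV_D1 * FV_D2) / sqrt(square(u) + 1.0);
}
static mat fv_inverse_m(const mat& f) {
  return (sinh((f - FV_D4) / FV_D1) - FV_D3) / FV_D2;
}
static mat fl_slope_m(const mat& x) {
  mat out(size(x), fill::zeros);
  for (int i = 0; i < 3; ++i) {
    mat w = FL_B3[i] + FL_B4[i] * x;
    mat z = (x - FL_B2[i]) / w;
    mat dz = (w - (x - FL_B2[i]) * FL_B4[i]) / square(w);
    out += FL_B1[i] * exp(-0.5 * square(z)) % (-z) % dz;
  }
  return out / FL_NORM;
}
static mat fp_slope_m(const mat& x) {
  mat d = x - 1.0;
  mat rp = 0.5 * (1.0 + d / sqrt(square(d) + FP_DELTA * FP_DELTA));
  mat r = 0.5 * (d + sqrt(square(d) + FP_DELTA * FP_DELTA) - FP_DELTA);
  return (FP_KPE / FP_E0) * rp % exp(FP_KPE * r / FP_E0) /
         std::expm1(FP_KPE);
}

// solve afa * f_v(v) + beta * v = rhs for v: warm closed-form start
// (exact for beta -> 0) plus safeguarded Newton within a maintained
// bracket (branchless mask arithmetic)
static mat solve_vtilde_m(const mat& rhs, const mat& afa, double beta) {
  const double B = 50.0;
  static const double f_lo = FV_D1 * std::asinh(FV_D2 * (-49.9) + FV_D3) +
                             FV_D4;
  static const double f_hi = FV_D1 * std::asinh(FV_D2 * (49.9) + FV_D3) +
                             FV_D4;
  mat lo(size(rhs)); lo.fill(-B);
  mat hi(size(rhs)); hi.fill(B);
  mat arg = clamp(rhs / (afa + 1e-12), std::min(f_lo, f_hi),
                  std::max(f_lo, f_hi));
  mat v = clamp(fv_inverse_m(arg), -B, B);
  for (int it = 0; it < 8; ++it) {
    mat g = afa % f_velocity_m(v) + beta * v - rhs;
    mat pos = conv_to<mat>::from(g > 0);
    hi = pos % v + (1.0 - pos) % hi;
    lo = (1.0 - pos) % v + pos % lo;
    mat dg = afa % fv_slope_m(v) + beta;
    mat vn = v - g / dg;
    mat bad = conv_to<mat>::from((vn < lo) || (vn > hi) || (vn != vn));
    v = bad % (0.5 * (lo + hi)) + (1.0 - bad) % vn;
  }
  return v;
}

struct ContractionOut {
  mat dftilde, lstar, fpass, ddftilde;
};

// implicit contraction dynamics (tendon force state); all matrix args
// m x C; with want_grad the exact derivative of the rate with respect to
// the normalized tendon force is also computed (chain rule through the
// tendon inverse, the constant-thickness geometry and the implicit
// velocity solve)
static ContractionOut contraction_rate_m(
    const mat& ftilde, const mat& a, const vec& lmt, const vec& lmtdot,
    const mat& lo, const mat& LS, const mat& h, const mat& vmax,
    const mat& kp, double c3, double beta,
    double geom_eps, bool want_grad = false) {
  mat ftc = ftilde;
  ftc.elem(find(ftc < -c3 + 1e-9)).fill(-c3 + 1e-9);
  mat ltn = 1.0 + log1p(ftc / c3) / kp;
  mat lT = -(LS % ltn);
  mat proj = lT.each_col() + lmt;      // lmt - lT
  proj.elem(find(proj < geom_eps)).fill(geom_eps);
  mat ell = sqrt(square(proj) + square(h));
  mat cosa = proj / ell;
  mat lstar = ell / lo;
  mat fpass = f_passive_m(lstar);
  mat afa = a % f_active_m(lstar);
  mat rhs = ftc / cosa - fpass;
  mat vt = solve_vtilde_m(rhs, afa, beta);
  mat neg_elldot = -(vt % vmax % lo) / cosa;   // -elldot/cosa
  mat lTdot = neg_elldot.each_col() + lmtdot;  // lmtdot - elldot/cosa
  ContractionOut out;
  out.dftilde = kp % (ftc + c3) % lTdot / LS;
  out.lstar = lstar;
  out.fpass = fpass;
  if (want_grad) {
    mat elldot = vt % vmax % lo;
    mat dproj = -LS / (kp % (ftc + c3));
    mat dcosa = dproj % (1.0 - square(cosa)) / ell;
    mat dlstar = cosa % dproj / lo;
    mat drhs = 1.0 / cosa - ftc % dcosa / square(cosa) -
               fp_slope_m(lstar) % dlstar;
    mat dafa = a % fl_slope_m(lstar) % dlstar;
    mat dvt = (drhs - dafa % f_velocity_m(vt)) /
              (afa % fv_slope_m(vt) + beta);
    mat delldot = dvt % vmax % lo;
    mat dlTdot = -(delldot % cosa - elldot % dcosa) / square(cosa);
    out.ddftilde = kp % (lTdot + (ftc + c3) % dlTdot) / LS;
  }
  return out;
}

// smooth-blend activation rate and its derivative in a
static const double ACT_W = 0.1;
static mat act_rate_m(const mat& e, const mat& a, const mat& ta,
                      const mat& td) {
  mat s = 0.5 + 0.5 * tanh((e - a) / ACT_W);
  mat tau = td + (ta - td) % s;
  return (e - a) / tau;
}
static mat act_rate_da_m(const mat& e, const mat& a, const mat& ta,
                         const mat& td) {
  mat u = (e - a) / ACT_W;
  mat th = tanh(u);
  mat s = 0.5 + 0.5 * th;
  mat ds = -0.5 * (1.0 - square(th)) / ACT_W;
  mat tau = td + (ta - td) % s;
  mat dtau = (ta - td) % ds;
  return -1.0 / tau - (e - a) % dtau / square(tau);
}

// [[Rcpp::export]]
Rcpp::List rs_batch_eval_cpp(const arma::mat& theta, const Rcpp::List& prob,
                             const arma::ivec& col_trial,
                             const arma::ivec& col_start) {
  const int m = Rcpp::as<int>(prob["m"]);
  const int K = Rcpp::as<int>(prob["K"]);
  const int C = theta.n_cols;
  const double beta = Rcpp::as<double>(prob["beta"]);
  const double geom_eps = 1e-6;

  Rcpp::List wl = prob["weights"];
  const double w1 = Rcpp::as<double>(wl["w1"]);
  const double w2 = Rcpp::as<double>(wl["w2"]);
  const double w3 = Rcpp::as<double>(wl["w3"]);
  const double w4 = Rcpp::as<double>(wl["w4"]);
  const double w5 = Rcpp::as<double>(wl["w5"]);
  const double w6 = Rcpp::as<double>(wl["w6"]);

  vec lo0 = Rcpp::as<vec>(prob["lo0"]);
  vec LS0 = Rcpp::as<vec>(prob["LS0"]);
  vec sina0 = Rcpp::as<vec>(prob["sina0"]);
  vec Fmax = Rcpp::as<vec>(prob["Fmax"]);
  vec vmax_v = Rcpp::as<vec>(prob["vmax"]);
  vec tau_a_v = Rcpp::as<vec>(prob["tau_a"]);
  vec tau_d_v = Rcpp::as<vec>(prob["tau_d"]);
  Rcpp::List tcl = prob["tc"];
  vec kp_v = Rcpp::as<vec>(tcl["kp"]);
  if (kp_v.n_elem == 1) kp_v = vec(m, fill::value(kp_v(0)));
  const double c3 = Rcpp::as<double>(tcl["c3"]);

  mat p_ell(m, C, fill::ones), p_L(m, C, fill::ones);
  bool has_tune = !Rf_isNull(prob["tune_idx"]);
  if (has_tune) {
    Rcpp::List ti = prob["tune_idx"];
    uvec ip = Rcpp::as<uvec>(ti["p_ell"]) - 1;
    uvec iL = Rcpp::as<uvec>(ti["p_L"]) - 1;
    p_ell = theta.rows(ip);
    p_L = theta.rows(iL);
  }
  mat LO_full = repmat(lo0, 1, C) % p_ell;
  mat LS_full = repmat(LS0, 1, C) % p_L;
  mat H_full = LO_full.each_col() % sina0;

  const double A11 = 5.0 / 12.0, A12 = -1.0 / 12.0;
  const double A21 = 3.0 / 4.0, A22 = 1.0 / 4.0;

  rowvec J(C, fill::zeros);
  mat parts(6, C, fill::zeros);

  Rcpp::List trials = prob["trials"];
  Rcpp::List idx = prob["idx"];
  for (int j = 0; j < trials.size(); ++j) {
    Rcpp::List tr = trials[j];
    Rcpp::List id = idx[j];
    const int n = Rcpp::as<int>(tr["n"]);
    const double hstep = Rcpp::as<double>(tr["h"]);
    const double srate = Rcpp::as<double>(tr["s_rate"]);
    mat LMT = Rcpp::as<mat>(tr["LMT"]);
    mat LMTD = Rcpp::as<mat>(tr["LMTD"]);
    cube ARMS = Rcpp::as<cube>(tr["ARMS"]);
    mat MEXT = Rcpp::as<mat>(tr["MEXT"]);
    vec caps = Rcpp::as<vec>(tr["caps"]);
    vec wq = Rcpp::as<vec>(tr["wq"]);

    uvec ia0 = Rcpp::as<uvec>(id["a0"]) - 1;
    uvec if0 = Rcpp::as<uvec>(id["f0"]) - 1;
    uvec iE = Rcpp::as<uvec>(id["E"]) - 1;

    // columns relevant to this trial, ordered by start interval; other
    // columns reuse the base column's contribution
    std::vector<uword> act;
    for (int c = 0; c < C; ++c) {
      if (col_trial(c) == 0 || col_trial(c) == j + 1) act.push_back(c);
    }
    const uword na = act.size();
    uvec ord(na);
    {
      std::vector<uword> tmp(act);
      std::stable_sort(tmp.begin(), tmp.end(), [&](uword a, uword b) {
        return col_start(a) < col_start(b);
      });
      for (uword c = 0; c < na; ++c) ord(c) = tmp[c];
    }
    ivec starts(na);
    for (uword c = 0; c < na; ++c) starts(c) = col_start(ord(c));

    mat LO = LO_full.cols(ord);
    mat LS = LS_full.cols(ord);
    mat H = H_full.cols(ord);
    mat VM = repmat(vmax_v, 1, na);
    mat TA = repmat(tau_a_v, 1, na);
    mat TD = repmat(tau_d_v, 1, na);
    mat KP = repmat(kp_v, 1, na);

    mat As = theta.submat(ia0, ord);
    mat Fs = theta.submat(if0, ord);
    mat kprevs(m, na, fill::zeros);
    rowvec acc1(na, fill::zeros), acc2(na, fill::zeros),
        acc3(na, fill::zeros), acc4(na, fill::zeros), acc5(na, fill::zeros);

    uword cur = 0;
    while (cur < na && starts(cur) <= 0) ++cur;

    for (int i = 0; i < n; ++i) {
      // activate columns whose first affected interval is i: their
      // trajectory equals the base column's up to here
      while (cur < na && starts(cur) <= i) {
        // inherit the base column's state AND accumulated objective:
        // the perturbed trajectory is identical up to this interval
        As.col(cur) = As.col(0);
        Fs.col(cur) = Fs.col(0);
        kprevs.col(cur) = kprevs.col(0);
        acc1(cur) = acc1(0); acc2(cur) = acc2(0); acc3(cur) = acc3(0);
        acc4(cur) = acc4(0); acc5(cur) = acc5(0);
        ++cur;
      }
      uvec cols = ord.head(cur);
      mat E1 = theta.submat(iE.subvec((2 * i) * m, (2 * i + 1) * m - 1),
                            cols);
      mat E2 = theta.submat(iE.subvec((2 * i + 1) * m,
                                      (2 * i + 2) * m - 1), cols);
      const int s1 = 2 * i, s2 = 2 * i + 1;
      mat A = As.head_cols(cur), Fv = Fs.head_cols(cur);
      mat LOc = LO.head_cols(cur), LSc = LS.head_cols(cur),
          Hc = H.head_cols(cur), VMc = VM.head_cols(cur),
          TAc = TA.head_cols(cur), TDc = TD.head_cols(cur),
          KPc = KP.head_cols(cur);

      mat A1 = A, A2 = A;
      for (int it = 0; it < 4; ++it) {
        mat f1 = act_rate_m(E1, A1, TAc, TDc);
        mat f2 = act_rate_m(E2, A2, TAc, TDc);
        mat g1 = A1 - A - hstep * (A11 * f1 + A12 * f2);
        mat g2 = A2 - A - hstep * (A21 * f1 + A22 * f2);
        mat d1 = act_rate_da_m(E1, A1, TAc, TDc);
        mat d2 = act_rate_da_m(E2, A2, TAc, TDc);
        mat J11 = 1.0 - hstep * A11 * d1, J12 = -hstep * A12 * d2;
        mat J21 = -hstep * A21 * d1, J22 = 1.0 - hstep * A22 * d2;
        mat det = J11 % J22 - J12 % J21;
        A1 -= (J22 % g1 - J12 % g2) / det;
        A2 -= (-J21 % g1 + J11 % g2) / det;
      }
      mat f1 = act_rate_m(E1, A1, TAc, TDc);
      mat f2 = act_rate_m(E2, A2, TAc, TDc);

      vec lmt1 = LMT.col(s1), lmt2 = LMT.col(s2);
      vec lmd1 = LMTD.col(s1), lmd2 = LMTD.col(s2);
      mat F1 = Fv + kprevs.head_cols(cur) * (hstep / 3.0);
      mat F2 = Fv + kprevs.head_cols(cur) * hstep;
      ContractionOut r1, r2;
      // Newton with the exact analytic stage Jacobian
      for (int it = 0; it < 6; ++it) {
        r1 = contraction_rate_m(F1, A1, lmt1, lmd1, LOc, LSc, Hc, VMc,
                                KPc, c3, beta, geom_eps, true);
        r2 = contraction_rate_m(F2, A2, lmt2, lmd2, LOc, LSc, Hc, VMc,
                                KPc, c3, beta, geom_eps, true);
        mat g1c = F1 - Fv - hstep * (A11 * r1.dftilde + A12 * r2.dftilde);
        mat g2c = F2 - Fv - hstep * (A21 * r1.dftilde + A22 * r2.dftilde);
        mat J11 = 1.0 - hstep * A11 * r1.ddftilde;
        mat J12 = -hstep * A12 * r2.ddftilde;
        mat J21 = -hstep * A21 * r1.ddftilde;
        mat J22 = 1.0 - hstep * A22 * r2.ddftilde;
        mat det = J11 % J22 - J12 % J21;
        mat dF1 = (J22 % g1c - J12 % g2c) / det;
        mat dF2 = (-J21 % g1c + J11 % g2c) / det;
        F1 -= dF1;
        F2 -= dF2;
        if (std::max(abs(dF1).max(), abs(dF2).max()) < 1e-11) break;
      }
      r1 = contraction_rate_m(F1, A1, lmt1, lmd1, LOc, LSc, Hc, VMc, KPc,
                              c3, beta, geom_eps);
      r2 = contraction_rate_m(F2, A2, lmt2, lmd2, LOc, LSc, Hc, VMc, KPc,
                              c3, beta, geom_eps);

      const double wq1 = wq(s1), wq2 = wq(s2);
      acc1.head(cur) += wq1 * sum(square(A1), 0) + wq2 * sum(square(A2), 0);
      acc3.head(cur) += (wq1 * sum(square(f1), 0) +
                         wq2 * sum(square(f2), 0)) / (srate * srate);
      acc4.head(cur) += (wq1 * sum(square(r1.dftilde), 0) +
                         wq2 * sum(square(r2.dftilde), 0)) /
                        (srate * srate);
      acc5.head(cur) += wq1 * sum(square(r1.fpass), 0) +
                        wq2 * sum(square(r2.fpass), 0);
      for (int k = 0; k < K; ++k) {
        vec wk1 = Fmax % ARMS.slice(k).col(s1);
        vec wk2 = Fmax % ARMS.slice(k).col(s2);
        rowvec Mm1 = sum(F1.each_col() % wk1, 0);
        rowvec Mm2 = sum(F2.each_col() % wk2, 0);
        rowvec ar1 = (MEXT(k, s1) - Mm1) / caps(k);
        rowvec ar2 = (MEXT(k, s2) - Mm2) / caps(k);
        acc2.head(cur) += wq1 * square(ar1) + wq2 * square(ar2);
      }
      As.head_cols(cur) = A2;
      Fs.head_cols(cur) = F2;
      kprevs.head_cols(cur) = r2.dftilde;
    }

    // scatter this trial's contribution; columns not simulated for this
    // trial take the base column's value
    rowvec tJ(C); tJ.fill(w1 * acc1(0) + w2 * acc2(0) +
                          w3 * (acc3(0) + acc4(0)) + w4 * acc5(0));
    rowvec t1f(C); t1f.fill(acc1(0));
    rowvec t2f(C); t2f.fill(acc2(0));
    rowvec t34f(C); t34f.fill(acc3(0) + acc4(0));
    rowvec t4f(C); t4f.fill(acc5(0));
    for (uword c = 0; c < na; ++c) {
      const uword cc = ord(c);
      tJ(cc) = w1 * acc1(c) + w2 * acc2(c) + w3 * (acc3(c) + acc4(c)) +
               w4 * acc5(c);
      t1f(cc) = acc1(c);
      t2f(cc) = acc2(c);
      t34f(cc) = acc3(c) + acc4(c);
      t4f(cc) = acc5(c);
    }
    J += tJ;
    parts.row(0) += w1 * t1f;
    parts.row(1) += w2 * t2f;
    parts.row(2) += w3 * t34f;
    parts.row(3) += w4 * t4f;
  }
  rowvec t5 = w5 * sum(square(p_ell - 1.0), 0);
  rowvec t6 = w6 * sum(square(p_L - 1.0), 0);
  J += t5 + t6;
  parts.row(4) = t5;
  parts.row(5) = t6;
  return Rcpp::List::create(Rcpp::Named("J") = J.t(),
                            Rcpp::Named("parts") = parts);
}
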