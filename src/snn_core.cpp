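// Batched forward roll-out and BPTT adjoint pass for recurrent networks of
// LIF neurons with an adaptive (spike-frequency adapting) threshold.
//
// Time indexing (0-based step t, dt = 1 ms):
//   c(t)  = Win x(t-2) + Wrec_eff z(t-2)            synaptic delay of 1 ms on
//                                                   top of the 1-step integration
//   vp(t) = alpha v(t-1) + (1-alpha) c(t)           pre-reset membrane potential
//   a(t)  = rho a(t-1) + (1-rho) z(t-1)             threshold adaptation trace
//   A(t)  = v_th + beta a(t)                        (floored at 0.01 v_th)
//   z(t)  = gate(t) * H((vp(t)-A(t))/A(t))          gate = not refractory
//   v(t)  = vp(t) - v_th z(t)                       reset by subtraction
//   s(t)  = kappa s(t-1) + z(t)                     readout trace
//   y(t)  = Wout s(t) + bout
//
// The backward pass differentiates this exact graph, replacing dz/dv_norm by
// the dampened pseudo-derivative gamma*max(0, 1-|v_norm|); the refractory
// gate and the spike's effect on future gating carry no gradient. Synaptic
// sums use BLAS; all per-neuron updates run in fused element-wise loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List snn_forward_cpp(const arma::cube& x,      // B x n_in x T
                           const arma::mat& Win,     // n_rec x n_in
                           const arma::mat& Wrec,    // n_rec x n_rec
                           const arma::mat& Wout,    // n_out x n_rec
                           const arma::vec& bout,    // n_out
                           const arma::vec& alpha,   // n_rec
                           const arma::vec& rho,     // n_rec
                           const arma::vec& beta,    // n_rec
                           double v_th,
                           int n_ref,
                           double kappa,
                           double gamma,
                           bool record_grad,
                           bool use_stp,
                           const arma::vec& stp_U,    // n_rec (per presynaptic neuron)
                           const arma::vec& stp_eF,   // exp(-dt/F)
                           const arma::vec& stp_eD) { // exp(-dt/D)
  const uword B = x.n_rows, T = x.n_slices, n = Win.n_rows,
              n_out = Wout.n_rows;
  const double A_floor = 0.01 * v_th;

  mat v(B, n, fill::zeros), a(B, n, fill::zeros), s(B, n, fill::zeros);
  mat refr(B, n, fill::zeros);
  mat z1(B, n, fill::zeros), z2(B, n, fill::zeros);
  mat cur(B, n, fill::zeros), zeff(B, n);
  const mat WinT = Win.t(), WrecT = Wrec.t(), WoutT = Wout.t();

  // STP state per (batch, presynaptic neuron); identical across postsynaptic
  // targets because U, F, D are shared per presynaptic neuron.
  mat up, rp;
  if (use_stp) { up.zeros(B, n); rp.zeros(B, n); }

  cube Z(B, n, T, fill::none), A_rec(B, n, T, fill::none),
      Y(B, n_out, T, fill::none), Vc(B, n, T, fill::none);
  cube VP, PD, S;
  if (record_grad) {
    VP.set_size(B, n, T); PD.set_size(B, n, T); S.set_size(B, n, T);
  }
  bool finite_ok = true;

  for (uword t = 0; t < T; ++t) {
    if (t >= 2) {
      cur = x.slice(t - 2) * WinT;
      if (use_stp) {
        // transmission factors are the state before this spike arrives
        double* ze = zeff.memptr();
        const double* z2p = z2.memptr();
        const double* upp = up.memptr();
        const double* rpp = rp.memptr();
        for (uword j = 0; j < n; ++j) {
          const double U = stp_U(j);
          for (uword b = 0; b < B; ++b) {
            uword k = j * B + b;
            ze[k] = z2p[k] * (U + upp[k]) * (1.0 - rpp[k]);
          }
        }
        cur += zeff * WrecT;
        for (uword j = 0; j < n; ++j) {
          const double U = stp_U(j), eF = stp_eF(j), eD = stp_eD(j);
          double* upc = up.colptr(j);
          double* rpc = rp.colptr(j);
          const double* z2c = z2.colptr(j);
          for (uword b = 0; b < B; ++b) {
            double u_now = U + upc[b], r_now = 1.0 - rpc[b];
            upc[b] = eF * upc[b] + U * (1.0 - u_now) * z2c[b];
            rpc[b] = eD * rpc[b] + u_now * r_now * z2c[b];
          }
        }
      } else {
        cur += z2 * WrecT;
      }
    } else {
      cur.zeros();
    }

    double* Zp = Z.slice_memptr(t);
    double* Ap = A_rec.slice_memptr(t);
    double* Vp_ = Vc.slice_memptr(t);
    double* VPp = record_grad ? VP.slice_memptr(t) : nullptr;
    double* PDp = record_grad ? PD.slice_memptr(t) : nullptr;
    double* Sp = record_grad ? S.slice_memptr(t) : nullptr;

    for (uword j = 0; j < n; ++j) {
      const double al = alpha(j), rh = rho(j), be = beta(j);
      double* vc = v.colptr(j);
      double* ac = a.colptr(j);
      double* sc = s.colptr(j);
      double* rc = refr.colptr(j);
      double* z1c = z1.colptr(j);
      double* z2c = z2.colptr(j);
      const double* cc = cur.colptr(j);
      const uword off = j * B;
      for (uword b = 0; b < B; ++b) {
        double vp = al * vc[b] + (1.0 - al) * cc[b];
        double at = rh * ac[b] + (1.0 - rh) * z1c[b];
        double A = v_th + be * at;
        if (A < A_floor) A = A_floor;
        double vn = (vp - A) / A;
        bool gated = rc[b] > 0.5;
        double z = (!gated && vn >= 0.0) ? 1.0 : 0.0;
        rc[b] = (z > 0.5) ? (double)n_ref : (gated ? rc[b] - 1.0 : 0.0);
        double vnew = vp - v_th * z;
        double snew = kappa * sc[b] + z;
        vc[b] = vnew; ac[b] = at; sc[b] = snew;
        z2c[b] = z1c[b]; z1c[b] = z;
        Zp[off + b] = z; Ap[off + b] = A; Vp_[off + b] = vnew;
        if (record_grad) {
          VPp[off + b] = vp;
          double pd = 1.0 - std::fabs(vn);
          PDp[off + b] = (gated || pd < 0.0) ? 0.0 : gamma * pd;
          Sp[off + b] = snew;
        }
        if (!std::isfinite(vnew)) finite_ok = false;
      }
    }
    mat yslice = s * WoutT;
    yslice.each_row() += bout.t();
    Y.slice(t) = yslice;
  }

  if (!finite_ok)
    Rcpp::stop("non-finite membrane potential during simulation");

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("z") = Z, Rcpp::Named("A") = A_rec, Rcpp::Named("v") = Vc,
      Rcpp::Named("y") = Y);
  if (record_grad) {
    out["vp"] = VP; out["pd"] = PD; out["s"] = S;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List snn_backward_cpp(const arma::cube& x,    // B x n_in x T
                            const arma::cube& Z,    // spikes
                            const arma::cube& VP,   // pre-reset potential
                            const arma::cube& A,    // thresholds
                            const arma::cube& PD,   // pseudo-derivatives
                            const arma::cube& S,    // readout traces
                            const arma::cube& gy,   // dL/dy, B x n_out x T
                            const arma::vec& gz_const,  // n_rec constant dL/dz
                            const arma::cube& gz_extra, // B x n x T or empty
                            const arma::mat& Win,
                            const arma::mat& Wrec,
                            const arma::mat& Wout,
                            const arma::vec& alpha,
                            const arma::vec& rho,
                            const arma::vec& beta,
                            double v_th,
                            double kappa) {
  const uword B = x.n_rows, T = x.n_slices, n = Wrec.n_rows,
              n_in = Win.n_cols, n_out = Wout.n_rows;
  const double A_floor = 0.01 * v_th;
  const bool has_extra = gz_extra.n_elem > 0;

  mat gWin(n, n_in, fill::zeros), gWrec(n, n, fill::zeros),
      gWout(n_out, n, fill::zeros);
  vec gbout(n_out, fill::zeros);

  mat ls(B, n, fill::zeros), la(B, n, fill::zeros),
      lvp(B, n, fill::zeros), lvp2(B, n, fill::zeros);
  mat lz(B, n), rec_term(B, n), m(B, n);

  for (sword t = T - 1; t >= 0; --t) {
    const mat gy_t(const_cast<double*>(gy.slice_memptr(t)), B, n_out, false,
                   true);
    // readout-trace adjoint: ls(t) = gy(t) Wout + kappa ls(t+1)
    ls *= kappa;
    ls += gy_t * Wout;
    // recurrent adjoint arriving from v(t+2): ((1-alpha) o lvp(t+2)) Wrec
    for (uword j = 0; j < n; ++j) {
      const double oa = 1.0 - alpha(j);
      double* mc = m.colptr(j);
      const double* l2 = lvp2.colptr(j);
      for (uword b = 0; b < B; ++b) mc[b] = oa * l2[b];
    }
    rec_term = m * Wrec;

    const double* PDp = PD.slice_memptr(t);
    const double* Ap = A.slice_memptr(t);
    const double* VPp = VP.slice_memptr(t);
    const double* gze = has_extra ? gz_extra.slice_memptr(t) : nullptr;

    for (uword j = 0; j < n; ++j) {
      const double al = alpha(j), rh = rho(j), be = beta(j),
                   gzc = gz_const(j);
      double* lzc = lz.colptr(j);
      double* lac = la.colptr(j);
      double* lvpc = lvp.colptr(j);
      const double* lsc = ls.colptr(j);
      const double* rtc = rec_term.colptr(j);
      const uword off = j * B;
      for (uword b = 0; b < B; ++b) {
        const uword k = off + b;
        double lv_t = al * lvpc[b];            // lvp here still holds lvp(t+1)
        double lzv = lsc[b] - v_th * lv_t +
                     (1.0 - rh) * lac[b] + rtc[b] + gzc;
        if (gze) lzv += gze[k];
        double pd = PDp[k], At = Ap[k];
        double lvp_t = lv_t + lzv * pd / At;
        double la_t = rh * lac[b];
        if (At > A_floor)
          la_t -= lzv * pd * VPp[k] / (At * At) * be;
        lzc[b] = lzv; lac[b] = la_t;
        // shift: lvp2 gets old lvp(t+1), lvp gets lvp(t)
        lvp2.at(b, j) = lvpc[b];
        lvpc[b] = lvp_t;
      }
    }

    gWout += gy_t.t() * mat(const_cast<double*>(S.slice_memptr(t)), B, n,
                            false, true);
    gbout += sum(gy_t, 0).t();
    if (t >= 2) {
      for (uword j = 0; j < n; ++j) {
        const double oa = 1.0 - alpha(j);
        double* mc = m.colptr(j);
        const double* lvpc = lvp.colptr(j);
        for (uword b = 0; b < B; ++b) mc[b] = oa * lvpc[b];
      }
      gWin += m.t() * x.slice(t - 2);
      gWrec += m.t() * mat(const_cast<double*>(Z.slice_memptr(t - 2)), B, n,
                           false, true);
    }
  }

  return Rcpp::List::create(Rcpp::Named("Win") = gWin,
                            Rcpp::Named("Wrec") = gWrec,
                            Rcpp::Named("Wout") = gWout,
                            Rcpp::Named("bout") = gbout);
}
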