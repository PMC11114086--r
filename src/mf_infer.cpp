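#include <Rcpp.h>
using namespace Rcpp;

// Mean-field (coordinate-ascent) inference for a two-level categorical HMM.
//
// Per trial the model has T epochs with hidden chains s1 (n1 states) and s2
// (n2 states), coupled within each epoch by a behaviour likelihood
// P(o1 | s1, s2), plus a person factor s3 (n3 states) that supplies the
// starting-state priors P(s1,0 | s3) and P(s2,0 | s3). The posterior is
// approximated by q(s3) * prod_t q(s1,t) q(s2,t); updates are sequential
// full-conditional (coordinate ascent) steps on the floored-log model, so the
// variational free energy is non-increasing across sweeps.
//
// All probability inputs are converted to logs floored at log(lfloor); that
// floored model defines the free energy that certifies convergence.

static inline void softmax_inplace(std::vector<double> &u, std::vector<double> &q) {
  const int n = u.size();
  double m = u[0];
  for (int i = 1; i < n; ++i) if (u[i] > m) m = u[i];
  double s = 0.0;
  for (int i = 0; i < n; ++i) { q[i] = std::exp(u[i] - m); s += q[i]; }
  for (int i = 0; i < n; ++i) q[i] /= s;
}

static inline double xlogx(double x) { return (x > 0.0) ? x * std::log(x) : 0.0; }

struct MFWork {
  int n1, n2, n3, T;
  // floored log model terms
  const std::vector<double> *lD, *lS, *lP, *lB1, *lB2; // lD: n3 x n1 (col-major by row index s3? we store row-major: lD[s*n1+i])
  const double *lL1; // n1 x n2 x T (i + n1*k + n1*n2*t)
  const double *lL2; // n2 x T
  std::vector<std::vector<double> > u1, q1, u2, q2;
  std::vector<double> u3, q3;

  void init() {
    u1.assign(T, std::vector<double>(n1, 0.0));
    q1.assign(T, std::vector<double>(n1, 1.0 / n1));
    u2.assign(T, std::vector<double>(n2, 0.0));
    q2.assign(T, std::vector<double>(n2, 1.0 / n2));
    u3.assign(n3, 0.0);
    q3.assign(n3, 1.0 / n3);
  }

  double free_energy() const {
    double elogp = 0.0, elogq = 0.0;
    const std::vector<double> &D = *lD, &S = *lS, &P = *lP, &B1 = *lB1, &B2 = *lB2;
    for (int s = 0; s < n3; ++s) {
      elogp += q3[s] * P[s];
      for (int i = 0; i < n1; ++i) elogp += q3[s] * q1[0][i] * D[s * n1 + i];
      for (int k = 0; k < n2; ++k) elogp += q3[s] * q2[0][k] * S[s * n2 + k];
      elogq += xlogx(q3[s]);
    }
    for (int t = 1; t < T; ++t) {
      for (int i = 0; i < n1; ++i)
        for (int j = 0; j < n1; ++j)
          elogp += q1[t][i] * q1[t - 1][j] * B1[i + n1 * j];
      for (int k = 0; k < n2; ++k)
        for (int j = 0; j < n2; ++j)
          elogp += q2[t][k] * q2[t - 1][j] * B2[k + n2 * j];
    }
    for (int t = 0; t < T; ++t) {
      const double *L = lL1 + (size_t)n1 * n2 * t;
      for (int k = 0; k < n2; ++k) {
        elogp += q2[t][k] * lL2[k + n2 * t];
        for (int i = 0; i < n1; ++i)
          elogp += q1[t][i] * q2[t][k] * L[i + n1 * k];
      }
      for (int i = 0; i < n1; ++i) elogq += xlogx(q1[t][i]);
      for (int k = 0; k < n2; ++k) elogq += xlogx(q2[t][k]);
    }
    return elogq - elogp;
  }

  // forward filtering pass used as initialization: epoch by epoch, update
  // q1 then q2 from prior/forward and observation messages only (no
  // backward messages), then q3. Avoids spurious penalties on boundary
  // states from floored log transition zeros under a uniform start.
  // init_mode 0 starts the person factor at its (learned) prior, anchoring
  // the pass in the currently dominant person hypothesis's basin;
  // init_mode 1 starts it uniform over the person states with
  // non-negligible prior mass (maximum entropy over live hypotheses),
  // letting the observations pick the best-fitting one regardless of their
  // relative prior weights. The lowest-free-energy fixed point across
  // starts is kept. Person states the model excludes a priori never enter
  // a start, so a model whose split states carry zero prior mass explores
  // exactly the same basins as the reduced Integrated-only model.
  void forward_init(int init_mode) {
    const std::vector<double> &D = *lD, &S = *lS, &P = *lP, &B1 = *lB1, &B2 = *lB2;
    const double dead = std::log(1e-12);
    if (init_mode == 0) {
      for (int s = 0; s < n3; ++s) u3[s] = P[s];
    } else {
      for (int s = 0; s < n3; ++s) u3[s] = (P[s] < dead) ? P[s] : 0.0;
    }
    softmax_inplace(u3, q3);
    for (int t = 0; t < T; ++t) {
      const double *L = lL1 + (size_t)n1 * n2 * t;
      for (int i = 0; i < n1; ++i) {
        double v = 0.0;
        if (t == 0) {
          for (int s = 0; s < n3; ++s) v += q3[s] * D[s * n1 + i];
        } else {
          for (int j = 0; j < n1; ++j) v += q1[t - 1][j] * B1[i + n1 * j];
        }
        for (int k = 0; k < n2; ++k) v += q2[t][k] * L[i + n1 * k];
        u1[t][i] = v;
      }
      softmax_inplace(u1[t], q1[t]);
      for (int k = 0; k < n2; ++k) {
        double v = lL2[k + n2 * t];
        if (t == 0) {
          for (int s = 0; s < n3; ++s) v += q3[s] * S[s * n2 + k];
        } else {
          for (int j = 0; j < n2; ++j) v += q2[t - 1][j] * B2[k + n2 * j];
        }
        for (int i = 0; i < n1; ++i) v += q1[t][i] * L[i + n1 * k];
        u2[t][k] = v;
      }
      softmax_inplace(u2[t], q2[t]);
    }
    for (int s = 0; s < n3; ++s) {
      double v = P[s];
      for (int i = 0; i < n1; ++i) v += q1[0][i] * D[s * n1 + i];
      for (int k = 0; k < n2; ++k) v += q2[0][k] * S[s * n2 + k];
      u3[s] = v;
    }
    softmax_inplace(u3, q3);
  }

  void sweep(double damp) {
    const std::vector<double> &D = *lD, &S = *lS, &P = *lP, &B1 = *lB1, &B2 = *lB2;
    std::vector<double> prop;
    // internal chain
    prop.assign(n1, 0.0);
    for (int t = 0; t < T; ++t) {
      for (int i = 0; i < n1; ++i) {
        double v = 0.0;
        if (t == 0) {
          for (int s = 0; s < n3; ++s) v += q3[s] * D[s * n1 + i];
        } else {
          for (int j = 0; j < n1; ++j) v += q1[t - 1][j] * B1[i + n1 * j];
        }
        if (t < T - 1)
          for (int j = 0; j < n1; ++j) v += q1[t + 1][j] * B1[j + n1 * i];
        const double *L = lL1 + (size_t)n1 * n2 * t;
        for (int k = 0; k < n2; ++k) v += q2[t][k] * L[i + n1 * k];
        prop[i] = v;
      }
      for (int i = 0; i < n1; ++i) u1[t][i] = (1.0 - damp) * u1[t][i] + damp * prop[i];
      softmax_inplace(u1[t], q1[t]);
    }
    // external chain
    prop.assign(n2, 0.0);
    for (int t = 0; t < T; ++t) {
      for (int k = 0; k < n2; ++k) {
        double v = lL2[k + n2 * t];
        if (t == 0) {
          for (int s = 0; s < n3; ++s) v += q3[s] * S[s * n2 + k];
        } else {
          for (int j = 0; j < n2; ++j) v += q2[t - 1][j] * B2[k + n2 * j];
        }
        if (t < T - 1)
          for (int j = 0; j < n2; ++j) v += q2[t + 1][j] * B2[j + n2 * k];
        const double *L = lL1 + (size_t)n1 * n2 * t;
        for (int i = 0; i < n1; ++i) v += q1[t][i] * L[i + n1 * k];
        prop[k] = v;
      }
      for (int k = 0; k < n2; ++k) u2[t][k] = (1.0 - damp) * u2[t][k] + damp * prop[k];
      softmax_inplace(u2[t], q2[t]);
    }
    // person factor
    std::vector<double> p3(n3, 0.0);
    for (int s = 0; s < n3; ++s) {
      double v = P[s];
      for (int i = 0; i < n1; ++i) v += q1[0][i] * D[s * n1 + i];
      for (int k = 0; k < n2; ++k) v += q2[0][k] * S[s * n2 + k];
      p3[s] = v;
    }
    for (int s = 0; s < n3; ++s) u3[s] = (1.0 - damp) * u3[s] + damp * p3[s];
    softmax_inplace(u3, q3);
  }

  double run(int init_mode, double tol, int max_iter, double damp,
             int &iters, bool &converged, std::vector<double> *trace) {
    init();
    forward_init(init_mode);
    double Fp = R_PosInf, F = R_PosInf;
    int it = 0;
    converged = false;
    for (it = 0; it < max_iter; ++it) {
      sweep(damp);
      F = free_energy();
      if (trace) trace->push_back(F);
      if (std::fabs(Fp - F) < tol) { converged = true; ++it; break; }
      Fp = F;
    }
    iters = it;
    return F;
  }

  // run the fixed point from the prior-anchored and maximum-entropy starts
  // and keep the solution with the lowest free energy
  double run_multistart(double tol, int max_iter, double damp,
                        int &iters, bool &converged,
                        std::vector<double> *trace) {
    double bestF = R_PosInf;
    std::vector<std::vector<double> > b1, b2;
    std::vector<double> b3, btrace;
    int bit = 0;
    bool bconv = false;
    for (int mode = 0; mode < 2; ++mode) {
      int it;
      bool conv;
      std::vector<double> tr;
      double F = run(mode, tol, max_iter, damp, it, conv,
                     trace ? &tr : (std::vector<double> *)0);
      if (F < bestF) {
        bestF = F;
        b1 = q1; b2 = q2; b3 = q3;
        bit = it; bconv = conv;
        if (trace) btrace = tr;
      }
    }
    q1 = b1; q2 = b2; q3 = b3;
    iters = bit; converged = bconv;
    if (trace) *trace = btrace;
    return bestF;
  }
};

static void floored_log_rows(const NumericMatrix &counts, std::vector<double> &out,
                             double lfloor) {
  // normalize each row of a concentration matrix and take floored logs;
  // out is row-major: out[r * ncol + c]
  const int nr = counts.nrow(), nc = counts.ncol();
  out.assign((size_t)nr * nc, 0.0);
  const double lf = std::log(lfloor);
  for (int r = 0; r < nr; ++r) {
    double s = 0.0;
    for (int c = 0; c < nc; ++c) s += counts(r, c);
    for (int c = 0; c < nc; ++c) {
      double p = (s > 0.0) ? counts(r, c) / s : 1.0 / nc;
      out[(size_t)r * nc + c] = (p < lfloor) ? lf : std::log(p);
    }
  }
}

static void floored_log_vec(const NumericVector &x, std::vector<double> &out,
                            double lfloor, bool normalize) {
  const int n = x.size();
  out.assign(n, 0.0);
  const double lf = std::log(lfloor);
  double s = 0.0;
  if (normalize) { for (int i = 0; i < n; ++i) s += x[i]; }
  for (int i = 0; i < n; ++i) {
    double p = normalize ? ((s > 0.0) ? x[i] / s : 1.0 / n) : x[i];
    out[i] = (p < lfloor) ? lf : std::log(p);
  }
}

static void floored_log_mat(const NumericMatrix &m, std::vector<double> &out,
                            double lfloor) {
  // column-stochastic matrix -> column-major floored log, out[i + nr*j]
  const int nr = m.nrow(), nc = m.ncol();
  out.assign((size_t)nr * nc, 0.0);
  const double lf = std::log(lfloor);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out[i + (size_t)nr * j] = (m(i, j) < lfloor) ? lf : std::log(m(i, j));
}

// [[Rcpp::export]]
List mf_run_sequence_cpp(NumericMatrix dispC, NumericMatrix sitC,
                         NumericVector personC, NumericMatrix B1,
                         NumericMatrix B2, NumericVector lL1,
                         NumericVector lL2, int epochs_per_trial,
                         double eta, bool learn, bool rigid_split,
                         int integrated_index,
                         double tol, int max_iter, double damp, double lfloor,
                         bool predict, NumericVector A1flat, int n_o1,
                         bool keep_trace) {
  const int n1 = dispC.ncol(), n2 = sitC.ncol(), n3 = dispC.nrow();
  const int T = epochs_per_trial;
  const int E = lL2.size() / n2;
  const int n_trials = E / T;
  if (n_trials * T != E) stop("epoch count not a multiple of epochs_per_trial");
  if ((int)lL1.size() != n1 * n2 * E) stop("lL1 has wrong length");

  // working copies of the concentration parameters
  NumericMatrix dC = clone(dispC), sC = clone(sitC);
  NumericVector pC = clone(personC);

  std::vector<double> lB1, lB2;
  floored_log_mat(B1, lB1, lfloor);
  floored_log_mat(B2, lB2, lfloor);

  NumericMatrix q1_out(n1, E), q2_out(n2, E), q3_out(n3, n_trials);
  NumericVector F_out(n_trials);
  IntegerVector iters(n_trials);
  LogicalVector conv(n_trials);
  NumericMatrix pred_out(predict ? n_o1 : 1, predict ? E : 1);
  NumericMatrix pred_internal(predict ? n1 : 1, predict ? E : 1);
  List traces(keep_trace ? n_trials : 0);
  // trajectory of person concentrations (before trial 1, after each trial)
  NumericMatrix person_trace(n3, n_trials + 1);
  for (int s = 0; s < n3; ++s) person_trace(s, 0) = pC[s];

  MFWork w;
  w.n1 = n1; w.n2 = n2; w.n3 = n3; w.T = T;
  w.lB1 = &lB1; w.lB2 = &lB2;

  std::vector<double> lD, lS, lP;
  std::vector<double> zerosL1((size_t)n1 * n2 * T, 0.0), zerosL2((size_t)n2 * T, 0.0);
  std::vector<double> maskedL1, maskedL2;

  for (int tr = 0; tr < n_trials; ++tr) {
    floored_log_rows(dC, lD, lfloor);
    floored_log_rows(sC, lS, lfloor);
    floored_log_vec(pC, lP, lfloor, true);
    w.lD = &lD; w.lS = &lS; w.lP = &lP;

    const double *L1_trial = &lL1[(size_t)n1 * n2 * T * tr];
    const double *L2_trial = &lL2[(size_t)n2 * T * tr];

    if (predict) {
      // prediction for epoch t: infer with observations up to epoch t-1 plus
      // the current epoch's cue, then mix the behaviour likelihood
      for (int t = 0; t < T; ++t) {
        maskedL1.assign(L1_trial, L1_trial + (size_t)n1 * n2 * T);
        maskedL2.assign(L2_trial, L2_trial + (size_t)n2 * T);
        for (int tt = t; tt < T; ++tt)
          for (size_t z = 0; z < (size_t)n1 * n2; ++z)
            maskedL1[(size_t)n1 * n2 * tt + z] = 0.0;
        for (int tt = t + 1; tt < T; ++tt)
          for (int k = 0; k < n2; ++k) maskedL2[(size_t)n2 * tt + k] = 0.0;
        w.lL1 = maskedL1.data(); w.lL2 = maskedL2.data();
        int pit;
        bool pconv;
        w.run_multistart(tol, max_iter, damp, pit, pconv,
                         (std::vector<double> *)0);
        for (int o = 0; o < n_o1; ++o) {
          double v = 0.0;
          for (int k = 0; k < n2; ++k)
            for (int i = 0; i < n1; ++i)
              v += A1flat[o + (size_t)n_o1 * i + (size_t)n_o1 * n1 * k] *
                   w.q1[t][i] * w.q2[t][k];
          pred_out(o, T * tr + t) = v;
        }
        for (int i = 0; i < n1; ++i)
          pred_internal(i, T * tr + t) = w.q1[t][i];
      }
    }

    // full-trial inference
    w.lL1 = L1_trial; w.lL2 = L2_trial;
    int it = 0;
    bool converged = false;
    std::vector<double> trace;
    double F = w.run_multistart(tol, max_iter, damp, it, converged,
                                keep_trace ? &trace : (std::vector<double> *)0);
    F_out[tr] = F;
    iters[tr] = it;
    conv[tr] = converged;
    if (keep_trace) traces[tr] = wrap(trace);
    for (int t = 0; t < T; ++t) {
      for (int i = 0; i < n1; ++i) q1_out(i, T * tr + t) = w.q1[t][i];
      for (int k = 0; k < n2; ++k) q2_out(k, T * tr + t) = w.q2[t][k];
    }
    for (int s = 0; s < n3; ++s) q3_out(s, tr) = w.q3[s];

    if (learn) {
      // Dirichlet count accumulation from the trial-initial posteriors
      for (int s = 0; s < n3; ++s) {
        pC[s] += eta * w.q3[s];
        bool upd = (s == integrated_index) || !rigid_split;
        if (upd)
          for (int i = 0; i < n1; ++i) dC(s, i) += eta * w.q3[s] * w.q1[0][i];
        for (int k = 0; k < n2; ++k) sC(s, k) += eta * w.q3[s] * w.q2[0][k];
      }
    }
    for (int s = 0; s < n3; ++s) person_trace(s, tr + 1) = pC[s];
  }

  List out = List::create(
      _["q_internal"] = q1_out, _["q_external"] = q2_out,
      _["q_person"] = q3_out, _["free_energy"] = F_out,
      _["n_iterations"] = iters, _["converged"] = conv,
      _["d_disp"] = dC, _["d_sit"] = sC, _["d_person"] = pC,
      _["person_trace"] = person_trace);
  if (predict) {
    out["predictions"] = pred_out;
    out["predictive_internal"] = pred_internal;
  }
  if (keep_trace) out["free_energy_trace"] = traces;
  return out;
}
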