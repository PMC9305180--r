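// Continuous-wave Bloch-McConnell propagation for 1-3 proton pools
// (water "a", exchangeable solute "b", semisolid "c"), with exact
// forward-mode sensitivities of every acquired signal with respect to the
// acquisition-schedule parameters.
//
// Pool parameter vector layout (length 13, fixed order):
//   [0] R1a  [1] R2a  [2] M0
//   [3] fb   [4] kb   [5] R1b  [6] R2b  [7] dwb (ppm)
//   [8] fc   [9] kc  [10] R1c [11] R2c [12] dwc (ppm)
// State vector: (Mx, My, Mz) per pool, water first; length 3*npools.
// Schedule matrix columns: omega1 (uT), tsat (s), wrf (ppm), fa (deg), trec (s).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double GAMMA_2PI = 42.577; // MHz/T == Hz/uT for protons

struct PoolPars {
  int np;                 // number of pools (1..3)
  double M0;
  vec R1, R2, f, k, dw;   // per pool; f[0]=1, k[0]=0, dw[0]=0
  vec Meq;                // equilibrium Mz per pool
};

static PoolPars unpack_pools(const vec &p, int npools) {
  if (npools < 1 || npools > 3) Rcpp::stop("npools must be 1, 2 or 3");
  PoolPars pp;
  pp.np = npools;
  pp.M0 = p(2);
  pp.R1.set_size(npools); pp.R2.set_size(npools);
  pp.f.set_size(npools);  pp.k.set_size(npools); pp.dw.set_size(npools);
  pp.R1(0) = p(0); pp.R2(0) = p(1); pp.f(0) = 1.0; pp.k(0) = 0.0; pp.dw(0) = 0.0;
  if (npools >= 2) {
    pp.f(1) = p(3); pp.k(1) = p(4); pp.R1(1) = p(5); pp.R2(1) = p(6); pp.dw(1) = p(7);
  }
  if (npools >= 3) {
    pp.f(2) = p(8); pp.k(2) = p(9); pp.R1(2) = p(10); pp.R2(2) = p(11); pp.dw(2) = p(12);
  }
  if (!pp.R1.is_finite() || !pp.R2.is_finite() || !pp.f.is_finite() ||
      !pp.k.is_finite() || !pp.dw.is_finite() || !std::isfinite(pp.M0))
    Rcpp::stop("non-finite pool parameter");
  pp.Meq = pp.f * pp.M0;
  return pp;
}

// Assemble generator A and constant vector c of dM/dt = A M + c.
static void bm_system(const PoolPars &pp, double omega1_uT, double wrf_ppm,
                      double b0, mat &A, vec &cv) {
  const int d = 3 * pp.np;
  const double w1 = 2.0 * datum::pi * GAMMA_2PI * omega1_uT;   // rad/s
  const double per_ppm = 2.0 * datum::pi * GAMMA_2PI * b0;     // rad/s per ppm
  A.zeros(d, d);
  cv.zeros(d);
  // water exchange loss rate
  double kx = 0.0;
  for (int i = 1; i < pp.np; ++i) kx += pp.f(i) * pp.k(i);
  for (int i = 0; i < pp.np; ++i) {
    const int x = 3 * i, y = 3 * i + 1, z = 3 * i + 2;
    const double delta = (pp.dw(i) - wrf_ppm) * per_ppm;
    const double kloss = (i == 0) ? kx : pp.k(i);
    A(x, x) = -(pp.R2(i) + kloss); A(x, y) =  delta;
    A(y, x) = -delta;              A(y, y) = -(pp.R2(i) + kloss); A(y, z) =  w1;
    A(z, y) = -w1;                 A(z, z) = -(pp.R1(i) + kloss);
    cv(z) = pp.R1(i) * pp.Meq(i);
    if (i > 0) {
      // water gains from pool i at rate k_i, pool i gains from water at f_i k_i
      A(0, x) = pp.k(i); A(1, y) = pp.k(i); A(2, z) = pp.k(i);
      A(x, 0) = pp.f(i) * pp.k(i);
      A(y, 1) = pp.f(i) * pp.k(i);
      A(z, 2) = pp.f(i) * pp.k(i);
    }
  }
}

// dA/d(omega1 in uT) and dA/d(wrf in ppm): sparse, same shape as A.
static void bm_system_grad(const PoolPars &pp, double b0, int which, mat &dA) {
  const int d = 3 * pp.np;
  dA.zeros(d, d);
  const double g1 = 2.0 * datum::pi * GAMMA_2PI;
  const double per_ppm = g1 * b0;
  for (int i = 0; i < pp.np; ++i) {
    const int x = 3 * i, y = 3 * i + 1, z = 3 * i + 2;
    if (which == 0) {            // omega1
      dA(y, z) += g1; dA(z, y) -= g1;
    } else {                      // wrf
      dA(x, y) -= per_ppm; dA(y, x) += per_ppm;
    }
  }
}

// Augmented (d+1)x(d+1) generator [[A, c],[0, 0]] so that the affine ODE
// propagates as a single matrix exponential.
static mat augment(const mat &A, const vec &cv) {
  const int d = A.n_rows;
  mat B(d + 1, d + 1, fill::zeros);
  B.submat(0, 0, d - 1, d - 1) = A;
  B.submat(0, d, d - 1, d) = cv;
  return B;
}

// Frechet derivative L(tB, t dB) of the matrix exponential via the
// block-triangular identity expm([[X, E],[0, X]]) = [[e^X, L],[0, e^X]].
static mat expm_frechet(const mat &B, const mat &dB, double t, mat *Pout) {
  const int n = B.n_rows;
  mat M(2 * n, 2 * n, fill::zeros);
  M.submat(0, 0, n - 1, n - 1) = B * t;
  M.submat(0, n, n - 1, 2 * n - 1) = dB * t;
  M.submat(n, n, 2 * n - 1, 2 * n - 1) = B * t;
  mat F = expmat(M);
  if (Pout) *Pout = F.submat(0, 0, n - 1, n - 1);
  return F.submat(0, n, n - 1, 2 * n - 1);
}

// [[Rcpp::export]]
Rcpp::List bm_matrix_cpp(const arma::vec &pool, int npools, double omega1_uT,
                         double wrf_ppm, double b0) {
  PoolPars pp = unpack_pools(pool, npools);
  mat A; vec cv;
  bm_system(pp, omega1_uT, wrf_ppm, b0, A, cv);
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("c") = cv);
}

// [[Rcpp::export]]
arma::vec sat_propagate_cpp(const arma::vec &m, const arma::vec &pool, int npools,
                            double omega1_uT, double tsat, double wrf_ppm, double b0) {
  PoolPars pp = unpack_pools(pool, npools);
  const int d = 3 * pp.np;
  if ((int)m.n_elem != d) Rcpp::stop("state length must be 3*npools");
  if (tsat == 0.0) return m;
  mat A; vec cv;
  bm_system(pp, omega1_uT, wrf_ppm, b0, A, cv);
  mat P = expmat(augment(A, cv) * tsat);
  vec maug(d + 1); maug.head(d) = m; maug(d) = 1.0;
  vec out = P * maug;
  vec res = out.head(d);
  if (!res.is_finite()) Rcpp::stop("non-finite magnetization after saturation");
  return res;
}

// [[Rcpp::export]]
Rcpp::List readout_relax_cpp(const arma::vec &m, const arma::vec &pool, int npools,
                             double fa_deg, double trec) {
  PoolPars pp = unpack_pools(pool, npools);
  const int d = 3 * pp.np;
  if ((int)m.n_elem != d) Rcpp::stop("state length must be 3*npools");
  const double fa = fa_deg * datum::pi / 180.0;
  vec out(d, fill::zeros);                       // spoiling zeroes transverse
  double sig = m(2) * std::sin(fa);
  for (int i = 0; i < pp.np; ++i) {
    const int z = 3 * i + 2;
    double mz = m(z) * std::cos(fa);
    out(z) = pp.Meq(i) + (mz - pp.Meq(i)) * std::exp(-pp.R1(i) * trec);
  }
  return Rcpp::List::create(Rcpp::Named("signal") = sig, Rcpp::Named("m") = out);
}

// Core single-trajectory simulation with optional jacobian.
// grad_cols: logical length 5 (omega1, tsat, wrf, fa, trec).
// Trainable parameters are ordered column-major: for each selected column,
// entries 1..N. Returns signals (N) and jacobian (N x K).
static void sim_one(const PoolPars &pp, const mat &sched, double b0,
                    const std::vector<int> &gcols, vec &signals, mat &jac,
                    const vec *m_start) {
  const int d = 3 * pp.np;
  const int N = sched.n_rows;
  const int nsel = gcols.size();
  const int K = nsel * N;
  signals.set_size(N);
  if (K > 0) jac.zeros(N, K);

  vec maug(d + 1, fill::zeros);
  if (m_start) maug.head(d) = *m_start;
  else for (int i = 0; i < pp.np; ++i) maug(3 * i + 2) = pp.Meq(i);
  maug(d) = 1.0;

  mat U;                      // (d+1) x K sensitivity columns (last row 0)
  if (K > 0) U.zeros(d + 1, K);

  mat A, dA, P, L; vec cv;
  const double deg = datum::pi / 180.0;

  for (int n = 0; n < N; ++n) {
    const double w1 = sched(n, 0), ts = sched(n, 1), wr = sched(n, 2);
    const double fa = sched(n, 3) * deg, tr = sched(n, 4);

    // --- saturation block ---
    bm_system(pp, w1, wr, b0, A, cv);
    mat B = augment(A, cv);
    vec maug_pre = maug;
    // Frechet derivatives of this block's propagator for omega1 / wrf
    std::vector<std::pair<int, mat>> Lterms;
    bool haveP = false;
    for (int s = 0; s < nsel; ++s) {
      const int col = gcols[s];
      if (col == 0 || col == 2) {
        bm_system_grad(pp, b0, col == 0 ? 0 : 1, dA);
        mat dB(d + 1, d + 1, fill::zeros);
        dB.submat(0, 0, d - 1, d - 1) = dA;
        L = expm_frechet(B, dB, ts, haveP ? nullptr : &P);
        haveP = true;
        Lterms.emplace_back(s * N + n, L);
      }
    }
    if (!haveP) P = expmat(B * ts);
    // propagate accumulated sensitivities, then add this step's own terms
    if (K > 0) U = P * U;
    for (auto &lt : Lterms) U.col(lt.first) += lt.second * maug_pre;
    for (int s = 0; s < nsel; ++s) {
      if (gcols[s] == 1)   // tsat: dP/dts = B P
        U.col(s * N + n) += (B * (P * maug_pre));
    }
    maug = P * maug_pre;

    // --- spoil, excite, readout, recover ---
    const double sfa = std::sin(fa), cfa = std::cos(fa);
    // zero transverse rows of state and sensitivities
    for (int i = 0; i < pp.np; ++i) {
      maug(3 * i) = 0.0; maug(3 * i + 1) = 0.0;
      if (K > 0) { U.row(3 * i).zeros(); U.row(3 * i + 1).zeros(); }
    }
    signals(n) = maug(2) * sfa;
    if (K > 0) {
      for (int kk = 0; kk < K; ++kk) jac(n, kk) = U(2, kk) * sfa;
      for (int s = 0; s < nsel; ++s) {
        if (gcols[s] == 3) jac(n, s * N + n) += maug(2) * cfa * deg;
      }
    }
    for (int i = 0; i < pp.np; ++i) {
      const int z = 3 * i + 2;
      const double E = std::exp(-pp.R1(i) * tr);
      const double mz_pre = maug(z);
      const double mz1 = mz_pre * cfa;
      maug(z) = pp.Meq(i) + (mz1 - pp.Meq(i)) * E;
      if (K > 0) {
        for (int kk = 0; kk < K; ++kk) U(z, kk) *= cfa * E;
        for (int s = 0; s < nsel; ++s) {
          const int kidx = s * N + n;
          if (gcols[s] == 3)       // flip angle (degrees)
            U(z, kidx) += -mz_pre * sfa * deg * E;
          else if (gcols[s] == 4)  // recovery time
            U(z, kidx) += (mz1 - pp.Meq(i)) * (-pp.R1(i)) * E;
        }
      }
    }
  }
  if (!signals.is_finite()) Rcpp::stop("non-finite signal trajectory");
}

static std::vector<int> sel_cols(const Rcpp::LogicalVector &grad_cols) {
  std::vector<int> g;
  if (grad_cols.size() != 5) Rcpp::stop("grad_cols must have length 5");
  for (int j = 0; j < 5; ++j) if (grad_cols[j]) g.push_back(j);
  return g;
}

// [[Rcpp::export]]
Rcpp::List sim_trajectory_cpp(const arma::vec &pool, int npools,
                              const arma::mat &sched, double b0,
                              Rcpp::LogicalVector grad_cols,
                              Rcpp::Nullable<Rcpp::NumericVector> m_start = R_NilValue) {
  PoolPars pp = unpack_pools(pool, npools);
  if (sched.n_cols != 5) Rcpp::stop("schedule must have 5 columns");
  std::vector<int> g = sel_cols(grad_cols);
  vec signals; mat jac;
  if (m_start.isNotNull()) {
    vec ms = Rcpp::as<vec>(m_start.get());
    sim_one(pp, sched, b0, g, signals, jac, &ms);
  } else {
    sim_one(pp, sched, b0, g, signals, jac, nullptr);
  }
  return Rcpp::List::create(Rcpp::Named("signals") = signals,
                            Rcpp::Named("jacobian") = jac);
}

// [[Rcpp::export]]
Rcpp::List sim_batch_cpp(const arma::mat &pools, int npools, const arma::mat &sched,
                         double b0, bool jacobian, Rcpp::LogicalVector grad_cols) {
  if (sched.n_cols != 5) Rcpp::stop("schedule must have 5 columns");
  if (pools.n_cols != 13) Rcpp::stop("pool matrix must have 13 columns");
  const int M = pools.n_rows, N = sched.n_rows;
  std::vector<int> g = jacobian ? sel_cols(grad_cols) : std::vector<int>();
  const int K = g.size() * N;
  mat S(M, N);
  cube J;
  if (K > 0) J.set_size(N, K, M);
  vec signals; mat jac;
  for (int m = 0; m < M; ++m) {
    PoolPars pp = unpack_pools(pools.row(m).t(), npools);
    sim_one(pp, sched, b0, g, signals, jac, nullptr);
    S.row(m) = signals.t();
    if (K > 0) J.slice(m) = jac;
  }
  if (K > 0)
    return Rcpp::List::create(Rcpp::Named("signals") = S, Rcpp::Named("jacobian") = J);
  return Rcpp::List::create(Rcpp::Named("signals") = S);
}
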