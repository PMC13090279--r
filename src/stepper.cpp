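#include <Rcpp.h>
using namespace Rcpp;

// Trapezoid integrals of the age density over the juvenile ([0, tau*]) and
// adult ([tau*, end]) segments; the shared node N1 takes half weight in each,
// so y1 + y2 equals the single trapezoid over the whole grid exactly.
static inline void pop_sizes(const std::vector<double>& U, int N1, double h,
                             double& y1, double& y2) {
  double s1 = 0.5 * U[0] + 0.5 * U[N1];
  for (int k = 1; k < N1; ++k) s1 += U[k];
  int NL = (int)U.size() - 1;
  double s2 = 0.5 * U[N1] + 0.5 * U[NL];
  for (int k = N1 + 1; k < NL; ++k) s2 += U[k];
  y1 = h * s1;
  y2 = h * s2;
}

struct StepCtx {
  int N1, NL;
  double h, r, a, s, b, k, g, zeta, muM, rho;
  bool saturated, kmre;
  double xhat, y1hat;
  const std::vector<double>* phiA;   // adult indicator at grid ages
  const std::vector<double>* phiB;   // juvenile indicator
  const std::vector<double>* muB;    // base death rate (or full mu in KMRE mode)
  const std::vector<double>* Bt;     // base birth rate (or full B in KMRE mode)
};

// One step of the scheme.  Order of operations: prey update, interior
// density shift with Euler decay, newborn node, then the population
// integrals.  With lagY the returned Y pair is the trapezoid of the
// PRE-update density (the printed scheme); otherwise of the new density.
// clampNeg floors the Euler decay factor (and the prey) at zero; when it is
// false a produced negative value sets *neg.
static void one_step(const StepCtx& c, double& X, std::vector<double>& U,
                     double& Y1, double& Y2, bool lagY, bool clampNeg,
                     bool* neg) {
  const int NL = c.NL;
  // prey (forward Euler; saturated variant bounds the juvenile gain).
  // In decoupled (KMRE) mode the rates ignore the prey and the prey is
  // held fixed.
  double Xn = X;
  if (!c.kmre) {
    double sy1 = c.saturated ? c.s * c.y1hat * std::tanh(Y1 / c.y1hat)
                             : c.s * Y1;
    Xn = X * (1.0 + c.h * (c.r - c.a * X + sy1 - c.b * Y2));
    if (Xn < 0) {
      if (clampNeg) Xn = 0.0; else *neg = true;
    }
  }
  // birth integral (trapezoid) evaluated at the pre-update prey size
  double dotA = 0, dotB = 0;
  {
    const std::vector<double>& pA = *c.phiA;
    const std::vector<double>& bt = *c.Bt;
    dotA = 0.5 * pA[0] * U[0] + 0.5 * pA[NL] * U[NL];
    dotB = 0.5 * bt[0] * U[0] + 0.5 * bt[NL] * U[NL];
    for (int k = 1; k < NL; ++k) {
      dotA += pA[k] * U[k];
      dotB += bt[k] * U[k];
    }
  }
  double newborn;
  if (c.kmre) {
    newborn = c.h * dotB;  // rates independent of the prey
  } else {
    double kx = c.saturated ? c.k * c.xhat * std::tanh(X / c.xhat)
                            : c.k * X;
    newborn = c.h * (kx * dotA + (1.0 - std::exp(-c.zeta * X)) * dotB);
  }
  // interior shift with decay; density advected past NL is discarded
  double hunger = c.kmre ? 0.0 : c.muM * std::exp(-c.rho * X);
  const std::vector<double>& pB = *c.phiB;
  const std::vector<double>& mb = *c.muB;
  double y1n, y2n;
  if (lagY) pop_sizes(U, c.N1, c.h, y1n, y2n);
  for (int k = NL; k >= 1; --k) {
    double mu = c.kmre ? mb[k - 1]
                       : c.g * X * pB[k - 1] + mb[k - 1] + hunger;
    double f = 1.0 - c.h * mu;
    if (f < 0) {
      if (clampNeg) f = 0.0; else *neg = true;
    }
    U[k] = U[k - 1] * f;
  }
  U[0] = newborn;
  if (!lagY) pop_sizes(U, c.N1, c.h, y1n, y2n);
  X = Xn;
  Y1 = y1n;
  Y2 = y2n;
}

static StepCtx make_ctx(List params, int N1, double h,
                        const std::vector<double>& phiA,
                        const std::vector<double>& phiB,
                        const std::vector<double>& muB,
                        const std::vector<double>& Bt,
                        bool kmre, int NL) {
  StepCtx c;
  c.N1 = N1; c.NL = NL; c.h = h;
  c.r = as<double>(params["r"]); c.a = as<double>(params["a"]);
  c.s = as<double>(params["s"]); c.b = as<double>(params["b"]);
  c.k = as<double>(params["k"]); c.g = as<double>(params["g"]);
  c.zeta = as<double>(params["zeta"]); c.muM = as<double>(params["mu_M"]);
  c.rho = as<double>(params["rho"]);
  c.saturated = as<std::string>(params["variant"]) == "saturated";
  c.xhat = as<double>(params["x_hat"]); c.y1hat = as<double>(params["y1_hat"]);
  c.kmre = kmre;
  c.phiA = &phiA; c.phiB = &phiB; c.muB = &muB; c.Bt = &Bt;
  return c;
}

// [[Rcpp::export]]
List cpp_integrate(double X0, NumericVector U0, double h, int nsteps, int N1,
                   NumericVector phiA_, NumericVector phiB_,
                   NumericVector muB_, NumericVector Bt_,
                   List params, bool kmre,
                   double blowup, bool checkU, bool clampNeg, bool lagY,
                   int stride, IntegerVector snapshotSteps) {
  int NL = U0.size() - 1;
  std::vector<double> U(U0.begin(), U0.end());
  std::vector<double> phiA(phiA_.begin(), phiA_.end());
  std::vector<double> phiB(phiB_.begin(), phiB_.end());
  std::vector<double> muB(muB_.begin(), muB_.end());
  std::vector<double> Bt(Bt_.begin(), Bt_.end());
  StepCtx c = make_ctx(params, N1, h, phiA, phiB, muB, Bt, kmre, NL);

  double X = X0, Y1, Y2;
  pop_sizes(U, N1, h, Y1, Y2);

  std::vector<double> rt, rx, ry1, ry2;
  rt.reserve(nsteps / std::max(stride, 1) + 2);
  rt.push_back(0.0); rx.push_back(X); ry1.push_back(Y1); ry2.push_back(Y2);

  std::set<int> snaps(snapshotSteps.begin(), snapshotSteps.end());
  List snapList;
  std::vector<double> snapTimes;
  if (snaps.count(0)) {
    snapList.push_back(NumericVector(U.begin(), U.end()));
    snapTimes.push_back(0.0);
  }

  std::string status = "completed";
  int nDone = 0;
  for (int n = 0; n < nsteps; ++n) {
    bool neg = false;
    one_step(c, X, U, Y1, Y2, lagY, clampNeg, &neg);
    nDone = n + 1;
    if (neg) { status = "negative_density"; break; }
    bool blown = X > blowup || Y1 > blowup || Y2 > blowup;
    if (!blown && checkU)
      for (int k = 0; k <= NL; ++k)
        if (U[k] > blowup) { blown = true; break; }
    if (blown) {
      rt.push_back(nDone * h); rx.push_back(X);
      ry1.push_back(Y1); ry2.push_back(Y2);
      status = "blowup";
      break;
    }
    if (nDone % stride == 0 || nDone == nsteps) {
      rt.push_back(nDone * h); rx.push_back(X);
      ry1.push_back(Y1); ry2.push_back(Y2);
    }
    if (snaps.count(nDone)) {
      snapList.push_back(NumericVector(U.begin(), U.end()));
      snapTimes.push_back(nDone * h);
    }
  }

  return List::create(
    _["time"] = NumericVector(rt.begin(), rt.end()),
    _["x"] = NumericVector(rx.begin(), rx.end()),
    _["y1"] = NumericVector(ry1.begin(), ry1.end()),
    _["y2"] = NumericVector(ry2.begin(), ry2.end()),
    _["status"] = status,
    _["steps_done"] = nDone,
    _["X_final"] = X,
    _["U_final"] = NumericVector(U.begin(), U.end()),
    _["snapshots"] = snapList,
    _["snapshot_times"] = NumericVector(snapTimes.begin(), snapTimes.end()));
}

// First return of the trajectory started on the section X = Xstar to that
// section in the upward (dX > 0) direction.  The crossing state is linearly
// interpolated between the bracketing steps.
// [[Rcpp::export]]
List cpp_poincare(double Xstar, NumericVector U0, double h, int maxSteps,
                  int N1,
                  NumericVector phiA_, NumericVector phiB_,
                  NumericVector muB_, NumericVector Bt_,
                  List params, bool lagY) {
  int NL = U0.size() - 1;
  std::vector<double> U(U0.begin(), U0.end());
  std::vector<double> phiA(phiA_.begin(), phiA_.end());
  std::vector<double> phiB(phiB_.begin(), phiB_.end());
  std::vector<double> muB(muB_.begin(), muB_.end());
  std::vector<double> Bt(Bt_.begin(), Bt_.end());
  StepCtx c = make_ctx(params, N1, h, phiA, phiB, muB, Bt, false, NL);

  double X = Xstar, Y1, Y2;
  pop_sizes(U, N1, h, Y1, Y2);
  std::vector<double> Uprev(U);
  double Xprev = X;

  for (int n = 0; n < maxSteps; ++n) {
    Uprev = U; Xprev = X;
    bool neg = false;
    one_step(c, X, U, Y1, Y2, lagY, false, &neg);
    if (neg)
      return List::create(_["status"] = "negative_density");
    if (n >= 1 && Xprev < Xstar && X >= Xstar) {
      double th = (Xstar - Xprev) / (X - Xprev);
      NumericVector Uc(NL + 1);
      for (int k = 0; k <= NL; ++k)
        Uc[k] = Uprev[k] + th * (U[k] - Uprev[k]);
      return List::create(_["status"] = "ok",
                          _["U"] = Uc,
                          _["time"] = (n + th) * h);
    }
  }
  return List::create(_["status"] = "no_return");
}
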