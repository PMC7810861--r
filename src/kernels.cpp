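#include <Rcpp.h>
using namespace Rcpp;

// Compiled model layout shared by the RK4 and Gillespie kernels.
// A "compiled" model (built by compile_model() on the R side) is a list:
//   n      : number of nodes
//   alpha  : length-n transcription rate coefficients (conc / h)
//   delta  : length-n decay rate coefficients (1 / h)
//   num0   : length-n constant numerator part (beta_X plus any active
//            external activator contribution); ignored for eq4 nodes
//   den0   : length-n constant extra denominator part (active external
//            inhibitor contribution, e.g. beta_RESTi on RESTc)
//   eq4    : length-n integer flag; 1 -> reduced form 1/(1 + sum_inh)
//   esrc   : edge source node index (0-based)
//   etgt   : edge target node index (0-based)
//   esign  : +1 activation, -1 inhibition
//   ek, eh : per-edge dissociation constant and Hill exponent

struct CModel {
  int n;
  NumericVector alpha, delta, num0, den0, ek, eh;
  IntegerVector eq4, esrc, etgt, esign;
  int ne;
};

static CModel unpack(const List& m) {
  CModel cm;
  cm.n     = as<int>(m["n"]);
  cm.alpha = m["alpha"];
  cm.delta = m["delta"];
  cm.num0  = m["num0"];
  cm.den0  = m["den0"];
  cm.eq4   = m["eq4"];
  cm.esrc  = m["esrc"];
  cm.etgt  = m["etgt"];
  cm.esign = m["esign"];
  cm.ek    = m["ek"];
  cm.eh    = m["eh"];
  cm.ne    = cm.esrc.size();
  return cm;
}

// Shea-Ackers regulatory activity for every node at one state.
// `work` is caller-provided scratch of length >= 2n.
static void sa_all(const CModel& cm, const double* y, double* sa,
                   double* work) {
  double* sact = work;
  double* sinh_ = work + cm.n;
  for (int i = 0; i < cm.n; ++i) { sact[i] = 0.0; sinh_[i] = 0.0; }
  for (int e = 0; e < cm.ne; ++e) {
    double conc = y[cm.esrc[e]];
    double term = conc <= 0.0 ? 0.0 : std::pow(conc / cm.ek[e], cm.eh[e]);
    if (cm.esign[e] > 0) sact[cm.etgt[e]] += term; else sinh_[cm.etgt[e]] += term;
  }
  for (int i = 0; i < cm.n; ++i) {
    if (cm.eq4[i]) {
      sa[i] = 1.0 / (1.0 + sinh_[i] + cm.den0[i]);
    } else {
      double num = cm.num0[i] + sact[i];
      sa[i] = num / (1.0 + num + sinh_[i] + cm.den0[i]);
    }
  }
}

static void rhs(const CModel& cm, const double* y, double* dy,
                double* work) {
  double* sa = work + 2 * cm.n;
  sa_all(cm, y, sa, work);
  for (int i = 0; i < cm.n; ++i)
    dy[i] = cm.alpha[i] * sa[i] - cm.delta[i] * y[i];
}

// [[Rcpp::export(name = ".sa_all_cpp")]]
NumericVector sa_all_cpp(List model, NumericVector state) {
  CModel cm = unpack(model);
  NumericVector out(cm.n);
  std::vector<double> work(3 * cm.n);
  sa_all(cm, state.begin(), out.begin(), work.data());
  return out;
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(List model, NumericVector state) {
  CModel cm = unpack(model);
  NumericVector out(cm.n);
  std::vector<double> work(3 * cm.n);
  rhs(cm, state.begin(), out.begin(), work.data());
  return out;
}

// Classic fixed-step RK4; a final partial step is taken when the duration
// is not an integer multiple of the step.  Negative excursions are clamped
// to zero and counted.  The recorded grid runs t = 0 .. duration inclusive;
// `record_every` > 1 thins the recorded rows (the final state is always
// recorded).  Two quadratures are accumulated on the full-resolution grid
// regardless of thinning:
//   absint[i]  = trapezoid of |d y_i / dt|  (RHS evaluated at grid points)
//   d2int[i]   = trapezoid of |d2 y_i / dt2| (central differences,
//                endpoint values replicated from their neighbours)
// [[Rcpp::export(name = ".rk4_cpp")]]
List rk4_cpp(List model, NumericVector y0, double duration, double step,
             int record_every = 1) {
  CModel cm = unpack(model);
  const int n = cm.n;
  if (duration < 0) stop("duration must be >= 0");
  if (step <= 0) stop("step must be > 0");
  if (record_every < 1) stop("record_every must be >= 1");
  long nfull = (long)std::floor(duration / step + 1e-9);
  double rem = duration - nfull * step;
  if (rem < 1e-9) rem = 0.0;
  long nstep = nfull + (rem > 0 ? 1 : 0);

  // rows recorded: t=0, every record_every-th step, and the final state
  long nrow = 1;
  for (long s = 1; s <= nstep; ++s)
    if (s % record_every == 0 || s == nstep) ++nrow;

  NumericMatrix path(nrow, n);
  NumericVector times(nrow), absint(n), d2int(n);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n), work(3 * n);
  std::vector<double> dprev(n);              // RHS at previous grid point
  std::vector<double> yprev(n), yprev2(n);   // rolling states for d2
  std::vector<double> d2prev(n), d2first(n);
  long clamped = 0, nd2 = 0;

  for (int i = 0; i < n; ++i) path(0, i) = y[i];
  times[0] = 0.0;
  long row = 1;

  rhs(cm, y.data(), dprev.data(), work.data());
  for (int i = 0; i < n; ++i) yprev[i] = y[i];

  double t = 0.0;
  for (long s = 1; s <= nstep; ++s) {
    double h = (s <= nfull) ? step : rem;
    rhs(cm, y.data(), k1.data(), work.data());
    for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
    rhs(cm, tmp.data(), k2.data(), work.data());
    for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
    rhs(cm, tmp.data(), k3.data(), work.data());
    for (int i = 0; i < n; ++i) tmp[i] = y[i] + h * k3[i];
    rhs(cm, tmp.data(), k4.data(), work.data());
    for (int i = 0; i < n; ++i) yprev2[i] = yprev[i];
    for (int i = 0; i < n; ++i) yprev[i] = y[i];
    for (int i = 0; i < n; ++i) {
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (y[i] < 0.0) { y[i] = 0.0; ++clamped; }
      if (!std::isfinite(y[i]))
        stop("integration blew up at t = %f (node %d)", t + h, i + 1);
    }
    t += h;
    // |dy/dt| trapezoid: RHS at the new grid point vs the previous one
    rhs(cm, y.data(), tmp.data(), work.data());
    for (int i = 0; i < n; ++i) {
      absint[i] += 0.5 * h * (std::fabs(dprev[i]) + std::fabs(tmp[i]));
      dprev[i] = tmp[i];
    }
    // |d2y/dt2| by central differences at the interior point s-1
    if (s >= 2) {
      for (int i = 0; i < n; ++i) {
        double d2 = (y[i] - 2.0 * yprev[i] + yprev2[i]) / (step * step);
        d2 = std::fabs(d2);
        if (nd2 == 0) d2first[i] = d2;
        else d2int[i] += 0.5 * step * (d2prev[i] + d2);
        d2prev[i] = d2;
      }
      ++nd2;
    }
    if (s % record_every == 0 || s == nstep) {
      for (int i = 0; i < n; ++i) path(row, i) = y[i];
      times[row] = t;
      ++row;
    }
  }
  // endpoint replication: first and last interior d2 values each extend
  // one trapezoid panel to the boundary grid points
  if (nd2 >= 1) {
    for (int i = 0; i < n; ++i)
      d2int[i] += step * (d2first[i] + d2prev[i]);
  }
  return List::create(_["times"] = times, _["path"] = path,
                      _["clamped"] = clamped, _["absint"] = absint,
                      _["d2int"] = d2int);
}

// Gillespie direct method on the rescaled reaction system: per node X a
// production channel (jump +eta_X, propensity alpha_X * SA(X) / eta_X) and
// a decay channel (jump -eta_X, propensity delta_X * [X] / eta_X).
// Propensities are recomputed after every event.  Output is recorded on a
// uniform grid by last-value carry-forward.  Uses R's RNG (set.seed() on
// the R side makes runs reproducible).
// [[Rcpp::export(name = ".gillespie_cpp")]]
List gillespie_cpp(List model, NumericVector y0, double duration,
                   NumericVector eta, double out_step) {
  CModel cm = unpack(model);
  const int n = cm.n;
  if (duration <= 0) stop("duration must be > 0");
  if (out_step <= 0) stop("out_step must be > 0");
  long ngrid = (long)std::floor(duration / out_step + 1e-9) + 1;
  NumericMatrix path(ngrid, n);
  NumericVector times(ngrid);
  for (long g = 0; g < ngrid; ++g) times[g] = g * out_step;

  std::vector<double> y(n), sa(n), a(2 * n), work(3 * n);
  for (int i = 0; i < n; ++i) {
    // snap the initial state to a non-negative multiple of eta
    double m = std::max(0.0, std::round(y0[i] / eta[i]));
    y[i] = m * eta[i];
  }

  GetRNGstate();
  double t = 0.0;
  long g = 0;
  long nevents = 0;
  for (int i = 0; i < n; ++i) path(0, i) = y[i];
  g = 1;

  while (t < duration) {
    sa_all(cm, y.data(), sa.data(), work.data());
    double a0 = 0.0;
    for (int i = 0; i < n; ++i) {
      a[2 * i]     = cm.alpha[i] * sa[i] / eta[i];
      a[2 * i + 1] = cm.delta[i] * y[i] / eta[i];
      a0 += a[2 * i] + a[2 * i + 1];
    }
    double tnext;
    if (a0 <= 0.0) {
      tnext = duration;            // frozen state: let remaining time elapse
    } else {
      tnext = t + exp_rand() / a0;
    }
    // record grid points passed while waiting
    while (g < ngrid && times[g] <= tnext + 1e-12) {
      for (int i = 0; i < n; ++i) path(g, i) = y[i];
      ++g;
    }
    t = tnext;
    if (a0 <= 0.0 || t >= duration) break;
    double r = unif_rand() * a0, acc = 0.0;
    int ch = 2 * n - 1;
    for (int c = 0; c < 2 * n; ++c) {
      acc += a[c];
      if (r <= acc) { ch = c; break; }
    }
    int node = ch / 2;
    if (ch % 2 == 0) y[node] += eta[node];
    else             y[node] = std::max(0.0, y[node] - eta[node]);
    ++nevents;
    if (nevents % 4096 == 0) checkUserInterrupt();
  }
  while (g < ngrid) {
    for (int i = 0; i < n; ++i) path(g, i) = y[i];
    ++g;
  }
  PutRNGstate();
  return List::create(_["times"] = times, _["path"] = path,
                      _["nevents"] = nevents);
}
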