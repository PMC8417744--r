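// EMU cascade solver and Metropolis-Hastings flux sampler.
//
// The cascade structure is built once in R (see build_emu_system): per EMU
// size a small dense linear balance system whose coefficients are linear in
// the fluxes, with convolution nodes feeding condensation terms. Solving is
// the per-proposal hot path of the sampler, so the structure is parsed into
// plain C++ vectors once and reused across proposals.

#include <RcppArmadillo.h>
using namespace Rcpp;

struct Level {
  int n, size;
  std::vector<int> conv_out, conv_a, conv_b;
  std::vector<int> Ai, Aj, Ar;
  std::vector<double> Aw;
  std::vector<int> Bi, Br, Bslot;
  std::vector<double> Bw;
  std::vector<int> out_slots;
};

struct EmuSys {
  std::vector<Level> levels;
  std::vector<arma::vec> input_vals;
  std::vector<int> input_slots;
  int n_slots;
  std::vector<int> target_slots;
};

static std::vector<int> ivec(SEXP x) {
  IntegerVector v(x);
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> dvec(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}

static EmuSys parse_sys(const List& sys) {
  EmuSys out;
  List levels = sys["levels"];
  for (int li = 0; li < levels.size(); ++li) {
    List lev = levels[li];
    Level L;
    L.n = as<int>(lev["n"]);
    L.size = as<int>(lev["size"]);
    IntegerMatrix conv = lev["conv"];
    for (int c = 0; c < conv.nrow(); ++c) {
      L.conv_out.push_back(conv(c, 0));
      L.conv_a.push_back(conv(c, 1));
      L.conv_b.push_back(conv(c, 2));
    }
    L.Ai = ivec(lev["A_i"]); L.Aj = ivec(lev["A_j"]);
    L.Ar = ivec(lev["A_r"]); L.Aw = dvec(lev["A_w"]);
    L.Bi = ivec(lev["B_i"]); L.Br = ivec(lev["B_r"]);
    L.Bslot = ivec(lev["B_slot"]); L.Bw = dvec(lev["B_w"]);
    L.out_slots = ivec(lev["out_slots"]);
    out.levels.push_back(L);
  }
  List inputs = sys["inputs"];
  for (int i = 0; i < inputs.size(); ++i) {
    List in = inputs[i];
    out.input_slots.push_back(as<int>(in["slot"]));
    out.input_vals.push_back(as<arma::vec>(in["values"]));
  }
  out.n_slots = as<int>(sys["n_slots"]);
  IntegerVector tg = sys["targets"];
  for (int i = 0; i < tg.size(); ++i) out.target_slots.push_back(tg[i]);
  return out;
}

static void conv_into(const arma::vec& a, const arma::vec& b, arma::vec& out) {
  out.zeros(a.n_elem + b.n_elem - 1);
  for (arma::uword i = 0; i < a.n_elem; ++i)
    for (arma::uword j = 0; j < b.n_elem; ++j)
      out(i + j) += a(i) * b(j);
}

static bool solve_cascade(const EmuSys& es, const arma::vec& v,
                          std::vector<arma::vec>& slots) {
  slots.assign(es.n_slots, arma::vec());
  for (size_t k = 0; k < es.input_slots.size(); ++k)
    slots[es.input_slots[k] - 1] = es.input_vals[k];

  for (const Level& L : es.levels) {
    for (size_t c = 0; c < L.conv_out.size(); ++c)
      conv_into(slots[L.conv_a[c] - 1], slots[L.conv_b[c] - 1],
                slots[L.conv_out[c] - 1]);
    arma::mat A(L.n, L.n, arma::fill::zeros);
    for (size_t t = 0; t < L.Ai.size(); ++t)
      A(L.Ai[t] - 1, L.Aj[t] - 1) += v(L.Ar[t] - 1) * L.Aw[t];
    arma::mat R(L.n, L.size + 1, arma::fill::zeros);
    for (size_t t = 0; t < L.Bi.size(); ++t) {
      const arma::vec& src = slots[L.Bslot[t] - 1];
      double w = v(L.Br[t] - 1) * L.Bw[t];
      for (int m = 0; m <= L.size; ++m)
        R(L.Bi[t] - 1, m) -= w * src(m);
    }
    // Pools consumed only by zero-flux reactions have a ~zero diagonal; at
    // steady state they then also receive no inflow, so their MDV is
    // irrelevant downstream (every outgoing term is weighted by that zero
    // flux). Pin them to unlabeled to keep the system nonsingular.
    double vscale = arma::abs(v).max();
    for (int i = 0; i < L.n; ++i) {
      if (std::fabs(A(i, i)) < 1e-12 * std::max(1.0, vscale)) {
        A.row(i).zeros();
        A(i, i) = 1.0;
        R.row(i).zeros();
        R(i, 0) = 1.0;
      }
    }
    arma::mat X;
    if (!arma::solve(X, A, R, arma::solve_opts::no_approx)) return false;
    for (int i = 0; i < L.n; ++i)
      slots[L.out_slots[i] - 1] = X.row(i).t();
  }
  return true;
}

// [[Rcpp::export]]
List emu_simulate_cpp(List sys, NumericVector flux) {
  EmuSys es = parse_sys(sys);
  arma::vec v = as<arma::vec>(flux);
  std::vector<arma::vec> slots;
  if (!solve_cascade(es, v, slots))
    stop("singular EMU balance system (disconnected pool with zero throughput)");
  List out(es.target_slots.size());
  for (size_t i = 0; i < es.target_slots.size(); ++i)
    out[i] = NumericVector(slots[es.target_slots[i] - 1].begin(),
                           slots[es.target_slots[i] - 1].end());
  return out;
}

// Weighted residual sum of squares for one experiment.
static double sys_rss(const EmuSys& es, const arma::vec& v,
                      const std::vector<arma::vec>& meas,
                      const std::vector<arma::vec>& sds, bool& ok,
                      std::vector<arma::vec>& work) {
  if (!solve_cascade(es, v, work)) { ok = false; return 0.0; }
  double rss = 0.0;
  for (size_t i = 0; i < es.target_slots.size(); ++i) {
    const arma::vec& sim = work[es.target_slots[i] - 1];
    for (arma::uword m = 0; m < meas[i].n_elem; ++m) {
      double r = (sim(m) - meas[i](m)) / sds[i](m);
      rss += r * r;
    }
  }
  ok = true;
  return rss;
}

// [[Rcpp::export]]
List mh_run_cpp(List sys_list, List meas_list, NumericVector v0,
                NumericMatrix Nmat, NumericVector lb, NumericVector ub,
                NumericVector theta0, double sigma0, int steps, int burn_in,
                int thin, int adapt_every, double target_acc) {
  int n_exp = sys_list.size();
  std::vector<EmuSys> systems;
  std::vector<std::vector<arma::vec>> meas(n_exp), sds(n_exp);
  for (int e = 0; e < n_exp; ++e) {
    systems.push_back(parse_sys(sys_list[e]));
    List me = meas_list[e];
    List vals = me["values"], sd = me["sds"];
    for (int i = 0; i < vals.size(); ++i) {
      meas[e].push_back(as<arma::vec>(vals[i]));
      sds[e].push_back(as<arma::vec>(sd[i]));
    }
  }

  arma::vec base = as<arma::vec>(v0);
  arma::mat N = as<arma::mat>(Nmat);
  arma::vec lo = as<arma::vec>(lb), hi = as<arma::vec>(ub);
  double tol = 1e-7 * std::max(1.0, arma::abs(hi).max());
  arma::vec theta = as<arma::vec>(theta0);
  int k = theta.n_elem;
  double sigma = sigma0;
  std::vector<arma::vec> work;

  arma::vec v = base + N * theta;
  bool ok;
  double rss = 0.0;
  for (int e = 0; e < n_exp; ++e)
    rss += sys_rss(systems[e], v, meas[e], sds[e], ok, work);

  int n_keep = (steps - burn_in) / thin;
  arma::mat kept(n_keep, k);
  arma::vec kept_rss(n_keep);
  int stored = 0, accepted = 0, proposals = 0;
  int win_acc = 0, win_n = 0;

  RNGScope scope;
  for (int step = 1; step <= steps; ++step) {
    arma::vec prop = theta;
    for (int j = 0; j < k; ++j) prop(j) += sigma * R::norm_rand();
    arma::vec vp = base + N * prop;
    bool in_bounds = arma::all(vp >= lo - tol) && arma::all(vp <= hi + tol);
    ++proposals; ++win_n;
    if (in_bounds) {
      double rss_p = 0.0;
      bool solved = true;
      for (int e = 0; e < n_exp && solved; ++e)
        rss_p += sys_rss(systems[e], vp, meas[e], sds[e], solved, work);
      if (solved && R::unif_rand() < std::exp(-(rss_p - rss) / 2.0)) {
        theta = prop; v = vp; rss = rss_p;
        ++accepted; ++win_acc;
      }
    }
    if (step <= burn_in && adapt_every > 0 && step % adapt_every == 0) {
      double rate = win_n > 0 ? (double)win_acc / win_n : 0.0;
      sigma *= std::exp(rate - target_acc);
      win_acc = 0; win_n = 0;
    }
    if (step > burn_in && (step - burn_in) % thin == 0 && stored < n_keep) {
      kept.row(stored) = theta.t();
      kept_rss(stored) = rss;
      ++stored;
    }
  }
  return List::create(
    _["theta"] = wrap(kept), _["rss"] = wrap(kept_rss),
    _["acceptance"] = (double)accepted / proposals,
    _["sigma"] = sigma, _["retained"] = stored);
}
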