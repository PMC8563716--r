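// Rate-coded hippocampal autoencoder core: settling dynamics, k-winners-
// take-all inhibition, and two-phase (expectation/outcome) contrastive
// learning with a small Hebbian term.  Kept in C++ because a full
// ensemble run settles ~10^7 cycles.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Par {
  int n_dg, n_ca3, n_ca1;
  int k_dg, k_ca3, k_ca1, k_out;
  double gain, gain_ca1, gain_ec, dt;
  double lr_in_dg, lr_in_ca3, lr_dg_ca3, lr_ca3_ca1;
  double lr_in_ca1, lr_out_ca1, lr_ca1_out, lr_out_in;
  double hebb;
  double scale_ca3_ca1, scale_in_ca1, scale_out_ca1;
  int n_cycles, n_expect;
  bool test_category_free;  // category units of EC_in free (big-loop driven) at test
  double exp_in;            // expected active units in an EC pattern
};

static Par read_par(const List& par) {
  Par p;
  p.n_dg = par["n_dg"]; p.n_ca3 = par["n_ca3"]; p.n_ca1 = par["n_ca1"];
  p.k_dg = par["k_dg"]; p.k_ca3 = par["k_ca3"]; p.k_ca1 = par["k_ca1"];
  p.k_out = par["k_out"];
  p.gain = par["gain"]; p.gain_ca1 = par["gain_ca1"];
  p.gain_ec = par["gain_ec"]; p.dt = par["dt"];
  p.lr_in_dg = par["lr_in_dg"]; p.lr_in_ca3 = par["lr_in_ca3"];
  p.lr_dg_ca3 = par["lr_dg_ca3"]; p.lr_ca3_ca1 = par["lr_ca3_ca1"];
  p.lr_in_ca1 = par["lr_in_ca1"]; p.lr_out_ca1 = par["lr_out_ca1"];
  p.lr_ca1_out = par["lr_ca1_out"]; p.lr_out_in = par["lr_out_in"];
  p.hebb = par["hebb"];
  p.scale_ca3_ca1 = par["scale_ca3_ca1"]; p.scale_in_ca1 = par["scale_in_ca1"];
  p.scale_out_ca1 = par["scale_out_ca1"];
  p.n_cycles = par["n_cycles"]; p.n_expect = par["n_expect"];
  p.test_category_free = par["test_category_free"];
  p.exp_in = par["exp_in"];
  return p;
}

struct Weights {
  arma::mat in_dg, in_ca3, dg_ca3, ca3_ca1, in_ca1, out_ca1, ca1_out, out_in;
};

static Weights read_weights(const List& W) {
  Weights w;
  w.in_dg   = as<arma::mat>(W["in_dg"]);
  w.in_ca3  = as<arma::mat>(W["in_ca3"]);
  w.dg_ca3  = as<arma::mat>(W["dg_ca3"]);
  w.ca3_ca1 = as<arma::mat>(W["ca3_ca1"]);
  w.in_ca1  = as<arma::mat>(W["in_ca1"]);
  w.out_ca1 = as<arma::mat>(W["out_ca1"]);
  w.ca1_out = as<arma::mat>(W["ca1_out"]);
  w.out_in  = as<arma::mat>(W["out_in"]);
  return w;
}

static List weights_list(const Weights& w) {
  return List::create(
    _["in_dg"] = w.in_dg, _["in_ca3"] = w.in_ca3, _["dg_ca3"] = w.dg_ca3,
    _["ca3_ca1"] = w.ca3_ca1, _["in_ca1"] = w.in_ca1,
    _["out_ca1"] = w.out_ca1, _["ca1_out"] = w.ca1_out,
    _["out_in"] = w.out_in);
}

struct Acts {
  arma::vec in, dg, ca3, ca1, out;
  Acts(const Par& p)
    : in(10, arma::fill::zeros), dg(p.n_dg, arma::fill::zeros),
      ca3(p.n_ca3, arma::fill::zeros), ca1(p.n_ca1, arma::fill::zeros),
      out(10, arma::fill::zeros) {}
};

// k-WTA: inhibition threshold midway between the k-th and (k+1)-th largest
// net input; units with non-positive drive stay silent.
static void kwta_step(arma::vec& a, const arma::vec& net, int k,
                      double gain, double dt) {
  int n = net.n_elem;
  arma::vec s = arma::sort(net, "descend");
  double thr = 0.5 * (s[k - 1] + s[k]);
  for (int i = 0; i < n; ++i) {
    double target = net[i] <= 0.0 ? 0.0
                    : 1.0 / (1.0 + std::exp(-gain * (net[i] - thr)));
    a[i] += dt * (target - a[i]);
  }
}

static void logistic_step(arma::vec& a, const arma::vec& net, double bias,
                          double gain, double dt, const arma::uvec& free_idx) {
  for (arma::uword j = 0; j < free_idx.n_elem; ++j) {
    arma::uword i = free_idx[j];
    double target = net[i] <= 0.0 ? 0.0
                    : 1.0 / (1.0 + std::exp(-gain * (net[i] - bias)));
    a[i] += dt * (target - a[i]);
  }
}

// One Gauss-Seidel settling cycle.  in_clamp / out_clamp are 0/1 masks;
// clamped units are pinned to the pattern values.
static void cycle(Acts& a, const Weights& w, const Par& p,
                  const arma::vec& x_in, const arma::uvec& in_free,
                  const arma::vec& x_out, bool out_clamped) {
  // EC_in: clamped units pinned, free units driven by big-loop recurrence
  for (int i = 0; i < 10; ++i) a.in[i] = x_in[i];
  if (in_free.n_elem > 0) {
    arma::vec net_in = w.out_in.t() * a.out;  // identity-like, unnormalized
    // restore free-unit values (pinning above overwrote them)
    for (arma::uword j = 0; j < in_free.n_elem; ++j) a.in[in_free[j]] = x_in[in_free[j]];
    logistic_step(a.in, net_in, 0.5, p.gain_ec, p.dt, in_free);
  }
  arma::vec net_dg = (w.in_dg.t() * a.in) / p.exp_in;
  kwta_step(a.dg, net_dg, p.k_dg, p.gain, p.dt);
  arma::vec net_ca3 = (w.in_ca3.t() * a.in) / p.exp_in
                    + (w.dg_ca3.t() * a.dg) / p.k_dg;
  kwta_step(a.ca3, net_ca3, p.k_ca3, p.gain, p.dt);
  arma::vec net_ca1 = p.scale_ca3_ca1 * (w.ca3_ca1.t() * a.ca3) / p.k_ca3
                    + p.scale_in_ca1 * (w.in_ca1.t() * a.in) / p.exp_in
                    + p.scale_out_ca1 * (w.out_ca1.t() * a.out) / p.k_out;
  kwta_step(a.ca1, net_ca1, p.k_ca1, p.gain_ca1, p.dt);
  if (out_clamped) {
    a.out = x_out;
  } else {
    arma::vec net_out = (w.ca1_out.t() * a.ca1) / p.k_ca1;
    kwta_step(a.out, net_out, p.k_out, p.gain_ec, p.dt);
  }
}

static void check_finite(const Acts& a) {
  if (!a.in.is_finite() || !a.dg.is_finite() || !a.ca3.is_finite() ||
      !a.ca1.is_finite() || !a.out.is_finite())
    stop("dynamics divergence: non-finite activation");
}

static void settle(Acts& a, const Weights& w, const Par& p,
                   const arma::vec& x_in, const arma::uvec& in_free,
                   const arma::vec& x_out, bool out_clamped, int n_cycles) {
  // free EC_in units keep their current value as starting point
  arma::vec x_in_eff = x_in;
  for (arma::uword j = 0; j < in_free.n_elem; ++j) x_in_eff[in_free[j]] = a.in[in_free[j]];
  for (int c = 0; c < n_cycles; ++c) {
    // re-read free-unit state each cycle so big-loop dynamics propagate
    for (arma::uword j = 0; j < in_free.n_elem; ++j) x_in_eff[in_free[j]] = a.in[in_free[j]];
    cycle(a, w, p, x_in_eff, in_free, x_out, out_clamped);
  }
  check_finite(a);
}

// soft-bounded contrastive update + CPCA-style Hebbian term, clipped to [0,1]
static void update_w(arma::mat& W, const arma::vec& src_m, const arma::vec& tgt_m,
                     const arma::vec& src_p, const arma::vec& tgt_p,
                     double lr, double hebb) {
  if (lr <= 0.0) return;
  arma::mat chl = src_p * tgt_p.t() - src_m * tgt_m.t();
  W += lr * chl;
  if (hebb > 0.0) {
    // w_ij moves toward presynaptic activity where the postsynaptic unit is on
    W += lr * hebb * (src_p * arma::ones<arma::rowvec>(W.n_cols) - W)
               % (arma::ones<arma::vec>(W.n_rows) * tgt_p.t());
  }
  W.elem(arma::find(W < 0.0)).zeros();
  W.elem(arma::find(W > 1.0)).ones();
}

static const arma::uvec NO_FREE;

// expectation phase (EC_in clamped, EC_out free) then outcome phase
// (EC_out also clamped); weight update from the phase difference
static void train_trial(Weights& w, const Par& p, const arma::vec& pattern) {
  Acts a(p);
  arma::vec x_out = pattern;
  settle(a, w, p, pattern, NO_FREE, x_out, false, p.n_expect);
  Acts minus = a;
  settle(a, w, p, pattern, NO_FREE, x_out, true, p.n_cycles - p.n_expect);
  update_w(w.in_dg,   minus.in,  minus.dg,  a.in,  a.dg,  p.lr_in_dg,   p.hebb);
  update_w(w.in_ca3,  minus.in,  minus.ca3, a.in,  a.ca3, p.lr_in_ca3,  p.hebb);
  update_w(w.dg_ca3,  minus.dg,  minus.ca3, a.dg,  a.ca3, p.lr_dg_ca3,  p.hebb);
  update_w(w.ca3_ca1, minus.ca3, minus.ca1, a.ca3, a.ca1, p.lr_ca3_ca1, p.hebb);
  update_w(w.in_ca1,  minus.in,  minus.ca1, a.in,  a.ca1, p.lr_in_ca1,  p.hebb);
  update_w(w.out_ca1, minus.out, minus.ca1, a.out, a.ca1, p.lr_out_ca1, p.hebb);
  update_w(w.ca1_out, minus.ca1, minus.out, a.ca1, a.out, p.lr_ca1_out, p.hebb);
  update_w(w.out_in,  minus.out, minus.in,  a.out, a.in,  p.lr_out_in,  p.hebb);
}

// present every stimulus as a cue (category units blanked) and record
// settled activations; weights untouched
static List test_items_internal(const Weights& w, const Par& p,
                                const arma::mat& test_enc) {
  int n_stim = test_enc.n_rows;
  arma::mat dg(n_stim, p.n_dg), ca3(n_stim, p.n_ca3), ca1(n_stim, p.n_ca1),
            out(n_stim, 10), ec_in(n_stim, 10);
  arma::uvec in_free;
  if (p.test_category_free) in_free = {8, 9};
  for (int s = 0; s < n_stim; ++s) {
    arma::vec cue = test_enc.row(s).t();
    cue[8] = 0.0; cue[9] = 0.0;  // category units blanked at test
    Acts a(p);
    settle(a, w, p, cue, in_free, cue, false, p.n_cycles);
    dg.row(s) = a.dg.t(); ca3.row(s) = a.ca3.t(); ca1.row(s) = a.ca1.t();
    out.row(s) = a.out.t(); ec_in.row(s) = a.in.t();
  }
  return List::create(_["dg"] = dg, _["ca3"] = ca3, _["ca1"] = ca1,
                      _["ec_out"] = out, _["ec_in"] = ec_in);
}

// [[Rcpp::export]]
List hc_settle_cpp(List W, List par, NumericVector input,
                   IntegerVector free_in_units, bool clamp_out,
                   NumericVector out_pattern, int n_cycles,
                   Nullable<List> init_acts = R_NilValue) {
  Par p = read_par(par);
  Weights w = read_weights(W);
  Acts a(p);
  if (init_acts.isNotNull()) {
    List ia(init_acts);
    a.in = as<arma::vec>(ia["ec_in"]); a.dg = as<arma::vec>(ia["dg"]);
    a.ca3 = as<arma::vec>(ia["ca3"]); a.ca1 = as<arma::vec>(ia["ca1"]);
    a.out = as<arma::vec>(ia["ec_out"]);
  }
  arma::uvec in_free(free_in_units.size());
  for (int i = 0; i < free_in_units.size(); ++i) in_free[i] = free_in_units[i];
  settle(a, w, p, as<arma::vec>(input), in_free,
         as<arma::vec>(out_pattern), clamp_out, n_cycles);
  return List::create(_["ec_in"] = a.in, _["dg"] = a.dg, _["ca3"] = a.ca3,
                      _["ca1"] = a.ca1, _["ec_out"] = a.out);
}

// [[Rcpp::export]]
List hc_train_trial_cpp(List W, List par, NumericVector pattern) {
  Par p = read_par(par);
  Weights w = read_weights(W);
  train_trial(w, p, as<arma::vec>(pattern));
  return weights_list(w);
}

// [[Rcpp::export]]
List hc_test_items_cpp(List W, List par, NumericMatrix test_enc) {
  Par p = read_par(par);
  Weights w = read_weights(W);
  return test_items_internal(w, p, as<arma::mat>(test_enc));
}

// [[Rcpp::export]]
List hc_run_sequence_cpp(List W, List par, NumericMatrix seq_enc,
                         NumericMatrix test_enc, IntegerVector checkpoints) {
  Par p = read_par(par);
  Weights w = read_weights(W);
  arma::mat S = as<arma::mat>(seq_enc);
  arma::mat T = as<arma::mat>(test_enc);
  int n_trials = S.n_rows;
  List snaps(checkpoints.size());
  int next_cp = 0;
  for (int t = 0; t < n_trials; ++t) {
    train_trial(w, p, S.row(t).t());
    while (next_cp < checkpoints.size() && checkpoints[next_cp] == t + 1) {
      snaps[next_cp] = test_items_internal(w, p, T);
      ++next_cp;
    }
  }
  return List::create(_["snapshots"] = snaps, _["weights"] = weights_list(w));
}
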