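// Hot kernels of the data-augmented sampler: Gillespie simulation of one
// edge's complete subtree, and the factorised subtree density core shared
// by the proposal density and the complete-tree density.
//
// Uses R's RNG stream (R::rexp / R::runif / R::rlnorm), so results are
// reproducible with set.seed() and interleave correctly with R-side draws.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.918938533204673;
static const double SIGMA0_TOL = 1e-12;

struct Pars {
  double al, sl, am, sm, eps, rho;
  int mode;  // 0 turnover, 1 lognormal, 2 none
};

static Pars unpack(const List& params) {
  Pars p;
  p.al = as<double>(params["alpha_lambda"]);
  p.sl = as<double>(params["sigma_lambda"]);
  p.am = as<double>(params["alpha_mu"]);
  p.sm = as<double>(params["sigma_mu"]);
  p.eps = as<double>(params["epsilon"]);
  p.rho = as<double>(params["rho"]);
  std::string m = as<std::string>(params["death_mode"]);
  p.mode = (m == "turnover") ? 0 : (m == "lognormal" ? 1 : 2);
  return p;
}

// lognormal log-density
static inline double dlnorm_log(double x, double meanlog, double sdlog) {
  double z = (std::log(x) - meanlog) / sdlog;
  return -std::log(x) - std::log(sdlog) - LOG_SQRT_2PI - 0.5 * z * z;
}

// density (or constraint check) of one (lam, mu) draw from ancestral rates;
// returns -Inf on constraint violation
static double rate_draw_logdens(double lam, double mu, double ab, double ad,
                                const Pars& p) {
  double ll = 0.0;
  if (p.sl > 0) {
    ll += dlnorm_log(lam, std::log(p.al * ab), p.sl);
  } else {
    double tgt = p.al * ab;
    if (std::fabs(lam - tgt) > SIGMA0_TOL * std::max(tgt, 1.0))
      return R_NegInf;
  }
  if (p.mode == 1) {
    if (p.sm > 0) {
      ll += dlnorm_log(mu, std::log(p.am * ad), p.sm);
    } else {
      double tgt = p.am * ad;
      if (std::fabs(mu - tgt) > SIGMA0_TOL * std::max(tgt, 1.0))
        return R_NegInf;
    }
  }
  return ll;
}

// draw a daughter (lam, mu) pair
static inline void draw_pair(double pl, double pm, const Pars& p,
                             double& lam, double& mu) {
  lam = (p.sl > 0) ? R::rlnorm(std::log(p.al * pl), p.sl) : p.al * pl;
  switch (p.mode) {
    case 0: mu = p.eps * lam; break;
    case 1: mu = (p.sm > 0) ? R::rlnorm(std::log(p.am * pm), p.sm)
                            : p.am * pm; break;
    default: mu = 0.0;
  }
}

// [[Rcpp::export(name = ".sim_subtree_cpp")]]
SEXP sim_subtree_cpp(double edge_duration, bool ends_at_present,
                     double time_to_present, double anc_birth,
                     double anc_death, List params, int max_events) {
  if (edge_duration <= 0) return R_NilValue;
  if (ends_at_present) time_to_present = 0.0;
  Pars p = unpack(params);
  bool ln_mode = (p.mode == 1);

  double seed_lam, seed_mu;
  draw_pair(anc_birth, anc_death, p, seed_lam, seed_mu);
  double lq = rate_draw_logdens(seed_lam, seed_mu, anc_birth, anc_death, p);

  std::vector<double> lam(1, seed_lam), mu(1, seed_mu), seg0(1, 0.0);
  std::vector<int> did(1, 1);  // 1-based draw ids: 1 = seed, birth i -> 2i, 2i+1
  std::vector<std::vector<double> > ch_lam(1), ch_dt(1);
  std::vector<std::vector<int> > ch_did(1);
  std::vector<double> seg_lam, seg_mu, seg_dt;
  std::vector<int> seg_did, b_parent_did, d_did;
  std::vector<double> b_p_lam, b_c1_lam, b_c2_lam;
  std::vector<double> b_p_mu, b_c1_mu, b_c2_mu;
  std::vector<double> d_lam, d_mu;
  int n_events = 0, n_hidden = 0, n_births = 0;
  double t = 0.0;

  // phase 1: inside the edge
  for (;;) {
    double R_tot = 0.0;
    for (size_t i = 0; i < lam.size(); ++i) R_tot += lam[i] + mu[i];
    double dt = (R_tot > 0) ? R::rexp(1.0 / R_tot) : R_PosInf;
    if (t + dt >= edge_duration) {
      lq -= R_tot * (edge_duration - t);
      break;
    }
    t += dt;
    if (++n_events > max_events) return R_NilValue;
    size_t m = lam.size();
    double u = R::unif_rand() * R_tot, acc = 0.0;
    size_t idx = 2 * m - 1;
    bool is_birth = false;
    for (size_t i = 0; i < m; ++i) {
      acc += lam[i];
      if (u < acc) { idx = i; is_birth = true; break; }
    }
    if (!is_birth) {
      for (size_t i = 0; i < m; ++i) {
        acc += mu[i];
        if (u < acc) { idx = i; break; }
      }
      if (idx == 2 * m - 1) idx = m - 1;  // numerical edge: last death
    }
    double chosen = is_birth ? lam[idx] : mu[idx];
    lq += std::log(R_tot) - R_tot * dt + std::log(chosen / R_tot);
    if (is_birth) {
      size_t i = idx;
      double l1, m1, l2, m2;
      draw_pair(lam[i], mu[i], p, l1, m1);
      draw_pair(lam[i], mu[i], p, l2, m2);
      if (p.sl > 0) {
        double ml = std::log(p.al * lam[i]);
        lq += dlnorm_log(l1, ml, p.sl) + dlnorm_log(l2, ml, p.sl);
      }
      if (ln_mode && p.sm > 0) {
        double mm = std::log(p.am * mu[i]);
        lq += dlnorm_log(m1, mm, p.sm) + dlnorm_log(m2, mm, p.sm);
      }
      double dur = t - seg0[i];
      seg_lam.push_back(lam[i]); seg_mu.push_back(mu[i]);
      seg_dt.push_back(dur); seg_did.push_back(did[i]);
      b_p_lam.push_back(lam[i]); b_parent_did.push_back(did[i]);
      b_c1_lam.push_back(l1); b_c2_lam.push_back(l2);
      if (ln_mode) {
        b_p_mu.push_back(mu[i]);
        b_c1_mu.push_back(m1); b_c2_mu.push_back(m2);
      }
      ++n_births;
      ch_lam[i].push_back(lam[i]); ch_dt[i].push_back(dur);
      ch_did[i].push_back(did[i]);
      std::vector<double> cl = ch_lam[i], cd = ch_dt[i];
      std::vector<int> ci = ch_did[i];
      lam[i] = l1; mu[i] = m1; seg0[i] = t; did[i] = 2 * n_births;
      lam.push_back(l2); mu.push_back(m2); seg0.push_back(t);
      did.push_back(2 * n_births + 1);
      ch_lam.push_back(cl); ch_dt.push_back(cd); ch_did.push_back(ci);
    } else {
      size_t i = idx;
      seg_lam.push_back(lam[i]); seg_mu.push_back(mu[i]);
      seg_dt.push_back(t - seg0[i]); seg_did.push_back(did[i]);
      d_lam.push_back(lam[i]); d_did.push_back(did[i]);
      if (ln_mode) d_mu.push_back(mu[i]);
      lam.erase(lam.begin() + i); mu.erase(mu.begin() + i);
      seg0.erase(seg0.begin() + i); did.erase(did.begin() + i);
      ch_lam.erase(ch_lam.begin() + i); ch_dt.erase(ch_dt.begin() + i);
      ch_did.erase(ch_did.begin() + i);
      if (lam.empty()) return R_NilValue;  // extinct before edge end
    }
  }

  // edge end: close segments, choose the spine uniformly
  int k = (int) lam.size();
  for (int i = 0; i < k; ++i) {
    seg_lam.push_back(lam[i]); seg_mu.push_back(mu[i]);
    seg_dt.push_back(edge_duration - seg0[i]); seg_did.push_back(did[i]);
  }
  int sp = (k > 1) ? (int)(R::unif_rand() * k) : 0;
  if (sp >= k) sp = k - 1;
  lq -= std::log((double) k);
  double spine_lam = lam[sp], spine_mu = mu[sp];
  int spine_did = did[sp];
  std::vector<double> sp_seg_lam = ch_lam[sp], sp_seg_dt = ch_dt[sp];
  std::vector<int> sp_seg_did = ch_did[sp];
  sp_seg_lam.push_back(lam[sp]);
  sp_seg_dt.push_back(edge_duration - seg0[sp]);
  sp_seg_did.push_back(did[sp]);
  lam.erase(lam.begin() + sp); mu.erase(mu.begin() + sp);
  did.erase(did.begin() + sp);

  // phase 2: hidden survivors continue to extinction or the present
  if (!lam.empty()) {
    if (ends_at_present) {
      if (p.rho >= 1) return R_NilValue;
      for (size_t i = 0; i < lam.size(); ++i)
        if (R::unif_rand() < p.rho) return R_NilValue;
      lq += lam.size() * std::log1p(-p.rho);
      n_hidden = (int) lam.size();
    } else {
      seg0.assign(lam.size(), 0.0);
      double t2 = 0.0, H = time_to_present;
      for (;;) {
        if (lam.empty()) break;
        double R_tot = 0.0;
        for (size_t i = 0; i < lam.size(); ++i) R_tot += lam[i] + mu[i];
        double dt = (R_tot > 0) ? R::rexp(1.0 / R_tot) : R_PosInf;
        if (t2 + dt >= H) {
          lq -= R_tot * (H - t2);
          for (size_t i = 0; i < lam.size(); ++i) {
            seg_lam.push_back(lam[i]); seg_mu.push_back(mu[i]);
            seg_dt.push_back(H - seg0[i]); seg_did.push_back(did[i]);
          }
          if (p.rho >= 1) return R_NilValue;
          for (size_t i = 0; i < lam.size(); ++i)
            if (R::unif_rand() < p.rho) return R_NilValue;
          lq += lam.size() * std::log1p(-p.rho);
          n_hidden += (int) lam.size();
          break;
        }
        t2 += dt;
        if (++n_events > max_events) return R_NilValue;
        size_t m = lam.size();
        double u = R::unif_rand() * R_tot, acc = 0.0;
        size_t idx = 2 * m - 1;
        bool is_birth = false;
        for (size_t i = 0; i < m; ++i) {
          acc += lam[i];
          if (u < acc) { idx = i; is_birth = true; break; }
        }
        if (!is_birth) {
          for (size_t i = 0; i < m; ++i) {
            acc += mu[i];
            if (u < acc) { idx = i; break; }
          }
          if (idx == 2 * m - 1) idx = m - 1;
        }
        double chosen = is_birth ? lam[idx] : mu[idx];
        lq += std::log(R_tot) - R_tot * dt + std::log(chosen / R_tot);
        if (is_birth) {
          size_t i = idx;
          double l1, m1, l2, m2;
          draw_pair(lam[i], mu[i], p, l1, m1);
          draw_pair(lam[i], mu[i], p, l2, m2);
          if (p.sl > 0) {
            double ml = std::log(p.al * lam[i]);
            lq += dlnorm_log(l1, ml, p.sl) + dlnorm_log(l2, ml, p.sl);
          }
          if (ln_mode && p.sm > 0) {
            double mm = std::log(p.am * mu[i]);
            lq += dlnorm_log(m1, mm, p.sm) + dlnorm_log(m2, mm, p.sm);
          }
          seg_lam.push_back(lam[i]); seg_mu.push_back(mu[i]);
          seg_dt.push_back(t2 - seg0[i]); seg_did.push_back(did[i]);
          b_p_lam.push_back(lam[i]); b_parent_did.push_back(did[i]);
          b_c1_lam.push_back(l1); b_c2_lam.push_back(l2);
          if (ln_mode) {
            b_p_mu.push_back(mu[i]);
            b_c1_mu.push_back(m1); b_c2_mu.push_back(m2);
          }
          ++n_births;
          lam[i] = l1; mu[i] = m1; seg0[i] = t2; did[i] = 2 * n_births;
          lam.push_back(l2); mu.push_back(m2); seg0.push_back(t2);
          did.push_back(2 * n_births + 1);
        } else {
          size_t i = idx;
          seg_lam.push_back(lam[i]); seg_mu.push_back(mu[i]);
          seg_dt.push_back(t2 - seg0[i]); seg_did.push_back(did[i]);
          d_lam.push_back(lam[i]); d_did.push_back(did[i]);
          if (ln_mode) d_mu.push_back(mu[i]);
          lam.erase(lam.begin() + i); mu.erase(mu.begin() + i);
          seg0.erase(seg0.begin() + i); did.erase(did.begin() + i);
        }
      }
    }
  }

  List out = List::create(
    _["seed"] = NumericVector::create(_["birth"] = seed_lam,
                                      _["death"] = seed_mu),
    _["spine"] = NumericVector::create(_["birth"] = spine_lam,
                                       _["death"] = spine_mu),
    _["k"] = k,
    _["ends_at_present"] = ends_at_present,
    _["seg_lam"] = wrap(seg_lam),
    _["seg_mu"] = ln_mode ? wrap(seg_mu) : R_NilValue,
    _["seg_dt"] = wrap(seg_dt),
    _["spine_seg_lam"] = wrap(sp_seg_lam),
    _["spine_seg_dt"] = wrap(sp_seg_dt),
    _["b_p_lam"] = wrap(b_p_lam),
    _["b_c1_lam"] = wrap(b_c1_lam),
    _["b_c2_lam"] = wrap(b_c2_lam),
    _["b_p_mu"] = wrap(b_p_mu),
    _["b_c1_mu"] = wrap(b_c1_mu),
    _["b_c2_mu"] = wrap(b_c2_mu),
    _["d_lam"] = wrap(d_lam),
    _["d_mu"] = wrap(d_mu),
    _["n_hidden"] = n_hidden,
    _["seg_did"] = wrap(seg_did),
    _["spine_seg_did"] = wrap(sp_seg_did),
    _["spine_did"] = spine_did,
    _["b_parent_did"] = wrap(b_parent_did),
    _["d_did"] = wrap(d_did),
    _["log_q"] = lq);
  out.attr("class") = "clads_subtree";
  return out;
}

// [[Rcpp::export(name = ".subtree_core_cpp")]]
double subtree_core_cpp(List sub, double anc_birth, double anc_death,
                        List params) {
  Pars p = unpack(params);
  bool ln_mode = (p.mode == 1);
  NumericVector seed = sub["seed"];
  double lq = rate_draw_logdens(seed[0], seed[1], anc_birth, anc_death, p);
  if (lq == R_NegInf) return R_NegInf;

  NumericVector seg_lam = sub["seg_lam"], seg_dt = sub["seg_dt"];
  if (ln_mode) {
    NumericVector seg_mu = sub["seg_mu"];
    for (int i = 0; i < seg_lam.size(); ++i)
      lq -= (seg_lam[i] + seg_mu[i]) * seg_dt[i];
  } else {
    for (int i = 0; i < seg_lam.size(); ++i)
      lq -= seg_lam[i] * (1.0 + p.eps) * seg_dt[i];
  }

  NumericVector bp = sub["b_p_lam"], b1 = sub["b_c1_lam"],
                b2 = sub["b_c2_lam"];
  for (int i = 0; i < bp.size(); ++i) {
    lq += std::log(bp[i]);
    if (p.sl > 0) {
      double ml = std::log(p.al * bp[i]);
      lq += dlnorm_log(b1[i], ml, p.sl) + dlnorm_log(b2[i], ml, p.sl);
    } else {
      double tgt = p.al * bp[i], tol = SIGMA0_TOL * std::max(tgt, 1.0);
      if (std::fabs(b1[i] - tgt) > tol || std::fabs(b2[i] - tgt) > tol)
        return R_NegInf;
    }
  }
  if (ln_mode && bp.size() > 0) {
    NumericVector mp = sub["b_p_mu"], mc1 = sub["b_c1_mu"],
                  mc2 = sub["b_c2_mu"];
    for (int i = 0; i < mp.size(); ++i) {
      if (p.sm > 0) {
        double mm = std::log(p.am * mp[i]);
        lq += dlnorm_log(mc1[i], mm, p.sm) + dlnorm_log(mc2[i], mm, p.sm);
      } else {
        double tgt = p.am * mp[i], tol = SIGMA0_TOL * std::max(tgt, 1.0);
        if (std::fabs(mc1[i] - tgt) > tol || std::fabs(mc2[i] - tgt) > tol)
          return R_NegInf;
      }
    }
  }

  NumericVector d_lam = sub["d_lam"];
  if (d_lam.size() > 0) {
    if (ln_mode) {
      NumericVector dm = sub["d_mu"];
      for (int i = 0; i < dm.size(); ++i) {
        if (dm[i] <= 0) return R_NegInf;
        lq += std::log(dm[i]);
      }
    } else {
      for (int i = 0; i < d_lam.size(); ++i) {
        double dmu = p.eps * d_lam[i];
        if (dmu <= 0) return R_NegInf;
        lq += std::log(dmu);
      }
    }
  }

  int n_hidden = as<int>(sub["n_hidden"]);
  if (n_hidden > 0) {
    if (p.rho >= 1) return R_NegInf;
    lq += n_hidden * std::log1p(-p.rho);
  }
  return lq;
}

// [[Rcpp::export(name = ".sim_complete_cpp")]]
List sim_complete_cpp(List params, double crown_age, int max_lineages,
                      int max_events, int want_n = -1) {
  Pars p = unpack(params);
  double l0 = as<double>(params["lambda0"]);
  double m0 = (p.mode == 0) ? p.eps * l0 : (p.mode == 1 ?
               as<double>(params["mu0"]) : 0.0);
  std::vector<double> lam, mu, t0v, t1v;
  std::vector<int> parent, status;  // status: 0 extant, 1 birth, 2 death
  lam.reserve(64); mu.reserve(64); t0v.reserve(64); t1v.reserve(64);
  parent.reserve(64); status.reserve(64);
  for (int i = 0; i < 2; ++i) {
    double li, mi;
    draw_pair(l0, m0, p, li, mi);
    parent.push_back(0); lam.push_back(li); mu.push_back(mi);
    t0v.push_back(0.0); t1v.push_back(NA_REAL); status.push_back(0);
  }
  std::vector<int> active;
  active.push_back(0); active.push_back(1);
  double t = 0.0;
  bool valid = true;
  int n_events = 0;
  double R_tot = lam[0] + mu[0] + lam[1] + mu[1];
  for (;;) {
    if ((n_events & 1023) == 0) {  // refresh against floating-point drift
      R_tot = 0.0;
      for (size_t a = 0; a < active.size(); ++a)
        R_tot += lam[active[a]] + mu[active[a]];
    }
    double dt = (R_tot > 0) ? R::rexp(1.0 / R_tot) : R_PosInf;
    if (t + dt >= crown_age) break;
    t += dt;
    if (++n_events > max_events) { valid = false; break; }
    double u = R::unif_rand() * R_tot, acc = 0.0;
    int pos = -1;
    bool is_birth = false;
    for (size_t a = 0; a < active.size(); ++a) {
      acc += lam[active[a]];
      if (u < acc) { pos = (int) a; is_birth = true; break; }
    }
    if (pos < 0) {
      for (size_t a = 0; a < active.size(); ++a) {
        acc += mu[active[a]];
        if (u < acc) { pos = (int) a; break; }
      }
      if (pos < 0) pos = (int) active.size() - 1;
    }
    int i = active[pos];
    if (is_birth) {
      double l1, m1, l2, m2;
      draw_pair(lam[i], mu[i], p, l1, m1);
      draw_pair(lam[i], mu[i], p, l2, m2);
      int id1 = (int) lam.size(), id2 = id1 + 1;
      parent.push_back(i + 1); lam.push_back(l1); mu.push_back(m1);
      t0v.push_back(t); t1v.push_back(NA_REAL); status.push_back(0);
      parent.push_back(i + 1); lam.push_back(l2); mu.push_back(m2);
      t0v.push_back(t); t1v.push_back(NA_REAL); status.push_back(0);
      t1v[i] = t; status[i] = 1;
      active.erase(active.begin() + pos);
      active.push_back(id1); active.push_back(id2);
      R_tot += l1 + m1 + l2 + m2 - lam[i] - mu[i];
      if ((int) active.size() > max_lineages) { valid = false; break; }
    } else {
      t1v[i] = t; status[i] = 2;
      active.erase(active.begin() + pos);
      R_tot -= lam[i] + mu[i];
      if (active.empty()) break;
    }
  }
  int nrec = (int) lam.size();
  LogicalVector sampled(nrec, false);
  int n_sampled = 0;
  if (valid) {
    for (size_t a = 0; a < active.size(); ++a) {
      int i = active[a];
      t1v[i] = crown_age;
      status[i] = 0;
      if (R::unif_rand() < p.rho) { sampled[i] = true; ++n_sampled; }
    }
  }
  // rejection fast path: spare the (large) array copies when the caller
  // only keeps replicates with a specific sampled tip count
  if (want_n >= 0 && (!valid || n_sampled != want_n))
    return List::create(_["valid"] = valid, _["n_sampled"] = n_sampled);
  return List::create(
    _["parent"] = wrap(parent), _["lam"] = wrap(lam), _["mu"] = wrap(mu),
    _["t0"] = wrap(t0v), _["t1"] = wrap(t1v),
    _["status_code"] = wrap(status), _["sampled"] = sampled,
    _["crown_age"] = crown_age, _["valid"] = valid,
    _["n_sampled"] = n_sampled);
}

// target-side contribution of one subtree: shared core plus log(rho) for a
// sampled tip (edge at present) or the birth-rate factor at the split
static double target_contrib(List sub, double anc_birth, double anc_death,
                             List& params) {
  double core = subtree_core_cpp(sub, anc_birth, anc_death, params);
  if (core == R_NegInf) return R_NegInf;
  bool at_present = as<bool>(sub["ends_at_present"]);
  if (at_present) {
    double rho = as<double>(params["rho"]);
    return core + std::log(rho);
  }
  NumericVector spine = sub["spine"];
  return core + std::log(spine[0]);
}

// [[Rcpp::export(name = ".edge_contribs_cpp")]]
NumericVector edge_contribs_cpp(List subs, IntegerVector parent, int root,
                                NumericVector root_rates, List params,
                                IntegerVector edges,
                                NumericVector contrib) {
  NumericVector out = clone(contrib);
  for (int k = 0; k < edges.size(); ++k) {
    int e = edges[k];
    int p = parent[e - 1];
    double ab, ad;
    if (p == root) {
      ab = root_rates[0]; ad = root_rates[1];
    } else {
      List ps = subs[p - 1];
      NumericVector sp = ps["spine"];
      ab = sp[0]; ad = sp[1];
    }
    List sub = subs[e - 1];
    out[e - 1] = target_contrib(sub, ab, ad, params);
  }
  return out;
}

// Non-centered transform of every latent birth-rate draw, keeping the
// standardized deviations fixed. `edges` must be ordered parents before
// children. Modifies a shallow copy of the subtree list and returns it
// with the log-Jacobian ingredients.
// [[Rcpp::export(name = ".transform_rates_cpp")]]
List transform_rates_cpp(List subs, IntegerVector parent, int root,
                         IntegerVector edges, List params_old,
                         List params_new) {
  Pars po = unpack(params_old), pn = unpack(params_new);
  double l0_old = as<double>(params_old["lambda0"]);
  double l0_new = as<double>(params_new["lambda0"]);
  double eps = (pn.mode == 0) ? pn.eps : 0.0;
  if (pn.mode == 1) stop("joint rate transform needs derived death rates");
  int nn = parent.size();
  std::vector<double> anc_old(nn + 1, 0.0), anc_new(nn + 1, 0.0);
  anc_old[root] = l0_old; anc_new[root] = l0_new;
  double sum_log_ratio = 0.0;
  int n_draws = 0;
  List out = clone(subs);
  for (int k = 0; k < edges.size(); ++k) {
    int e = edges[k];
    int p = parent[e - 1];
    List s = clone(as<List>(out[e - 1]));
    NumericVector seed = clone(as<NumericVector>(s["seed"]));
    NumericVector b1 = clone(as<NumericVector>(s["b_c1_lam"]));
    NumericVector b2 = clone(as<NumericVector>(s["b_c2_lam"]));
    IntegerVector bpd = s["b_parent_did"];
    int nb = b1.size();
    std::vector<double> v_old(1 + 2 * nb), v_new(1 + 2 * nb);
    v_old[0] = seed[0];
    for (int i = 0; i < nb; ++i) {
      v_old[1 + 2 * i] = b1[i];       // draw id 2(i+1) -> index 2i+1
      v_old[2 + 2 * i] = b2[i];       // draw id 2(i+1)+1 -> index 2i+2
    }
    double z = (std::log(v_old[0]) - std::log(po.al * anc_old[p])) / po.sl;
    v_new[0] = std::exp(std::log(pn.al * anc_new[p]) + pn.sl * z);
    for (int i = 0; i < nb; ++i) {
      int pd = bpd[i] - 1;  // 1-based draw id -> 0-based index
      for (int j = 1 + 2 * i; j <= 2 + 2 * i; ++j) {
        double zz = (std::log(v_old[j]) -
                     std::log(po.al * v_old[pd])) / po.sl;
        v_new[j] = std::exp(std::log(pn.al * v_new[pd]) + pn.sl * zz);
      }
    }
    seed[0] = v_new[0]; seed[1] = eps * v_new[0];
    s["seed"] = seed;
    if (nb > 0) {
      NumericVector bp = clone(as<NumericVector>(s["b_p_lam"]));
      for (int i = 0; i < nb; ++i) {
        b1[i] = v_new[1 + 2 * i];
        b2[i] = v_new[2 + 2 * i];
        bp[i] = v_new[bpd[i] - 1];
      }
      s["b_c1_lam"] = b1; s["b_c2_lam"] = b2; s["b_p_lam"] = bp;
    }
    IntegerVector seg_did = s["seg_did"];
    NumericVector seg_lam(seg_did.size());
    for (int i = 0; i < seg_did.size(); ++i)
      seg_lam[i] = v_new[seg_did[i] - 1];
    s["seg_lam"] = seg_lam;
    IntegerVector sp_did = s["spine_seg_did"];
    NumericVector sp_lam(sp_did.size());
    for (int i = 0; i < sp_did.size(); ++i)
      sp_lam[i] = v_new[sp_did[i] - 1];
    s["spine_seg_lam"] = sp_lam;
    int spine_did = as<int>(s["spine_did"]);
    NumericVector spine = clone(as<NumericVector>(s["spine"]));
    double sp_new = v_new[spine_did - 1];
    spine[0] = sp_new; spine[1] = eps * sp_new;
    s["spine"] = spine;
    IntegerVector d_did = s["d_did"];
    if (d_did.size() > 0) {
      NumericVector d_lam(d_did.size());
      for (int i = 0; i < d_did.size(); ++i)
        d_lam[i] = v_new[d_did[i] - 1];
      s["d_lam"] = d_lam;
    }
    s["log_q"] = NA_REAL;
    out[e - 1] = s;
    anc_old[e] = v_old[spine_did - 1];
    anc_new[e] = sp_new;
    for (size_t j = 0; j < v_new.size(); ++j)
      sum_log_ratio += std::log(v_new[j]) - std::log(v_old[j]);
    n_draws += (int) v_new.size();
  }
  return List::create(_["subs"] = out, _["sum_log_ratio"] = sum_log_ratio,
                      _["n_draws"] = n_draws);
}

// Per-edge sufficient statistics of the birth-rate inheritance draws:
// N_e draws, sum and sum of squares of d_j = log(child) - log(parent
// value). The centered conditionals of alpha_lambda / sigma_lambda depend
// on the latents only through these, which makes those updates O(1) per
// slice evaluation.
// [[Rcpp::export(name = ".inherit_stats_cpp")]]
NumericMatrix inherit_stats_cpp(List subs, IntegerVector parent, int root,
                                double lambda0) {
  int nn = parent.size();
  NumericMatrix out(nn, 3);  // N, S1, S2 per edge (child node id rows)
  std::vector<double> spine_lam(nn + 1, 0.0);
  spine_lam[root] = lambda0;
  // need parents processed first: iterate twice (spine values don't
  // depend on processing order, read directly from subs)
  for (int e = 1; e <= nn; ++e) {
    if (e == root) continue;
    List s = subs[e - 1];
    NumericVector sp = s["spine"];
    spine_lam[e] = sp[0];
  }
  for (int e = 1; e <= nn; ++e) {
    if (e == root) continue;
    List s = subs[e - 1];
    NumericVector seed = s["seed"];
    double anc = spine_lam[parent[e - 1]];
    double d = std::log(seed[0]) - std::log(anc);
    double N = 1.0, S1 = d, S2 = d * d;
    NumericVector bp = s["b_p_lam"], b1 = s["b_c1_lam"],
                  b2 = s["b_c2_lam"];
    for (int i = 0; i < bp.size(); ++i) {
      double d1 = std::log(b1[i]) - std::log(bp[i]);
      double d2 = std::log(b2[i]) - std::log(bp[i]);
      N += 2.0; S1 += d1 + d2; S2 += d1 * d1 + d2 * d2;
    }
    out(e - 1, 0) = N; out(e - 1, 1) = S1; out(e - 1, 2) = S2;
  }
  return out;
}

// Extract the standardized deviations z_j of every birth-rate draw, in
// edge order (seed, then birth daughters pairwise), plus sum(log V).
// [[Rcpp::export(name = ".get_z_cpp")]]
List get_z_cpp(List subs, IntegerVector parent, int root,
               IntegerVector edges, List params) {
  Pars p = unpack(params);
  double l0 = as<double>(params["lambda0"]);
  int nn = parent.size();
  std::vector<double> spine_lam(nn + 1, 0.0);
  spine_lam[root] = l0;
  for (int e = 1; e <= nn; ++e) {
    if (e == root) continue;
    List s = subs[e - 1];
    NumericVector sp = s["spine"];
    spine_lam[e] = sp[0];
  }
  std::vector<double> z;
  double sum_log_v = 0.0;
  for (int k = 0; k < edges.size(); ++k) {
    int e = edges[k];
    List s = subs[e - 1];
    NumericVector seed = s["seed"];
    double anc = spine_lam[parent[e - 1]];
    z.push_back((std::log(seed[0]) - std::log(p.al * anc)) / p.sl);
    sum_log_v += std::log(seed[0]);
    NumericVector bp = s["b_p_lam"], b1 = s["b_c1_lam"],
                  b2 = s["b_c2_lam"];
    for (int i = 0; i < bp.size(); ++i) {
      double m = std::log(p.al * bp[i]);
      z.push_back((std::log(b1[i]) - m) / p.sl);
      z.push_back((std::log(b2[i]) - m) / p.sl);
      sum_log_v += std::log(b1[i]) + std::log(b2[i]);
    }
  }
  return List::create(_["z"] = wrap(z), _["sum_log_v"] = sum_log_v);
}

// Rebuild every latent birth rate from a given z-vector (same ordering as
// .get_z_cpp), parents before children. Returns the rebuilt subtree list
// and sum(log V).
// [[Rcpp::export(name = ".set_z_cpp")]]
List set_z_cpp(List subs, IntegerVector parent, int root,
               IntegerVector edges, List params, NumericVector z) {
  Pars p = unpack(params);
  double l0 = as<double>(params["lambda0"]);
  double eps = (p.mode == 0) ? p.eps : 0.0;
  if (p.mode == 1) stop("z-field update needs derived death rates");
  int nn = parent.size();
  std::vector<double> anc_new(nn + 1, 0.0);
  anc_new[root] = l0;
  List out = clone(subs);
  int zi = 0;
  double sum_log_v = 0.0;
  for (int k = 0; k < edges.size(); ++k) {
    int e = edges[k];
    List s = clone(as<List>(out[e - 1]));
    NumericVector seed = clone(as<NumericVector>(s["seed"]));
    NumericVector b1 = clone(as<NumericVector>(s["b_c1_lam"]));
    NumericVector b2 = clone(as<NumericVector>(s["b_c2_lam"]));
    IntegerVector bpd = s["b_parent_did"];
    int nb = b1.size();
    std::vector<double> v(1 + 2 * nb);
    v[0] = std::exp(std::log(p.al * anc_new[parent[e - 1]]) +
                    p.sl * z[zi++]);
    for (int i = 0; i < nb; ++i) {
      double m = std::log(p.al * v[bpd[i] - 1]);
      v[1 + 2 * i] = std::exp(m + p.sl * z[zi++]);
      v[2 + 2 * i] = std::exp(m + p.sl * z[zi++]);
    }
    for (size_t j = 0; j < v.size(); ++j) sum_log_v += std::log(v[j]);
    seed[0] = v[0]; seed[1] = eps * v[0];
    s["seed"] = seed;
    if (nb > 0) {
      NumericVector bp = clone(as<NumericVector>(s["b_p_lam"]));
      for (int i = 0; i < nb; ++i) {
        b1[i] = v[1 + 2 * i]; b2[i] = v[2 + 2 * i];
        bp[i] = v[bpd[i] - 1];
      }
      s["b_c1_lam"] = b1; s["b_c2_lam"] = b2; s["b_p_lam"] = bp;
    }
    IntegerVector seg_did = s["seg_did"];
    NumericVector seg_lam(seg_did.size());
    for (int i = 0; i < seg_did.size(); ++i)
      seg_lam[i] = v[seg_did[i] - 1];
    s["seg_lam"] = seg_lam;
    IntegerVector sp_did = s["spine_seg_did"];
    NumericVector sp_lam(sp_did.size());
    for (int i = 0; i < sp_did.size(); ++i)
      sp_lam[i] = v[sp_did[i] - 1];
    s["spine_seg_lam"] = sp_lam;
    int spine_did = as<int>(s["spine_did"]);
    NumericVector spine = clone(as<NumericVector>(s["spine"]));
    spine[0] = v[spine_did - 1]; spine[1] = eps * v[spine_did - 1];
    s["spine"] = spine;
    IntegerVector d_did = s["d_did"];
    if (d_did.size() > 0) {
      NumericVector d_lam(d_did.size());
      for (int i = 0; i < d_did.size(); ++i)
        d_lam[i] = v[d_did[i] - 1];
      s["d_lam"] = d_lam;
    }
    s["log_q"] = NA_REAL;
    out[e - 1] = s;
    anc_new[e] = v[spine_did - 1];
  }
  return List::create(_["subs"] = out, _["sum_log_v"] = sum_log_v);
}
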