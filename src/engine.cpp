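#include "sim_common.h"
#include "diffusion.h"
using namespace Rcpp;

// ---- distribution sampling (R RNG stream) ---------------------------------

struct DistSpec {
  int type;                 // 0 fixed, 1 gamma(shape,scale), 2 truncnorm(sd,lo,hi), 3 histogram
  double a, b, lo, hi;
  std::vector<double> vals, cumw;
};

static DistSpec parse_dist(List d) {
  DistSpec s;
  s.type = as<int>(d["type"]);
  s.a = as<double>(d["a"]);
  s.b = as<double>(d["b"]);
  s.lo = as<double>(d["lo"]);
  s.hi = as<double>(d["hi"]);
  NumericVector v = d["vals"], w = d["wts"];
  s.vals.assign(v.begin(), v.end());
  s.cumw.resize(w.size());
  double acc = 0.0;
  for (int i = 0; i < w.size(); ++i) { acc += w[i]; s.cumw[i] = acc; }
  if (acc > 0) for (size_t i = 0; i < s.cumw.size(); ++i) s.cumw[i] /= acc;
  return s;
}

static double sample_dist(const DistSpec& s) {
  switch (s.type) {
    case 0: return s.a;
    case 1: return R::rgamma(s.a, s.b);
    case 2: {
      for (int tries = 0; tries < 1000; ++tries) {
        double v = R::rnorm(0.0, s.a);
        if (v > s.lo && v < s.hi) return v;
      }
      return 0.0;
    }
    default: {
      double u = unif_rand();
      size_t i = std::lower_bound(s.cumw.begin(), s.cumw.end(), u) - s.cumw.begin();
      if (i >= s.vals.size()) i = s.vals.size() - 1;
      return s.vals[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sample_dist(List dist, int n) {
  DistSpec s = parse_dist(dist);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_dist(s);
  return out;
}

// ---- field interpolation ---------------------------------------------------

static double field_value(const std::vector<double>& C, double L, int scheme,
                          double dx_phys, double xm) {
  int n = (int)C.size();
  if (n == 0) return 0.0;
  double pos;  // fractional node index
  if (scheme == 0) {
    if (L <= 0) return 0.0;
    double xi = xm / L;
    if (xi < 0) xi = 0;
    if (xi > 1) return 0.0;
    pos = xi * (n - 1);
  } else {
    if (xm < 0) xm = 0;
    pos = xm / dx_phys;
    if (pos > n - 1) return 0.0;
  }
  int i0 = (int)std::floor(pos);
  if (i0 >= n - 1) return C[n - 1];
  double f = pos - i0;
  return (1.0 - f) * C[i0] + f * C[i0 + 1];
}

// [[Rcpp::export]]
double cpp_field_value(NumericVector C, double L, int scheme, double dx_phys,
                       double xm) {
  std::vector<double> cc(C.begin(), C.end());
  return field_value(cc, L, scheme, dx_phys, xm);
}

// ---- donor selection -------------------------------------------------------

// Uniformly chosen occupied receiver whose x coordinate is within `band`
// of x_ref, excluding `exclude`; if the band is empty it widens to the
// receiver nearest in |dx| (spec fallback). Returns -1 if no receivers.
static int pick_donor(const NumericMatrix& xy, const std::vector<char>& occ,
                      const std::vector<char>& prod, double x_ref,
                      double band, int exclude) {
  int n = xy.nrow();
  std::vector<int> pool;
  for (int i = 0; i < n; ++i) {
    if (i == exclude || !occ[i] || prod[i]) continue;
    if (std::fabs(xy(i, 0) - x_ref) <= band) pool.push_back(i);
  }
  if (!pool.empty()) {
    int j = (int)(unif_rand() * pool.size());
    if (j >= (int)pool.size()) j = pool.size() - 1;
    return pool[j];
  }
  int best = -1;
  double bd = R_PosInf;
  for (int i = 0; i < n; ++i) {
    if (i == exclude || !occ[i] || prod[i]) continue;
    double d = std::fabs(xy(i, 0) - x_ref);
    if (d < bd) { bd = d; best = i; }
  }
  return best;
}

// [[Rcpp::export]]
int cpp_pick_donor(NumericMatrix xy, LogicalVector occupied,
                   LogicalVector producer, double x_ref, double band,
                   int exclude) {
  std::vector<char> occ(occupied.size()), prod(producer.size());
  for (int i = 0; i < occupied.size(); ++i) {
    occ[i] = occupied[i] ? 1 : 0;
    prod[i] = producer[i] ? 1 : 0;
  }
  return pick_donor(xy, occ, prod, x_ref, band, exclude);
}

// ---- the Monte-Carlo event loop -------------------------------------------

// Advances the tissue state by `nsteps` steps of length dt, starting after
// absolute step `t_offset` of a run with `duration_steps` steps in total
// (the absolute clock matters only for the apoptosis window). Processes per
// step, each sweeping cells in ascending site order: production (cytoneme
// deposition or field step + absorption), insertion, migration, decay,
// apoptosis. All randomness is drawn from R's RNG stream.
// [[Rcpp::export]]
List cpp_advance(NumericMatrix xy, IntegerMatrix nbor,
                 LogicalVector producer,
                 LogicalVector occ_in, NumericVector content_in,
                 IntegerVector fate_in, IntegerVector cid_in, int next_id,
                 List tp, List dyn,
                 double dt, int nsteps, int t_offset, int duration_steps,
                 IntegerVector snap_steps,
                 NumericVector field_in, double L_in,
                 double producer_edge, double radius,
                 int apop_killed_in) {
  int n = xy.nrow();
  std::vector<char> occ(n), prod(n);
  std::vector<double> content(n);
  std::vector<int> fate(n), cid(n);
  for (int i = 0; i < n; ++i) {
    occ[i] = occ_in[i] ? 1 : 0;
    prod[i] = producer[i] ? 1 : 0;
    content[i] = content_in[i];
    fate[i] = fate_in[i];
    cid[i] = cid_in[i];
  }

  int mode = as<int>(tp["mode"]);  // 0 cytoneme, 1 diffusion
  double p_fil = as<double>(tp["p_fil"]);
  double deposit = as<double>(tp["deposit_amount"]);
  double tol = as<double>(tp["contact_tolerance"]);
  double p_decay = as<double>(tp["p_decay"]);
  DistSpec len_d, ang_d;
  if (mode == 0) {
    len_d = parse_dist(tp["length_dist"]);
    ang_d = parse_dist(tp["angle_dist"]);
  }
  double D = as<double>(tp["D"]);
  double kappa = as<double>(tp["kappa"]);
  double C0 = as<double>(tp["C0"]);
  int scheme = as<int>(tp["scheme"]);
  double u_adv = as<double>(tp["u"]);
  double dx_phys = as<double>(tp["dx"]);

  double p_ins = as<double>(dyn["p_ins"]);
  double p_mig = as<double>(dyn["p_mig"]);
  double p_dirmig = as<double>(dyn["p_dirmig"]);
  double dirmig_scale = as<double>(dyn["dirmig_scale"]);
  bool apop_on = as<bool>(dyn["apoptosis_enabled"]);
  int apop_budget = as<int>(dyn["apoptosis_budget"]);
  double apop_window = as<double>(dyn["apoptosis_window"]);
  int apop_interval = as<int>(dyn["apoptosis_interval"]);
  double donor_band = as<double>(dyn["donor_band"]);
  double disc_floor = as<double>(dyn["discrepancy_floor"]);
  bool disc_relative = as<std::string>(dyn["discrepancy"]) == "relative";

  std::vector<double> field(field_in.begin(), field_in.end());
  double L = L_in;

  // apoptosis schedule from the absolute clock
  int win_start = duration_steps - (int)std::floor(duration_steps * apop_window) + 1;
  int n_sweeps = 0;
  for (int s = win_start; s <= duration_steps; ++s)
    if (s % apop_interval == 0) ++n_sweeps;
  int apop_killed = apop_killed_in;

  const int NC = 11;
  NumericMatrix counts(nsteps, NC);
  CharacterVector cn = CharacterVector::create(
      "n_occupied", "n_receivers", "filopodia", "deposits", "insertions",
      "insertions_skipped", "migrations", "decay_events", "decay_applied",
      "decay_amount", "apoptosis");
  colnames(counts) = cn;

  double tot_dep = 0, tot_ins_copied = 0, tot_apop_removed = 0,
         tot_apop_copied = 0, tot_dec = 0;
  std::vector<int> apop_step_log;
  std::vector<int> lin_child, lin_parent;  // donor lineage of copied cells
  List snapshots;
  int snap_ptr = 0;
  while (snap_ptr < snap_steps.size() && snap_steps[snap_ptr] <= t_offset)
    ++snap_ptr;

  std::vector<char> recv_mask(n);

  for (int k = 0; k < nsteps; ++k) {
    int s_abs = t_offset + k + 1;
    int n_occ = 0, n_recv = 0;
    for (int i = 0; i < n; ++i)
      if (occ[i]) { ++n_occ; if (!prod[i]) ++n_recv; }
    counts(k, 0) = n_occ;
    counts(k, 1) = n_recv;

    // -- production ---------------------------------------------------------
    if (mode == 0) {
      for (int i = 0; i < n; ++i) {
        if (!occ[i] || !prod[i]) continue;
        if (unif_rand() < p_fil) {
          counts(k, 2) += 1;
          double len = sample_dist(len_d);
          double ang = sample_dist(ang_d) * M_PI / 180.0;
          double tx = xy(i, 0) + len * std::cos(ang);
          double ty = xy(i, 1) + len * std::sin(ang);
          int tgt = deposit_target(xy, occ, prod, tx, ty, radius, tol);
          if (tgt >= 0) {
            content[tgt] += deposit;
            counts(k, 3) += 1;
            tot_dep += deposit;
          }
        }
      }
    } else {
      L = advance_field(field, L, D, kappa, C0, dt, scheme, u_adv, dx_phys, 1);
      for (int i = 0; i < n; ++i) {
        if (!occ[i] || prod[i]) continue;
        content[i] += field_value(field, L, scheme, dx_phys,
                                  xy(i, 0) - producer_edge);
      }
    }

    // -- insertion ----------------------------------------------------------
    for (int i = 0; i < n; ++i) {
      if (!occ[i] || prod[i]) continue;
      if (unif_rand() >= p_ins) continue;
      int target = -1;
      double bd = R_PosInf;
      for (int j = 0; j < n; ++j) {
        if (occ[j]) continue;
        double d = sqdist(xy(i, 0), xy(i, 1), xy(j, 0), xy(j, 1));
        if (d < bd) { bd = d; target = j; }
      }
      if (target < 0) { counts(k, 5) += 1; continue; }
      std::vector<int> path = path_via_occupied(xy, nbor, occ, i, target);
      for (int m = (int)path.size() - 1; m >= 1; --m) {
        int to = path[m], from = path[m - 1];
        occ[to] = 1;
        content[to] = content[from];
        fate[to] = fate[from];
        cid[to] = cid[from];
      }
      occ[i] = 0;  // vacated origin
      int donor = pick_donor(xy, occ, prod, xy(i, 0), donor_band, i);
      occ[i] = 1;
      if (donor >= 0) {
        content[i] = content[donor];
        fate[i] = fate[donor];
        tot_ins_copied += content[donor];
        lin_child.push_back(next_id);
        lin_parent.push_back(cid[donor]);
      } else {
        content[i] = 0.0;
        fate[i] = 0;
      }
      cid[i] = next_id++;
      counts(k, 4) += 1;
    }

    // -- migration ----------------------------------------------------------
    for (int i = 0; i < n; ++i) recv_mask[i] = (occ[i] && !prod[i]) ? 1 : 0;
    for (int i = 0; i < n; ++i) {
      if (!recv_mask[i]) continue;
      std::vector<int> nb = knn_masked(xy, nbor, recv_mask, i, 5);
      if (nb.empty()) continue;
      int j = nb[std::min((int)(unif_rand() * nb.size()), (int)nb.size() - 1)];
      double dc = content[i] - content[j];
      double sg = 0.0;
      if (dc > 0) sg = (xy(j, 0) < xy(i, 0)) ? 1.0 : -1.0;
      else if (dc < 0) sg = (xy(j, 0) > xy(i, 0)) ? 1.0 : -1.0;
      double adc = std::fabs(dc);
      double p = p_mig + p_dirmig * sg * adc / (adc + dirmig_scale);
      if (p < 0) p = 0;
      if (p > 1) p = 1;
      if (unif_rand() < p) {
        std::swap(content[i], content[j]);
        std::swap(fate[i], fate[j]);
        std::swap(cid[i], cid[j]);
        counts(k, 6) += 1;
      }
    }

    // -- decay --------------------------------------------------------------
    for (int i = 0; i < n; ++i) {
      if (!occ[i] || prod[i]) continue;
      if (unif_rand() < p_decay) {
        counts(k, 7) += 1;
        if (content[i] > 0) {
          double amt = std::min(1.0, content[i]);
          content[i] -= amt;
          if (content[i] < 0) content[i] = 0;
          counts(k, 8) += 1;
          counts(k, 9) += amt;
          tot_dec += amt;
        }
      }
    }

    // -- apoptosis ----------------------------------------------------------
    if (apop_on && n_sweeps > 0 && s_abs >= win_start &&
        s_abs % apop_interval == 0) {
      int sweep_idx = 0;
      for (int s = win_start; s <= s_abs; ++s)
        if (s % apop_interval == 0) ++sweep_idx;
      int target_cum = (int)std::lround((double)apop_budget * sweep_idx / n_sweeps);
      if (target_cum > apop_budget) target_cum = apop_budget;
      int kkill = target_cum - apop_killed;
      if (kkill > 0) {
        for (int i = 0; i < n; ++i) recv_mask[i] = (occ[i] && !prod[i]) ? 1 : 0;
        std::vector<std::pair<double, int> > disc;
        for (int i = 0; i < n; ++i) {
          if (!recv_mask[i]) continue;
          std::vector<int> nb = knn_masked(xy, nbor, recv_mask, i, 5);
          if (nb.empty()) continue;
          double mean = 0;
          for (size_t j = 0; j < nb.size(); ++j) mean += content[nb[j]];
          mean /= nb.size();
          double d = std::fabs(content[i] - mean);
          if (disc_relative) d /= content[i] + mean + 1.0;
          if (d > disc_floor)
            disc.push_back(std::make_pair(-d, i));  // sort: largest d, then index
        }
        std::sort(disc.begin(), disc.end());
        int nv = std::min((int)disc.size(), kkill);
        for (int v = 0; v < nv; ++v) {
          int victim = disc[v].second;
          tot_apop_removed += content[victim];
          occ[victim] = 0;
          int donor = pick_donor(xy, occ, prod, xy(victim, 0), donor_band, victim);
          occ[victim] = 1;
          if (donor >= 0) {
            content[victim] = content[donor];
            fate[victim] = fate[donor];
            tot_apop_copied += content[donor];
            lin_child.push_back(next_id);
            lin_parent.push_back(cid[donor]);
          } else {
            content[victim] = 0.0;
            fate[victim] = 0;
          }
          cid[victim] = next_id++;
          counts(k, 10) += 1;
          apop_step_log.push_back(s_abs);
          ++apop_killed;
        }
      }
    }

    // -- snapshot -----------------------------------------------------------
    if (snap_ptr < snap_steps.size() && snap_steps[snap_ptr] == s_abs) {
      while (snap_ptr < snap_steps.size() && snap_steps[snap_ptr] == s_abs)
        ++snap_ptr;
      int nk = 0;
      for (int i = 0; i < n; ++i) if (occ[i]) ++nk;
      IntegerVector ss(nk), sc(nk), sf(nk);
      NumericVector sv(nk);
      LogicalVector sp(nk);
      int c2 = 0;
      for (int i = 0; i < n; ++i) {
        if (!occ[i]) continue;
        ss[c2] = i + 1;
        sc[c2] = cid[i];
        sv[c2] = content[i];
        sf[c2] = fate[i];
        sp[c2] = prod[i] != 0;
        ++c2;
      }
      List snap = List::create(
          _["time"] = s_abs * dt, _["site"] = ss, _["cell_id"] = sc,
          _["producer"] = sp, _["content"] = sv, _["fate"] = sf);
      if (mode == 1) {
        snap["field"] = wrap(field);
        snap["L"] = L;
      }
      snapshots.push_back(snap);
    }
  }

  LogicalVector occ_out(n);
  NumericVector content_out(n);
  IntegerVector fate_out(n), cid_out(n);
  for (int i = 0; i < n; ++i) {
    occ_out[i] = occ[i] != 0;
    content_out[i] = content[i];
    fate_out[i] = fate[i];
    cid_out[i] = cid[i];
  }
  return List::create(
      _["occupied"] = occ_out, _["content"] = content_out,
      _["fate"] = fate_out, _["cell_id"] = cid_out, _["next_id"] = next_id,
      _["field"] = wrap(field), _["L"] = L, _["counts"] = counts,
      _["totals"] = NumericVector::create(
          _["deposited"] = tot_dep, _["insert_copied"] = tot_ins_copied,
          _["apoptosis_removed"] = tot_apop_removed,
          _["apoptosis_copied"] = tot_apop_copied,
          _["decayed"] = tot_dec),
      _["apoptosis_steps"] = wrap(apop_step_log),
      _["apoptosis_killed"] = apop_killed,
      _["lineage_child"] = wrap(lin_child),
      _["lineage_parent"] = wrap(lin_parent),
      _["snapshots"] = snapshots);
}
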