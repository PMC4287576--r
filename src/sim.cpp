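#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Clock-driven loop for a recurrent integrate-and-fire network with delta
// synapses.  Weights arrive in source-major compressed form (column j of
// the R-side sparse matrix = outgoing synapses of neuron j), with one
// integer delay (in steps, >= 1) per synapse.  External input is realised
// as per-step Poisson event counts scaled by the PSP efficacies; when the
// feedforward and background efficacies coincide the two processes are
// merged into one draw.  Uses R's RNG, so results are reproducible under
// set.seed() on the calling side.
//
// Step order: refractory bookkeeping -> exact subthreshold propagation ->
// delayed recurrent + external PSPs -> threshold test / reset.  Spikes of
// step t are stamped (t+1)*dt and delivered d steps later.
// [[Rcpp::export]]
List sim_core(int n, IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
              IntegerVector dsteps, bool pif, double decay, double v_rest,
              double v_th, double v_reset, int ref_steps,
              NumericVector lam_ffw, double j_ffw, double lam_bkg,
              double j_bkg, int n_steps, double dt, NumericVector v0,
              IntegerVector rec_ids, int vstat_start) {
  int D = 1;
  for (int e = 0; e < dsteps.size(); ++e)
    if (dsteps[e] + 1 > D) D = dsteps[e] + 1;

  std::vector<double> buf((size_t)D * n, 0.0);
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<int> refr(n, 0);
  std::vector<int> sp_id;
  std::vector<double> sp_t;

  bool combine = (j_ffw == j_bkg);
  std::vector<double> lam_tot(n);
  for (int i = 0; i < n; ++i) lam_tot[i] = lam_ffw[i] + lam_bkg;

  int n_rec = rec_ids.size();
  NumericMatrix vtrace(n_rec > 0 ? n_steps : 0, n_rec);
  NumericVector vsum(n), vcnt(n), shunt(n);

  for (int t = 0; t < n_steps; ++t) {
    size_t slot = (size_t)(t % D) * n;
    for (int i = 0; i < n; ++i) {
      if (refr[i] > 0) {          // clamped; synaptic input shunted
        --refr[i];
        v[i] = v_reset;
        // account the discarded charge (needed to reconstruct the free
        // membrane potential exactly); external events still arrive
        double lost = buf[slot + i];
        if (combine) {
          lost += j_ffw * R::rpois(lam_tot[i]);
        } else {
          if (lam_ffw[i] > 0) lost += j_ffw * R::rpois(lam_ffw[i]);
          if (lam_bkg > 0) lost += j_bkg * R::rpois(lam_bkg);
        }
        if (t >= vstat_start) shunt[i] += lost;
        continue;
      }
      if (!pif) v[i] = v_rest + (v[i] - v_rest) * decay;
      double inp = buf[slot + i];
      if (combine) {
        inp += j_ffw * R::rpois(lam_tot[i]);
      } else {
        if (lam_ffw[i] > 0) inp += j_ffw * R::rpois(lam_ffw[i]);
        if (lam_bkg > 0) inp += j_bkg * R::rpois(lam_bkg);
      }
      v[i] += inp;
      if (ISNAN(v[i])) stop("membrane potential became NaN");
      if (v[i] >= v_th) {
        sp_id.push_back(i + 1);
        sp_t.push_back((t + 1) * dt);
        v[i] = v_reset;
        refr[i] = ref_steps;
        for (int e = Wp[i]; e < Wp[i + 1]; ++e)
          buf[(size_t)((t + dsteps[e]) % D) * n + Wi[e]] += Wx[e];
      } else if (t >= vstat_start) {
        vsum[i] += v[i];
        vcnt[i] += 1.0;
      }
    }
    for (int i = 0; i < n; ++i) buf[slot + i] = 0.0;
    for (int k = 0; k < n_rec; ++k) vtrace(t, k) = v[rec_ids[k]];
  }

  return List::create(_["id"] = wrap(sp_id), _["time"] = wrap(sp_t),
                      _["vtrace"] = vtrace, _["vsum"] = vsum,
                      _["vcnt"] = vcnt, _["shunt"] = shunt,
                      _["v_end"] = NumericVector(v.begin(), v.end()));
}
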