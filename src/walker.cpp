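#include <Rcpp.h>
using namespace Rcpp;

// Single-molecule sliding/hopping walk on a 1D bp lattice.
//
// The walker is released at `start` (site 1, just excised) and walks with
// unbiased +/-1 bp steps. Every step carries a microscopic dissociation
// probability q. A dissociation starts an excursion: with the trap present
// it is captured with probability trap_capture_prob; a surviving excursion
// re-lands with probability p_return at a two-sided geometric displacement
// (mean hop_scale bp, clamped to the chain), otherwise the enzyme escapes
// to bulk. Sliding off either chain end is treated as a dissociative
// excursion from the end position. Arriving at site2 is an encounter:
// excision succeeds with probability E (chemistry treated as instantaneous
// because k_cl >> k_off); a failed encounter continues the walk.
//
// Outcome codes: 0 escape, 1 trap_capture, 2 excision (success), 3 step
// budget exhausted.

// [[Rcpp::export]]
List walk_molecules_cpp(int n, int start, int site2, int chain_len,
                        double q, double p_return, double hop_scale,
                        bool trap_on, double trap_capture_prob, double E,
                        int max_steps, bool record_events) {
  IntegerVector outcome(n), n_hops(n), n_encounters(n), n_steps(n);
  std::vector<int> ev_mol, ev_kind, ev_pos, ev_ord;
  // event kinds: 1 slide, 2 hop, 3 escape, 4 trap_capture, 5 excision
  const double p_geom = 1.0 / hop_scale;

  for (int i = 0; i < n; ++i) {
    int pos = start, hops = 0, enc = 0, steps = 0, out = 3, ord = 0;
    bool done = false;
    while (!done && steps < max_steps) {
      ++steps;
      bool excursion = false;
      if (unif_rand() < q) {
        excursion = true;
      } else {
        pos += (unif_rand() < 0.5) ? -1 : 1;
        if (pos < 0 || pos >= chain_len) {
          pos = (pos < 0) ? 0 : chain_len - 1;
          excursion = true;  // slid off an end
        } else if (record_events) {
          ev_mol.push_back(i + 1); ev_kind.push_back(1);
          ev_pos.push_back(pos); ev_ord.push_back(++ord);
        }
      }
      if (excursion) {
        if (trap_on && unif_rand() < trap_capture_prob) {
          out = 1; done = true;
          if (record_events) {
            ev_mol.push_back(i + 1); ev_kind.push_back(4);
            ev_pos.push_back(pos); ev_ord.push_back(++ord);
          }
        } else if (unif_rand() < p_return) {
          int mag = 1 + (int) R::rgeom(p_geom);
          int newpos = pos + ((unif_rand() < 0.5) ? -mag : mag);
          if (newpos < 0) newpos = 0;
          if (newpos >= chain_len) newpos = chain_len - 1;
          pos = newpos;
          ++hops;
          if (record_events) {
            ev_mol.push_back(i + 1); ev_kind.push_back(2);
            ev_pos.push_back(pos); ev_ord.push_back(++ord);
          }
        } else {
          out = 0; done = true;
          if (record_events) {
            ev_mol.push_back(i + 1); ev_kind.push_back(3);
            ev_pos.push_back(pos); ev_ord.push_back(++ord);
          }
        }
      }
      if (!done && pos == site2) {
        ++enc;
        if (unif_rand() < E) {
          out = 2; done = true;
          if (record_events) {
            ev_mol.push_back(i + 1); ev_kind.push_back(5);
            ev_pos.push_back(pos); ev_ord.push_back(++ord);
          }
        }
      }
    }
    outcome[i] = out; n_hops[i] = hops; n_encounters[i] = enc; n_steps[i] = steps;
  }

  List res = List::create(_["outcome"] = outcome, _["n_hops"] = n_hops,
                          _["n_encounters"] = n_encounters,
                          _["n_steps"] = n_steps);
  if (record_events) {
    res["events"] = DataFrame::create(
      _["molecule"] = wrap(ev_mol), _["kind"] = wrap(ev_kind),
      _["pos_bp"] = wrap(ev_pos), _["ordinal"] = wrap(ev_ord));
  }
  return res;
}
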