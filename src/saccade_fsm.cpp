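#include <Rcpp.h>
using namespace Rcpp;

// Four-step saccade recognition state machine over the derived DC/AC EOG
// traces, with continuous front-gaze baseline renewal.
//
// States: 0 idle, 1 onset (DC and AC beyond threshold, event emitted),
// 2 hold (DC beyond threshold, AC back at baseline), 3 return (opposite AC
// excursion while gaze returns to center). On completion the DC baseline is
// updated and a refractory period suppresses double-triggering.
//
// Labels: 0 = right, 1 = left, 2 = vertical (gated out, no command).

// [[Rcpp::export]]
List saccade_fsm_cpp(NumericVector h_dc, NumericVector h_ac,
                     NumericVector v_dc, NumericVector v_ac,
                     LogicalVector emg_active,
                     double fs,
                     double dc_thr, double ac_thr,
                     double dc_band, double ac_band,
                     double quiet_window, double refractory,
                     double h_ref0, double v_ref0,
                     bool refs_valid0,
                     bool return_trace) {
  const int n = h_dc.size();
  if (h_ac.size() != n || v_dc.size() != n || v_ac.size() != n ||
      emg_active.size() != n) {
    stop("All traces must have equal length.");
  }
  const int quiet_n = (int)std::ceil(quiet_window * fs);
  const int refrac_n = (int)std::ceil(refractory * fs);

  double h_ref = h_ref0, v_ref = v_ref0;
  bool refs_valid = refs_valid0;
  int state = 0;          // 0 idle, 1 onset, 2 hold, 3 return
  int quiet_run = 0;
  int refrac_until = -1;
  int last_renewal = -1;

  int cur_label = -1;     // 0 right, 1 left, 2 vertical
  int cur_dir = 0;        // sign of the tracked DC excursion
  bool cur_vertical = false;
  int cur_onset = -1;
  double cur_peak = 0.0;

  std::vector<int> ev_label;
  std::vector<int> ev_onset, ev_offset;
  std::vector<double> ev_peak;
  std::vector<int> ev_open;   // index into event vectors of the open event

  IntegerVector trace(return_trace ? n : 0);

  for (int i = 0; i < n; ++i) {
    const bool emg = emg_active[i];
    const bool ac_quiet = std::fabs(h_ac[i]) < ac_band &&
                          std::fabs(v_ac[i]) < ac_band;

    if (emg) {
      quiet_run = 0;
      refs_valid = false;         // references re-initialized after activity
      if (state != 0) {
        // close any event in flight at the mask boundary
        if (!ev_open.empty()) {
          ev_offset[ev_open.back()] = i;
          ev_open.pop_back();
        }
        state = 0;
      }
      if (return_trace) trace[i] = -1;
      continue;
    }

    quiet_run = ac_quiet ? quiet_run + 1 : 0;

    if (state == 0 && quiet_run >= quiet_n) {
      h_ref = h_dc[i];
      v_ref = v_dc[i];
      refs_valid = true;
      last_renewal = i;
    }

    const double dh = h_dc[i] - h_ref;
    const double dv = v_dc[i] - v_ref;

    const double tdc = cur_vertical ? dv : dh;
    const double tac = cur_vertical ? v_ac[i] : h_ac[i];

    switch (state) {
    case 0: {
      if (!refs_valid || i <= refrac_until) break;
      const bool trig_h = std::fabs(dh) > dc_thr &&
                          std::fabs(h_ac[i]) > ac_thr &&
                          ((dh > 0) == (h_ac[i] > 0));
      const bool trig_v = std::fabs(dv) > dc_thr &&
                          std::fabs(v_ac[i]) > ac_thr &&
                          ((dv > 0) == (v_ac[i] > 0));
      if (trig_h || trig_v) {
        // vertical gate: compare the changing ranges of the two components
        cur_vertical = !(trig_h && std::fabs(dh) > std::fabs(dv));
        if (cur_vertical) {
          cur_label = 2;
          cur_dir = dv >= 0 ? 1 : -1;
          cur_peak = std::fabs(dv);
        } else {
          cur_dir = dh > 0 ? 1 : -1;
          cur_label = cur_dir > 0 ? 0 : 1;
          cur_peak = std::fabs(dh);
        }
        cur_onset = i;
        state = 1;
        // step 1: direction determined, event emitted
        ev_label.push_back(cur_label);
        ev_onset.push_back(i);
        ev_offset.push_back(n - 1);
        ev_peak.push_back(cur_peak);
        ev_open.push_back((int)ev_label.size() - 1);
      }
      break;
    }
    case 1: { // onset: wait for the AC transient to settle
      if (std::fabs(tdc) > cur_peak) cur_peak = std::fabs(tdc);
      if (cur_dir * tac < -ac_thr) { state = 3; break; }
      if (std::fabs(tac) < ac_band) state = 2;
      break;
    }
    case 2: { // hold: gaze stays off-center until an opposite AC excursion
      if (std::fabs(tdc) > cur_peak) cur_peak = std::fabs(tdc);
      if (cur_dir * tac < -ac_thr) { state = 3; break; }
      // fallback: slow return without a detected opposite transient
      if (std::fabs(tdc) < dc_band && std::fabs(tac) < ac_band) state = 3;
      break;
    }
    case 3: { // return: both elements back within their baseline bands
      if (std::fabs(tdc) < dc_band && std::fabs(tac) < ac_band) {
        h_ref = h_dc[i];          // step 4: baseline update
        v_ref = v_dc[i];
        refs_valid = true;
        last_renewal = i;
        refrac_until = i + refrac_n;
        if (!ev_open.empty()) {
          int k = ev_open.back();
          ev_offset[k] = i;
          ev_peak[k] = cur_peak;
          ev_open.pop_back();
        }
        state = 0;
      }
      break;
    }
    }

    if (return_trace) trace[i] = state;
  }

  return List::create(
    _["label"] = wrap(ev_label),
    _["onset"] = wrap(ev_onset),
    _["offset"] = wrap(ev_offset),
    _["peak"] = wrap(ev_peak),
    _["h_ref"] = h_ref,
    _["v_ref"] = v_ref,
    _["refs_valid"] = refs_valid,
    _["last_renewal"] = last_renewal,
    _["trace"] = trace
  );
}
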