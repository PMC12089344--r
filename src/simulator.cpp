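#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event-driven simulation of one S phase on a single chromosome.
//
// Origins fire at the pre-sampled times in `firing_times` (Exp(f_j) draws,
// possibly astronomically large for floor-rate sites). A firing origin
// spawns a left- and a right-moving fork. Fork motion:
//   erlang  - each 1-kb step takes an independent Exp(v) time, so a k-site
//             traversal is Erlang(k, v) with mean k/v (the process-algebra
//             semantics);
//   deterministic - arrival at distance d from the origin is exactly
//             firing_time + d/v, the same floating-point expression the
//             min-formula oracle uses, so the two agree exactly.
// An origin whose site is passively replicated before its sampled firing
// time never fires; at a floating-point tie between a fork arrival and a
// site's own firing, the fork wins. A fork dies when it steps onto an
// already-replicated site (fork merging) or runs off the chromosome.
//
// Labels: 0 = origin, 1 = left_fork (replicated by a left-moving fork,
// origin to the right), 2 = right_fork.
struct Event {
  double time;
  int site;
  int type;        // 0 = fork arrival, 1 = origin firing
  int dir;         // -1 / +1 for forks
  int origin_site;
  double origin_time;
  int fork_id;
};

struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.time != b.time) return a.time > b.time;
    return a.type > b.type;  // fork (0) beats origin (1) at equal time
  }
};

// [[Rcpp::export]]
List cpp_simulate_once(NumericVector firing_times, double v, bool erlang) {
  const int n = firing_times.size();
  std::priority_queue<Event, std::vector<Event>, EventCmp> q;
  for (int j = 0; j < n; ++j) {
    if (R_finite(firing_times[j]))
      q.push({firing_times[j], j, 1, 0, j, firing_times[j], -1});
  }
  NumericVector rep_time(n, NA_REAL);
  IntegerVector label(n, NA_INTEGER);
  IntegerVector by_origin(n, NA_INTEGER);
  std::vector<char> done(n, 0);
  std::vector<double> fork_birth, fork_death;
  const double scale = 1.0 / v;  // R::rexp takes the scale (mean)
  int replicated = 0;

  while (!q.empty() && replicated < n) {
    Event e = q.top();
    q.pop();
    if (e.type == 1) {
      if (done[e.site]) continue;  // passively replicated; ORI retired
      done[e.site] = 1;
      ++replicated;
      rep_time[e.site] = e.time;
      label[e.site] = 0;
      by_origin[e.site] = e.site;
      for (int dir = -1; dir <= 1; dir += 2) {
        int nxt = e.site + dir;
        if (nxt < 0 || nxt >= n) continue;
        int fid = (int)fork_birth.size();
        fork_birth.push_back(e.time);
        fork_death.push_back(e.time);
        double t = erlang ? e.time + R::rexp(scale)
                          : e.origin_time + std::abs(nxt - e.site) / v;
        q.push({t, nxt, 0, dir, e.site, e.origin_time, fid});
      }
    } else {
      fork_death[e.fork_id] = e.time;
      if (done[e.site]) continue;  // merged into an oncoming fork
      done[e.site] = 1;
      ++replicated;
      rep_time[e.site] = e.time;
      label[e.site] = (e.dir > 0) ? 2 : 1;
      by_origin[e.site] = e.origin_site;
      int nxt = e.site + e.dir;
      if (nxt >= 0 && nxt < n) {
        double t = erlang ? e.time + R::rexp(scale)
                          : e.origin_time + std::abs(nxt - e.origin_site) / v;
        q.push({t, nxt, 0, e.dir, e.origin_site, e.origin_time, e.fork_id});
      }
    }
  }

  return List::create(
    _["time"] = rep_time,
    _["label"] = label,
    _["by_origin"] = by_origin,
    _["fork_birth"] = NumericVector(fork_birth.begin(), fork_birth.end()),
    _["fork_death"] = NumericVector(fork_death.begin(), fork_death.end()));
}
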