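#include <Rcpp.h>
using namespace Rcpp;

// Minute-resolution feeding within one day for a single vessel.
//
// carbon0    total food carbon in the vessel at day start [ug C]
// area       vessel bottom area [cm^2]
// n_stage    number of living feeders per stage (nauplius, copepodite, adult)
// a_max, k   Holling type-III coefficients per stage (same order)
//
// Every minute the per-capita ingestion rate is re-evaluated from the
// current bottom concentration; 1/1440 of the daily rate is consumed.
// If the aggregate demand of a minute exceeds the remaining food, the
// allocation is scaled proportionally and the pool floors at exactly 0.
//
// Returns per-capita daily intake per stage [ug C] and the final carbon.
// [[Rcpp::export(name = ".minuteLoopCpp")]]
List minute_loop_cpp(double carbon0, double area,
                     IntegerVector n_stage,
                     NumericVector a_max, NumericVector k,
                     int minutes = 1440) {
  const int S = n_stage.size();
  if (a_max.size() != S || k.size() != S)
    stop("stage coefficient vectors must match n_stage");
  if (carbon0 < 0) stop("carbon must be non-negative");
  if (area <= 0) stop("bottom area must be positive");

  std::vector<double> intake(S, 0.0);   // per-capita cumulative intake
  double carbon = carbon0;
  double consumed = 0.0;                // running total, for exact balance

  for (int m = 0; m < minutes; m++) {
    if (carbon <= 0.0) break;
    double conc = carbon / area;
    double c2 = conc * conc;
    double demand = 0.0;
    std::vector<double> rate(S);
    for (int s = 0; s < S; s++) {
      rate[s] = (a_max[s] * c2 / (c2 + k[s] * k[s])) / minutes;
      demand += rate[s] * n_stage[s];
    }
    if (demand <= 0.0) continue;
    double scale = 1.0;
    if (demand >= carbon) {        // pool exhausted this minute
      scale = carbon / demand;
      consumed += carbon;
      carbon = 0.0;
    } else {
      consumed += demand;
      carbon -= demand;
    }
    for (int s = 0; s < S; s++) intake[s] += rate[s] * scale;
  }

  return List::create(_["intake"] = NumericVector(intake.begin(), intake.end()),
                      _["carbon"] = carbon,
                      _["consumed"] = consumed);
}
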