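#include <Rcpp.h>
using namespace Rcpp;

// Patient-level monthly state-transition engine.
//
// States: 0..3 community NYHA classes I..IV, 4 index hospitalization,
// 5 readmission, 6 dead (absorbing). Each cycle the patient accrues the
// cost and utility of the state occupied during that cycle (no half-cycle
// correction), then transitions: death first, then discharge, then
// (re)admission, then NYHA class movement. A hospitalization occupies one
// full cycle; the per-admission cost is charged in that cycle. Three
// uniform draws are consumed per patient-cycle regardless of use, so the
// two arms (and an R reference implementation) can share one draw stream
// (common random numbers).
//
// draws is an n x 3 x T array in column-major order: (i, k, t) at
// i + n*k + 3*n*t.
//
// Returns an n x 4 matrix: discounted cost, discounted QALY, life months,
// admissions.
// [[Rcpp::export]]
NumericMatrix engine_run(IntegerVector init_class,      // 1..4 per patient
                         NumericVector p_death_comm,    // per patient
                         NumericVector p_death_hosp,    // per patient
                         NumericVector admit_prob,      // per class (4)
                         double readmit_prob,
                         NumericMatrix trans_cum,       // 4x4 cumulative rows
                         NumericVector cost_nondrug,    // per class (4)
                         NumericVector cost_drug,       // per class (4)
                         NumericVector age0,            // per patient
                         double drug_age_threshold,
                         NumericVector utility,         // per class (4)
                         double hosp_disutility,
                         double admission_cost,
                         NumericVector program_monthly, // per patient
                         double program_entry_cost,
                         NumericVector discount,        // per cycle (T)
                         double readmit_window,         // cycles; may be Inf
                         NumericVector draws) {
  const int n = init_class.size();
  const int T = discount.size();
  if (draws.size() < (R_xlen_t)3 * n * T) stop("draw stream exhausted");

  NumericMatrix out(n, 4);
  colnames(out) = CharacterVector::create("cost", "qaly", "life_months",
                                          "admissions");

  for (int i = 0; i < n; ++i) {
    int cur = init_class[i] - 1;  // 0..3 community, 4 index, 5 readmit
    int resident = cur;
    double msd = -1.0;            // months since discharge; -1 = never
    double cost = program_entry_cost;
    double qaly = 0.0;
    int life = 0, admissions = 0;

    for (int t = 0; t < T; ++t) {
      const int cls = (cur <= 3) ? cur : resident;
      double c = cost_nondrug[cls] + program_monthly[i];
      if (age0[i] + t / 12.0 >= drug_age_threshold) c += cost_drug[cls];
      double u = utility[cls];
      if (cur >= 4) {
        c += admission_cost;
        u -= hosp_disutility;
      }
      cost += discount[t] * c;
      qaly += discount[t] * u / 12.0;
      ++life;

      const double u1 = draws[i + n * (0 + 3 * t)];
      const double u2 = draws[i + n * (1 + 3 * t)];
      const double u3 = draws[i + n * (2 + 3 * t)];

      if (cur >= 4) {                       // hospital cycle
        if (u1 < p_death_hosp[i]) break;    // died in hospital
        cur = resident;                     // discharge
        msd = 0.0;
      } else {                              // community cycle
        if (u1 < p_death_comm[i]) break;    // died in community
        const bool elevated = (msd >= 0.0) && (msd < readmit_window);
        const double pa = elevated ? readmit_prob : admit_prob[cls];
        if (u2 < pa) {                      // (re)admission next cycle
          resident = cls;
          cur = elevated ? 5 : 4;
          ++admissions;
        } else {                            // NYHA transition
          int next = 3;
          for (int j = 0; j < 4; ++j) {
            if (u3 < trans_cum(cls, j)) { next = j; break; }
          }
          cur = next;
          if (msd >= 0.0) msd += 1.0;
        }
      }
    }

    out(i, 0) = cost;
    out(i, 1) = qaly;
    out(i, 2) = life;
    out(i, 3) = admissions;
  }
  return out;
}
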