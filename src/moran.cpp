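#include <Rcpp.h>
using namespace Rcpp;

// Agent-based mutation-selection process in a well-mixed population.
// Per update: pick a random individual X; with probability mu replace its
// strategy uniformly at random from the full set; otherwise pick a random
// role model Y != X and imitate with the Fermi probability
// 1/(1+exp(-beta (fY - fX))), where fitness is the average payoff against
// the other Z-1 individuals given the current strategy counts.
// Uses R's RNG so runs are reproducible under set.seed().

static inline double comp_fitness(const NumericMatrix& pay,
                                  const IntegerVector& counts,
                                  int s, int Z) {
  double acc = 0.0;
  int n = counts.size();
  for (int j = 0; j < n; ++j)
    if (counts[j] > 0) acc += counts[j] * pay(s, j);
  acc -= pay(s, s); // exclude self
  return acc / (Z - 1);
}

// [[Rcpp::export(name = ".moran_run")]]
List moran_run(NumericMatrix pay, int Z, double mu, double beta,
               double steps, double burn_in, int record_every,
               bool keep_trajectory) {
  int nS = pay.nrow();
  if (pay.ncol() != nS) stop("payoff matrix must be square");
  if (Z < 2) stop("Z must be at least 2");
  if (record_every < 1) record_every = 1;

  RNGScope scope;

  // initial population: uniform random strategies
  IntegerVector strat(Z);
  IntegerVector counts(nS);
  for (int i = 0; i < Z; ++i) {
    int s = (int)(unif_rand() * nS);
    if (s >= nS) s = nS - 1;
    strat[i] = s;
    counts[s]++;
  }

  long long n_steps = (long long)steps;
  long long n_burn = (long long)burn_in;
  NumericVector freq_acc(nS);
  long long n_rec = 0, n_mono = 0;

  long long traj_rows = 0;
  if (keep_trajectory && n_steps > n_burn)
    traj_rows = n_steps / record_every - n_burn / record_every;
  NumericMatrix traj(keep_trajectory ? traj_rows : 0, keep_trajectory ? nS : 0);
  IntegerVector traj_gen(keep_trajectory ? traj_rows : 0);
  long long traj_i = 0;

  for (long long step = 1; step <= n_steps; ++step) {
    int x = (int)(unif_rand() * Z); if (x >= Z) x = Z - 1;
    if (unif_rand() < mu) {
      int s = (int)(unif_rand() * nS); if (s >= nS) s = nS - 1;
      counts[strat[x]]--; counts[s]++; strat[x] = s;
    } else {
      int y = (int)(unif_rand() * (Z - 1)); if (y >= Z - 1) y = Z - 2;
      if (y >= x) y++;
      int sx = strat[x], sy = strat[y];
      if (sx != sy) {
        double fx = comp_fitness(pay, counts, sx, Z);
        double fy = comp_fitness(pay, counts, sy, Z);
        double p = 1.0 / (1.0 + exp(-beta * (fy - fx)));
        if (unif_rand() < p) {
          counts[sx]--; counts[sy]++; strat[x] = sy;
        }
      }
    }
    if (step > n_burn && (step % record_every) == 0) {
      n_rec++;
      bool mono = false;
      for (int s = 0; s < nS; ++s) {
        freq_acc[s] += (double)counts[s] / Z;
        if (counts[s] == Z) mono = true;
      }
      if (mono) n_mono++;
      if (keep_trajectory && traj_i < traj_rows) {
        for (int s = 0; s < nS; ++s) traj(traj_i, s) = (double)counts[s] / Z;
        traj_gen[traj_i] = (int)(step / record_every);
        traj_i++;
      }
    }
  }

  if (n_rec > 0)
    for (int s = 0; s < nS; ++s) freq_acc[s] /= n_rec;

  List out = List::create(
    _["frequencies"] = freq_acc,
    _["n_recorded"] = (double)n_rec,
    _["monomorphic_fraction"] = n_rec > 0 ? (double)n_mono / n_rec : NA_REAL,
    _["final_counts"] = counts);
  if (keep_trajectory) {
    out["trajectory"] = traj;
    out["generation"] = traj_gen;
  }
  return out;
}
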