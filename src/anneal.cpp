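#include <Rcpp.h>
using namespace Rcpp;

// Simulated-annealing maximisation of weighted bipartite modularity.
//
// B is the modularity matrix a_ij/F - r_i c_j / F^2 (n plants x m ants).
// Q(partition) = sum of B(i,j) over plant-ant pairs sharing a module.
// Moves: reassign one species to another (or a fresh) module, merge two
// modules, split one module at random. Geometric cooling; the best
// partition ever visited is returned. Uses R's RNG so results are
// reproducible under set.seed().

static double pair_sum(const NumericMatrix& B,
                       const IntegerVector& mp, const IntegerVector& ma,
                       int modp, int moda) {
  // sum of B(i,j) over plants in module modp and ants in module moda
  double s = 0.0;
  const int n = mp.size(), m = ma.size();
  for (int i = 0; i < n; ++i) {
    if (mp[i] != modp) continue;
    for (int j = 0; j < m; ++j) {
      if (ma[j] == moda) s += B(i, j);
    }
  }
  return s;
}

static double full_Q(const NumericMatrix& B,
                     const IntegerVector& mp, const IntegerVector& ma) {
  double q = 0.0;
  for (int i = 0; i < mp.size(); ++i)
    for (int j = 0; j < ma.size(); ++j)
      if (mp[i] == ma[j]) q += B(i, j);
  return q;
}

// [[Rcpp::export]]
List anneal_modules_cpp(NumericMatrix B, double t0, double cooling,
                        int patience, int max_steps) {
  const int n = B.nrow(), m = B.ncol(), S = n + m;
  IntegerVector mp(n), ma(m);
  for (int i = 0; i < n; ++i) mp[i] = i;           // every species its own
  for (int j = 0; j < m; ++j) ma[j] = n + j;       // module initially
  int next_label = S;

  double Qcur = full_Q(B, mp, ma);                 // 0 at the start
  IntegerVector best_mp = clone(mp), best_ma = clone(ma);
  double Qbest = Qcur;

  double T = t0;
  int since_improve = 0, step = 0;

  while (since_improve < patience && step < max_steps) {
    ++step;
    double u = unif_rand();
    double delta = 0.0;
    bool valid = false;

    if (u < 0.70) {
      // reassign one species to a random other module (possibly fresh)
      int sp = (int)(unif_rand() * S); if (sp >= S) sp = S - 1;
      bool is_plant = sp < n;
      int cur = is_plant ? mp[sp] : ma[sp - n];
      // candidate target: module of a random species, or a fresh label
      int target;
      if (unif_rand() < 0.10) {
        target = next_label;
      } else {
        int other = (int)(unif_rand() * S); if (other >= S) other = S - 1;
        target = other < n ? mp[other] : ma[other - n];
      }
      if (target != cur) {
        if (is_plant) {
          double gain = 0.0, loss = 0.0;
          for (int j = 0; j < m; ++j) {
            if (ma[j] == target) gain += B(sp, j);
            else if (ma[j] == cur) loss += B(sp, j);
          }
          delta = gain - loss;
        } else {
          int j = sp - n;
          double gain = 0.0, loss = 0.0;
          for (int i = 0; i < n; ++i) {
            if (mp[i] == target) gain += B(i, j);
            else if (mp[i] == cur) loss += B(i, j);
          }
          delta = gain - loss;
        }
        bool accept = delta > 0.0 ||
          (T > 0.0 && unif_rand() < std::exp(delta / T));
        if (accept) {
          if (is_plant) mp[sp] = target; else ma[sp - n] = target;
          if (target == next_label) ++next_label;
          valid = true;
        }
      }
    } else if (u < 0.85) {
      // merge the modules of two random species
      int s1 = (int)(unif_rand() * S); if (s1 >= S) s1 = S - 1;
      int s2 = (int)(unif_rand() * S); if (s2 >= S) s2 = S - 1;
      int x = s1 < n ? mp[s1] : ma[s1 - n];
      int y = s2 < n ? mp[s2] : ma[s2 - n];
      if (x != y) {
        delta = pair_sum(B, mp, ma, x, y) + pair_sum(B, mp, ma, y, x);
        bool accept = delta > 0.0 ||
          (T > 0.0 && unif_rand() < std::exp(delta / T));
        if (accept) {
          for (int i = 0; i < n; ++i) if (mp[i] == y) mp[i] = x;
          for (int j = 0; j < m; ++j) if (ma[j] == y) ma[j] = x;
          valid = true;
        }
      }
    } else {
      // split the module of a random species by a random bipartition
      int sp = (int)(unif_rand() * S); if (sp >= S) sp = S - 1;
      int x = sp < n ? mp[sp] : ma[sp - n];
      std::vector<int> pl, an;
      for (int i = 0; i < n; ++i) if (mp[i] == x) pl.push_back(i);
      for (int j = 0; j < m; ++j) if (ma[j] == x) an.push_back(j);
      if (pl.size() + an.size() >= 2) {
        std::vector<bool> pl_move(pl.size()), an_move(an.size());
        int moved = 0;
        for (size_t k = 0; k < pl.size(); ++k) {
          pl_move[k] = unif_rand() < 0.5;
          if (pl_move[k]) ++moved;
        }
        for (size_t k = 0; k < an.size(); ++k) {
          an_move[k] = unif_rand() < 0.5;
          if (an_move[k]) ++moved;
        }
        if (moved > 0 && moved < (int)(pl.size() + an.size())) {
          // links broken between stayers and movers
          double cut = 0.0;
          for (size_t a = 0; a < pl.size(); ++a)
            for (size_t b = 0; b < an.size(); ++b)
              if (pl_move[a] != an_move[b]) cut += B(pl[a], an[b]);
          delta = -cut;
          bool accept = delta > 0.0 ||
            (T > 0.0 && unif_rand() < std::exp(delta / T));
          if (accept) {
            int fresh = next_label++;
            for (size_t k = 0; k < pl.size(); ++k)
              if (pl_move[k]) mp[pl[k]] = fresh;
            for (size_t k = 0; k < an.size(); ++k)
              if (an_move[k]) ma[an[k]] = fresh;
            valid = true;
          }
        }
      }
    }

    if (valid) Qcur += delta;
    if (Qcur > Qbest + 1e-12) {
      Qbest = Qcur;
      best_mp = clone(mp);
      best_ma = clone(ma);
      since_improve = 0;
    } else {
      ++since_improve;
    }
    T *= cooling;
    if (T < 1e-12) T = 0.0;
  }

  return List::create(_["mp"] = best_mp, _["ma"] = best_ma,
                      _["Q"] = Qbest, _["steps"] = step);
}
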