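#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Random-swap lattice-gas mixing in a closed cubic container.
// One iteration = one raster-order sweep over all voxels; each focal voxel
// swaps with a uniformly chosen in-bounds neighbor among its 26 Moore
// neighbors (the closed walls truncate the neighborhood; uniformity among
// the surviving neighbors is kept by rejection).
// [[Rcpp::export]]
List cpp_simulate_mixing(int edge, int iterations, int seed, int export_every) {
  const int E = edge;
  const long n = (long)E * E * E;
  std::vector<int8_t> f(n);
  // left half (first axis, x) = 1, right half = 0
  for (int z = 0; z < E; ++z)
    for (int y = 0; y < E; ++y)
      for (int x = 0; x < E; ++x)
        f[x + (long)E * (y + (long)E * z)] = (x < E / 2) ? 1 : 0;

  std::mt19937 rng((uint32_t)seed);
  std::uniform_int_distribution<int> pick26(0, 25);

  List snaps;
  IntegerVector iters;
  auto push = [&](int it) {
    IntegerVector s(n);
    for (long i = 0; i < n; ++i) s[i] = f[i];
    s.attr("dim") = IntegerVector::create(E, E, E);
    snaps.push_back(s);
    iters.push_back(it);
  };
  push(0);

  for (int it = 1; it <= iterations; ++it) {
    for (int z = 0; z < E; ++z) {
      for (int y = 0; y < E; ++y) {
        for (int x = 0; x < E; ++x) {
          int dx, dy, dz, nx, ny, nz;
          do {
            int idx = pick26(rng);
            if (idx >= 13) ++idx;  // skip the center
            dx = idx % 3 - 1;
            dy = (idx / 3) % 3 - 1;
            dz = idx / 9 - 1;
            nx = x + dx; ny = y + dy; nz = z + dz;
          } while (nx < 0 || nx >= E || ny < 0 || ny >= E || nz < 0 || nz >= E);
          long a = x + (long)E * (y + (long)E * z);
          long b = nx + (long)E * (ny + (long)E * nz);
          int8_t tmp = f[a]; f[a] = f[b]; f[b] = tmp;
        }
      }
    }
    if (it % export_every == 0 || it == iterations) push(it);
  }
  return List::create(_["snapshots"] = snaps, _["iterations"] = iters);
}

// Metropolis single-spin-flip dynamics for the 2D nearest-neighbor
// ferromagnetic Ising model (J = 1, no external field, periodic
// boundaries), annealed from the lowest temperature upward reusing the
// previous configuration. At T = 0 only energy-decreasing flips are
// accepted. Returns one binary snapshot (spin -1 -> 0, +1 -> 1) per
// temperature, taken after the equilibration sweeps.
// [[Rcpp::export]]
List cpp_simulate_ising(int L, NumericVector temperatures, int sweeps, int seed) {
  const long n = (long)L * L;
  std::vector<int8_t> s(n, 1);  // ordered ferromagnetic start
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  List snaps;
  for (int ti = 0; ti < temperatures.size(); ++ti) {
    double T = temperatures[ti];
    double acc4 = 0.0, acc8 = 0.0;
    bool zeroT = (T <= 0.0);
    if (!zeroT) {
      acc4 = std::exp(-4.0 / T);
      acc8 = std::exp(-8.0 / T);
    }
    for (int sw = 0; sw < sweeps; ++sw) {
      for (int y = 0; y < L; ++y) {
        const int8_t* ru = &s[(long)L * ((y + 1) % L)];
        const int8_t* rd = &s[(long)L * ((y + L - 1) % L)];
        int8_t* rc = &s[(long)L * y];
        for (int x = 0; x < L; ++x) {
          const int xr = (x + 1 == L) ? 0 : x + 1;
          const int xl = (x == 0) ? L - 1 : x - 1;
          const int nn = rc[xr] + rc[xl] + ru[x] + rd[x];
          const int dE = 2 * rc[x] * nn;  // energy change of flipping spin x,y
          bool accept;
          if (zeroT) {
            accept = dE < 0;
          } else if (dE <= 0) {
            accept = true;
          } else {
            const double a = (dE == 4) ? acc4 : acc8;
            accept = unif(rng) < a;
          }
          if (accept) rc[x] = -rc[x];
        }
      }
    }
    IntegerMatrix img(L, L);
    for (int y = 0; y < L; ++y)
      for (int x = 0; x < L; ++x)
        img(x, y) = (s[x + (long)L * y] + 1) / 2;
    snaps.push_back(img);
  }
  return snaps;
}
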