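// Discrete 3D random-walk core: a point virion on the integer lattice
// [0, L-1]^3 with an absorbing sphere of radius R at the cube centre
// ((L-1)/2, ...). Encounter is strict: squared distance < R^2, tested
// after every move. Distances are tracked on a doubled integer grid
// (q = 2*x - (L-1)) so the comparison 4*D^2 < (2R)^2 is exact for
// lattice positions, including half-integer centres at even L.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---- RNG: splitmix64 key derivation + xoshiro256++ stream ----

static inline uint64_t sm64_once(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t rotl(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro {
  uint64_t s[4];
  void seed(uint64_t key) {
    // splitmix64 chain; guarantees a non-zero state
    uint64_t z = key;
    for (int i = 0; i < 4; ++i) { z = sm64_once(z); s[i] = z; }
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // unbiased-enough bounded draw (Lemire, top 32 bits)
  inline uint32_t bounded(uint32_t n) {
    return (uint32_t)(((uint64_t)(uint32_t)(next() >> 32) * n) >> 32);
  }
};

// counter-based per-walk key: independent of execution order, and adding
// runs/radii/repeats never perturbs existing streams
static inline uint64_t walk_key(double master_seed, int run_index,
                                int radius_index, int repeat_index) {
  uint64_t k = sm64_once((uint64_t)(int64_t)master_seed);
  k = sm64_once(k ^ (uint64_t)(uint32_t)run_index);
  k = sm64_once(k ^ (uint64_t)(uint32_t)radius_index);
  k = sm64_once(k ^ (uint64_t)(uint32_t)repeat_index);
  return k;
}

// move deltas: +x,-x,+y,-y,+z,-z
static const int DX[6] = { 1, -1, 0, 0, 0, 0 };
static const int DY[6] = { 0, 0, 1, -1, 0, 0 };
static const int DZ[6] = { 0, 0, 0, 0, 1, -1 };

struct WalkResult {
  double steps;
  bool encounter;
  int x, y, z;
};

// One walk. Coordinates x,y,z in [0,L-1]; doubled coordinates qx = 2x-(L-1)
// carry the exact squared distance d4 = qx^2+qy^2+qz^2 = 4*D^2.
// boundary "stay" policy: draw from all 6 directions, a blocked draw costs
// a step without movement; default "reflect" policy draws uniformly from
// the feasible subset only.
static WalkResult walk_one(int L, double R, int x, int y, int z,
                           double max_steps, Xoshiro &rng, bool stay_policy) {
  const int hi = L - 1;
  const double thr = 4.0 * R * R;      // (2R)^2
  int64_t qx = 2 * (int64_t)x - hi;
  int64_t qy = 2 * (int64_t)y - hi;
  int64_t qz = 2 * (int64_t)z - hi;
  int64_t d4 = qx * qx + qy * qy + qz * qz;
  double steps = 0.0;

  while (steps < max_steps) {
    int dir;
    if (x >= 1 && x <= hi - 1 && y >= 1 && y <= hi - 1 && z >= 1 && z <= hi - 1) {
      dir = (int)rng.bounded(6);        // interior fast path
    } else if (stay_policy) {
      dir = (int)rng.bounded(6);
      int nx = x + DX[dir], ny = y + DY[dir], nz = z + DZ[dir];
      if (nx < 0 || nx > hi || ny < 0 || ny > hi || nz < 0 || nz > hi) {
        steps += 1.0;                   // blocked draw spends the step in place
        continue;
      }
    } else {
      int feas[6]; int nf = 0;
      for (int d = 0; d < 6; ++d) {
        int nx = x + DX[d], ny = y + DY[d], nz = z + DZ[d];
        if (nx >= 0 && nx <= hi && ny >= 0 && ny <= hi && nz >= 0 && nz <= hi)
          feas[nf++] = d;
      }
      dir = feas[rng.bounded((uint32_t)nf)];
    }
    // apply move with incremental d4 update
    switch (dir) {
      case 0: d4 += 4 * (qx + 1); qx += 2; ++x; break;
      case 1: d4 -= 4 * (qx - 1); qx -= 2; --x; break;
      case 2: d4 += 4 * (qy + 1); qy += 2; ++y; break;
      case 3: d4 -= 4 * (qy - 1); qy -= 2; --y; break;
      case 4: d4 += 4 * (qz + 1); qz += 2; ++z; break;
      default: d4 -= 4 * (qz - 1); qz -= 2; --z; break;
    }
    steps += 1.0;
    if ((double)d4 < thr) {
      WalkResult r = { steps, true, x, y, z };
      return r;
    }
  }
  WalkResult r = { steps, false, x, y, z };
  return r;
}

static inline bool inside_sphere(int L, double R, int x, int y, int z) {
  const int hi = L - 1;
  int64_t qx = 2 * (int64_t)x - hi;
  int64_t qy = 2 * (int64_t)y - hi;
  int64_t qz = 2 * (int64_t)z - hi;
  return (double)(qx * qx + qy * qy + qz * qz) < 4.0 * R * R;
}

// draw a uniform interior start, redrawn until outside the sphere
static void random_start(int L, double R, Xoshiro &rng, int &x, int &y, int &z) {
  do {
    x = (int)rng.bounded((uint32_t)L);
    y = (int)rng.bounded((uint32_t)L);
    z = (int)rng.bounded((uint32_t)L);
  } while (inside_sphere(L, R, x, y, z));
}

// [[Rcpp::export]]
List cpp_run_walk(int edge_length, double target_radius, double max_steps,
                  double master_seed, int run_index, int radius_index,
                  int repeat_index, bool corner_start, bool stay_policy) {
  Xoshiro rng;
  rng.seed(walk_key(master_seed, run_index, radius_index, repeat_index));
  int x = 0, y = 0, z = 0;
  if (!corner_start)
    random_start(edge_length, target_radius, rng, x, y, z);
  WalkResult w = walk_one(edge_length, target_radius, x, y, z,
                          max_steps, rng, stay_policy);
  return List::create(
    _["steps"] = w.steps,
    _["terminated"] = w.encounter ? "encounter" : "cap_exceeded",
    _["final"] = IntegerVector::create(w.x, w.y, w.z));
}

// batch of technical repeats for one radius; returns per-walk step counts
// [[Rcpp::export]]
NumericVector cpp_walk_batch(int edge_length, double target_radius, int repeats,
                             double max_steps, double master_seed, int run_index,
                             int radius_index, bool corner_start, bool stay_policy) {
  NumericVector out(repeats);
  for (int rep = 0; rep < repeats; ++rep) {
    Xoshiro rng;
    rng.seed(walk_key(master_seed, run_index, radius_index, rep));
    int x = 0, y = 0, z = 0;
    if (!corner_start)
      random_start(edge_length, target_radius, rng, x, y, z);
    WalkResult w = walk_one(edge_length, target_radius, x, y, z,
                            max_steps, rng, stay_policy);
    out[rep] = w.encounter ? w.steps : NA_REAL;
    if ((rep & 7) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// full trace of one walk (row 0 = start), for boundary/encounter property
// checks; max_steps should be modest
// [[Rcpp::export]]
IntegerMatrix cpp_walk_trace(int edge_length, double target_radius,
                             double max_steps, double master_seed,
                             int run_index, int radius_index, int repeat_index,
                             bool corner_start, bool stay_policy) {
  Xoshiro rng;
  rng.seed(walk_key(master_seed, run_index, radius_index, repeat_index));
  int x = 0, y = 0, z = 0;
  if (!corner_start)
    random_start(edge_length, target_radius, rng, x, y, z);
  const int hi = edge_length - 1;
  std::vector<int> xs, ys, zs;
  xs.push_back(x); ys.push_back(y); zs.push_back(z);
  double steps = 0.0;
  bool hit = inside_sphere(edge_length, target_radius, x, y, z);
  while (!hit && steps < max_steps) {
    int dir;
    if (stay_policy) {
      dir = (int)rng.bounded(6);
      int nx = x + DX[dir], ny = y + DY[dir], nz = z + DZ[dir];
      if (nx < 0 || nx > hi || ny < 0 || ny > hi || nz < 0 || nz > hi) {
        steps += 1.0;
        xs.push_back(x); ys.push_back(y); zs.push_back(z);
        continue;
      }
    } else {
      int feas[6]; int nf = 0;
      for (int d = 0; d < 6; ++d) {
        int nx = x + DX[d], ny = y + DY[d], nz = z + DZ[d];
        if (nx >= 0 && nx <= hi && ny >= 0 && ny <= hi && nz >= 0 && nz <= hi)
          feas[nf++] = d;
      }
      dir = feas[rng.bounded((uint32_t)nf)];
    }
    x += DX[dir]; y += DY[dir]; z += DZ[dir];
    steps += 1.0;
    xs.push_back(x); ys.push_back(y); zs.push_back(z);
    hit = inside_sphere(edge_length, target_radius, x, y, z);
  }
  IntegerMatrix m(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    m(i, 0) = xs[i]; m(i, 1) = ys[i]; m(i, 2) = zs[i];
  }
  colnames(m) = CharacterVector::create("x", "y", "z");
  return m;
}
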