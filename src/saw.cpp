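// Self-avoiding-walk sampling on the simple cubic lattice (pivot algorithm)
// and orientation-averaged Debye scattering sums. Compiled because both are
// the inner loops of the synthetic-data generator: a pivot sweep touches
// O(N) lattice sites per attempted move and the Debye sum is O(N^2) per
// walk per q-point.
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <random>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct P3 {
  int x, y, z;
};

// pack a lattice site into one 64-bit key (coordinates stay well inside
// +/- 2^20 for any chain length we ever sample)
inline std::uint64_t pack(int x, int y, int z) {
  const std::uint64_t off = 1u << 20;
  return ((std::uint64_t)(x + off) << 42) |
         ((std::uint64_t)(y + off) << 21) |
         (std::uint64_t)(z + off);
}

// the 48 signed axis permutations of the octahedral group; index 0 is the
// identity and is never drawn as a pivot move
struct Sym {
  int perm[3];
  int sign[3];
};

std::vector<Sym> octahedral_group() {
  std::vector<Sym> g;
  int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                     {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  for (int p = 0; p < 6; ++p)
    for (int s = 0; s < 8; ++s) {
      Sym sy;
      for (int k = 0; k < 3; ++k) {
        sy.perm[k] = perms[p][k];
        sy.sign[k] = (s >> k) & 1 ? -1 : 1;
      }
      g.push_back(sy);
    }
  // move the identity to slot 0 so the sampler can skip it
  for (size_t i = 0; i < g.size(); ++i) {
    const Sym& sy = g[i];
    if (sy.perm[0] == 0 && sy.perm[1] == 1 && sy.perm[2] == 2 &&
        sy.sign[0] == 1 && sy.sign[1] == 1 && sy.sign[2] == 1) {
      std::swap(g[0], g[i]);
      break;
    }
  }
  return g;
}

inline P3 apply_sym(const Sym& s, const P3& pivot, const P3& p) {
  int d[3] = {p.x - pivot.x, p.y - pivot.y, p.z - pivot.z};
  P3 out;
  out.x = pivot.x + s.sign[0] * d[s.perm[0]];
  out.y = pivot.y + s.sign[1] * d[s.perm[1]];
  out.z = pivot.z + s.sign[2] * d[s.perm[2]];
  return out;
}

// one attempted pivot move; returns true (and updates chain) on acceptance
bool pivot_once(std::vector<P3>& chain, const std::vector<Sym>& group,
                std::mt19937& rng) {
  const int n = (int)chain.size();
  std::uniform_int_distribution<int> site_d(1, n - 2);
  std::uniform_int_distribution<int> sym_d(1, (int)group.size() - 1);
  const int k = site_d(rng);
  const Sym& sy = group[sym_d(rng)];
  const P3 pivot = chain[k];

  // rotate the shorter arm, test against the fixed arm
  const bool tail_shorter = (n - 1 - k) <= k;
  const int fix_lo = tail_shorter ? 0 : k;
  const int fix_hi = tail_shorter ? k : n - 1;
  const int mov_lo = tail_shorter ? k + 1 : 0;
  const int mov_hi = tail_shorter ? n - 1 : k - 1;

  std::unordered_set<std::uint64_t> occ;
  occ.reserve((fix_hi - fix_lo + 1) * 2);
  for (int i = fix_lo; i <= fix_hi; ++i)
    occ.insert(pack(chain[i].x, chain[i].y, chain[i].z));

  std::vector<P3> moved(mov_hi - mov_lo + 1);
  for (int i = mov_lo; i <= mov_hi; ++i) {
    P3 q = apply_sym(sy, pivot, chain[i]);
    if (occ.count(pack(q.x, q.y, q.z))) return false;
    moved[i - mov_lo] = q;
  }
  for (int i = mov_lo; i <= mov_hi; ++i) chain[i] = moved[i - mov_lo];
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".saw_pivot_cpp")]]
List saw_pivot_cpp(int n_beads, int n_walks, int burn_in_accepts,
                   int gap_accepts, int seed) {
  if (n_beads < 3) stop("n_beads must be at least 3");
  std::mt19937 rng((std::uint32_t)seed);
  std::vector<Sym> group = octahedral_group();

  // start from a straight rod (trivially self-avoiding)
  std::vector<P3> chain(n_beads);
  for (int i = 0; i < n_beads; ++i) chain[i] = {i, 0, 0};

  List out(n_walks);
  long accepted = 0;
  long target = burn_in_accepts;
  for (int w = 0; w < n_walks; ++w) {
    while (accepted < target) {
      if (pivot_once(chain, group, rng)) ++accepted;
    }
    IntegerMatrix m(n_beads, 3);
    for (int i = 0; i < n_beads; ++i) {
      m(i, 0) = chain[i].x;
      m(i, 1) = chain[i].y;
      m(i, 2) = chain[i].z;
    }
    out[w] = m;
    target += gap_accepts;
  }
  return out;
}

// [[Rcpp::export(name = ".debye_sum_cpp")]]
NumericVector debye_sum_cpp(List walks, NumericVector q, double spacing) {
  const int nq = q.size();
  NumericVector iq(nq, 0.0);
  const int nw = walks.size();
  for (int w = 0; w < nw; ++w) {
    IntegerMatrix m = walks[w];
    const int n = m.nrow();
    std::vector<double> x(n), y(n), z(n);
    for (int i = 0; i < n; ++i) {
      x[i] = m(i, 0) * spacing;
      y[i] = m(i, 1) * spacing;
      z[i] = m(i, 2) * spacing;
    }
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        for (int k = 0; k < nq; ++k) {
          const double qr = q[k] * r;
          iq[k] += (qr < 1e-12) ? 2.0 : 2.0 * std::sin(qr) / qr;
        }
      }
    }
    for (int k = 0; k < nq; ++k) iq[k] += n;  // i = j diagonal
  }
  IntegerMatrix m0 = walks[0];
  const double denom = (double)nw * m0.nrow() * m0.nrow();
  for (int k = 0; k < nq; ++k) iq[k] /= denom;
  return iq;
}
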