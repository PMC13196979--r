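#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <sstream>
#include <string>
#include <vector>
using namespace Rcpp;

// Face labels: 0 never binds; odd label a binds a + 1, even label a > 0
// binds a - 1. A label never binds itself.
static inline bool binds(int a, int b) {
  if (a <= 0 || b <= 0) return false;
  return (a % 2 == 1) ? (b == a + 1) : (b == a - 1);
}

// Faces are stored per tile in the order N, E, S, W. A tile rotated
// clockwise by r quarter-turns shows, on side d, its original face
// (d - r) mod 4.
static inline int face_of(const std::vector<int> &g, int tile, int rot,
                          int side) {
  return g[4 * tile + ((side - rot) % 4 + 4) % 4];
}

// Canonical string for an occupied-cell set under rotation + translation
// (mirror images stay distinct: only the 4 rotations are applied).
static std::string canonical_shape(std::vector<std::pair<int, int> > cells) {
  std::string best;
  for (int r = 0; r < 4; ++r) {
    if (r > 0) {
      for (size_t k = 0; k < cells.size(); ++k) {
        int x = cells[k].first, y = cells[k].second;
        cells[k] = std::make_pair(y, -x);  // rotate 90 degrees
      }
    }
    int mx = cells[0].first, my = cells[0].second;
    for (size_t k = 1; k < cells.size(); ++k) {
      mx = std::min(mx, cells[k].first);
      my = std::min(my, cells[k].second);
    }
    std::vector<std::pair<int, int> > norm(cells);
    for (size_t k = 0; k < norm.size(); ++k) {
      norm[k].first -= mx;
      norm[k].second -= my;
    }
    std::sort(norm.begin(), norm.end());
    std::ostringstream ss;
    for (size_t k = 0; k < norm.size(); ++k) {
      if (k) ss << ';';
      ss << norm[k].first << ',' << norm[k].second;
    }
    std::string s = ss.str();
    if (best.empty() || s < best) best = s;
  }
  return best;
}

static const int DX[4] = {0, 1, 0, -1};   // N, E, S, W
static const int DY[4] = {1, 0, -1, 0};

// One stochastic assembly run. Seeds with tile 0 at the origin; repeatedly
// picks uniformly at random among all (perimeter cell, tile type, rotation)
// placements that bind at least one adjacent occupied face (tiles rotate
// but never mirror); stops when no placement binds. Returns the canonical
// shape string, or "UNDEFINED" once the cell count exceeds (4t)^2/2
// (unbounded growth is possible).
static std::string assemble_once_cpp(const std::vector<int> &g, int t,
                                     std::vector<int> &grid, int D,
                                     std::vector<int> &dirty) {
  const int maxsize = 8 * t * t;  // (4t)^2 / 2
  const int C = D / 2;
  for (size_t k = 0; k < dirty.size(); ++k) grid[dirty[k]] = -1;
  dirty.clear();

  std::vector<int> occupied;           // cell codes
  std::vector<int> perimeter;          // cell codes, unique
  std::vector<std::pair<int, int> > cells;

  int c0 = C + D * C;
  grid[c0] = 0;  // tile 0, rotation 0
  dirty.push_back(c0);
  occupied.push_back(c0);
  cells.push_back(std::make_pair(0, 0));
  for (int d = 0; d < 4; ++d) {
    int cc = (C + DX[d]) + D * (C + DY[d]);
    perimeter.push_back(cc);
  }

  std::vector<int> cand_cell, cand_tile, cand_rot, cand_dummy;
  while (true) {
    cand_cell.clear(); cand_tile.clear(); cand_rot.clear();
    for (size_t pi = 0; pi < perimeter.size(); ++pi) {
      int cc = perimeter[pi];
      int x = cc % D, y = cc / D;
      for (int tl = 0; tl < t; ++tl) {
        for (int r = 0; r < 4; ++r) {
          bool ok = false;
          for (int d = 0; d < 4 && !ok; ++d) {
            int nc = (x + DX[d]) + D * (y + DY[d]);
            int v = grid[nc];
            if (v < 0) continue;
            int nb_face = face_of(g, v / 4, v % 4, (d + 2) % 4);
            if (binds(face_of(g, tl, r, d), nb_face)) ok = true;
          }
          if (ok) {
            cand_cell.push_back(cc);
            cand_tile.push_back(tl);
            cand_rot.push_back(r);
          }
        }
      }
    }
    if (cand_cell.empty()) break;
    int pick = (int)(unif_rand() * cand_cell.size());
    if (pick >= (int)cand_cell.size()) pick = cand_cell.size() - 1;
    int cc = cand_cell[pick];
    grid[cc] = 4 * cand_tile[pick] + cand_rot[pick];
    dirty.push_back(cc);
    occupied.push_back(cc);
    int x = cc % D, y = cc / D;
    cells.push_back(std::make_pair(x - C, y - C));
    if ((int)occupied.size() > maxsize) return "UNDEFINED";
    // the placed cell leaves the perimeter; its empty neighbours join it
    for (size_t pi = 0; pi < perimeter.size(); ++pi) {
      if (perimeter[pi] == cc) {
        perimeter[pi] = perimeter.back();
        perimeter.pop_back();
        break;
      }
    }
    for (int d = 0; d < 4; ++d) {
      int nc = (x + DX[d]) + D * (y + DY[d]);
      if (grid[nc] >= 0) continue;
      bool present = false;
      for (size_t pi = 0; pi < perimeter.size() && !present; ++pi)
        if (perimeter[pi] == nc) present = true;
      if (!present) perimeter.push_back(nc);
    }
  }
  return canonical_shape(cells);
}

// Repeat the stochastic assembly n_rep times for one genotype and tally
// canonical shapes (plus "UNDEFINED"). Uses R's RNG stream.
// [[Rcpp::export]]
List poly_assemble_tally(IntegerVector genotype, int t, int n_rep) {
  if ((int)genotype.size() != 4 * t)
    stop("genotype must have length 4t");
  std::vector<int> g(genotype.begin(), genotype.end());
  int maxsize = 8 * t * t;
  int D = 2 * (maxsize + 2) + 1;
  std::vector<int> grid((size_t)D * D, -1);
  std::vector<int> dirty;
  std::map<std::string, int> tally;
  for (int rep = 0; rep < n_rep; ++rep) {
    std::string s = assemble_once_cpp(g, t, grid, D, dirty);
    tally[s] += 1;
  }
  CharacterVector shapes(tally.size());
  IntegerVector counts(tally.size());
  int k = 0;
  for (std::map<std::string, int>::iterator it = tally.begin();
       it != tally.end(); ++it, ++k) {
    shapes[k] = it->first;
    counts[k] = it->second;
  }
  return List::create(_["shape"] = shapes, _["count"] = counts);
}

// Single assembly run returning the canonical shape string.
// [[Rcpp::export]]
std::string poly_assemble_once(IntegerVector genotype, int t) {
  if ((int)genotype.size() != 4 * t) stop("genotype must have length 4t");
  std::vector<int> g(genotype.begin(), genotype.end());
  int maxsize = 8 * t * t;
  int D = 2 * (maxsize + 2) + 1;
  std::vector<int> grid((size_t)D * D, -1);
  std::vector<int> dirty;
  return assemble_once_cpp(g, t, grid, D, dirty);
}

// Zero every face of tiles not connected to tile 0 in the tile-level
// binding graph. Tiles unreachable from the seed can never attach, so
// their labels are irrelevant to the ensemble.
static std::vector<int> zero_unreachable(const std::vector<int> &g, int t) {
  std::vector<char> present(4 * t + 3, 0);
  int maxlab = 0;
  for (size_t i = 0; i < g.size(); ++i) maxlab = std::max(maxlab, g[i]);
  std::vector<char> label_present(maxlab + 2, 0);
  for (size_t i = 0; i < g.size(); ++i)
    if (g[i] > 0) label_present[g[i]] = 1;
  std::vector<char> reach(t, 0);
  reach[0] = 1;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int a = 0; a < t; ++a) {
      if (!reach[a]) continue;
      for (int b = 0; b < t; ++b) {
        if (reach[b]) continue;
        bool conn = false;
        for (int fa = 0; fa < 4 && !conn; ++fa) {
          for (int fb = 0; fb < 4 && !conn; ++fb) {
            if (binds(g[4 * a + fa], g[4 * b + fb])) conn = true;
          }
        }
        if (conn) { reach[b] = 1; changed = true; }
      }
    }
  }
  std::vector<int> out(g);
  for (int tl = 0; tl < t; ++tl) {
    if (!reach[tl])
      for (int d = 0; d < 4; ++d) out[4 * tl + d] = 0;
  }
  return out;
}

// Canonical relabelling of one genotype variant: faces whose partner label
// does not occur anywhere become 0; binding pairs are renamed to (1,2),
// (3,4), ... in order of first occurrence.
static std::string relabel_string(const std::vector<int> &g) {
  int maxlab = 0;
  for (size_t i = 0; i < g.size(); ++i) maxlab = std::max(maxlab, g[i]);
  std::vector<char> present(maxlab + 2, 0);
  for (size_t i = 0; i < g.size(); ++i)
    if (g[i] > 0) present[g[i]] = 1;
  std::vector<int> rename(maxlab + 2, -1);
  int next = 1;
  std::ostringstream ss;
  for (size_t i = 0; i < g.size(); ++i) {
    int a = g[i];
    int out = 0;
    if (a > 0) {
      int partner = (a % 2 == 1) ? a + 1 : a - 1;
      if (partner <= maxlab + 1 && partner >= 1 && present[partner]) {
        if (rename[a] < 0) {
          rename[a] = next;
          rename[partner] = next + 1;
          next += 2;
        }
        out = rename[a];
      }
    }
    if (i) ss << ',';
    ss << out;
  }
  return ss.str();
}

// Canonical assembly-graph key of a genotype: minimum relabelled string
// over all tile permutations and per-tile rotations, after zeroing tiles
// unreachable from the seed tile.
// [[Rcpp::export]]
std::string poly_canonical_key(IntegerVector genotype, int t) {
  if ((int)genotype.size() != 4 * t) stop("genotype must have length 4t");
  if (t > 4) stop("canonical key supported for t <= 4");
  std::vector<int> g0(genotype.begin(), genotype.end());
  g0 = zero_unreachable(g0, t);
  std::vector<int> perm(t);
  for (int i = 0; i < t; ++i) perm[i] = i;
  std::string best;
  do {
    int nrot = 1;
    for (int i = 0; i < t; ++i) nrot *= 4;
    for (int rc = 0; rc < nrot; ++rc) {
      std::vector<int> variant(4 * t);
      int rr = rc;
      for (int i = 0; i < t; ++i) {
        int r = rr % 4;
        rr /= 4;
        for (int d = 0; d < 4; ++d)
          variant[4 * i + d] = face_of(g0, perm[i], r, d);
      }
      std::string s = relabel_string(variant);
      if (best.empty() || s < best) best = s;
    }
  } while (std::next_permutation(perm.begin(), perm.end()));
  return best;
}

// Canonical keys for a whole matrix of genotypes (rows).
// [[Rcpp::export]]
CharacterVector poly_canonical_keys(IntegerMatrix genotypes, int t) {
  int n = genotypes.nrow();
  CharacterVector out(n);
  IntegerVector row(4 * t);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 4 * t; ++j) row[j] = genotypes(i, j);
    out[i] = poly_canonical_key(row, t);
  }
  return out;
}
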