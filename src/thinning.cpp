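#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Topology-preserving sequential thinning.
//
// A foreground voxel is "simple" when its removal leaves both the local
// foreground and background topology unchanged. In 3D we use the standard
// (26, 6) characterization: exactly one 26-connected foreground component
// among the 26 neighbours, and exactly one 6-connected background component
// within the 18-neighbourhood that touches a face neighbour. In 2D (single
// slice) the (8, 4) analogue is used. Voxels are visited in order of
// increasing distance-transform value so the surviving curve stays medial.

namespace {

struct Nbhd {
  // 3x3x3 occupancy, index (di+1) + 3*(dj+1) + 9*(dk+1); centre at 13
  bool b[27];
};

inline int lidx(int di, int dj, int dk) {
  return (di + 1) + 3 * (dj + 1) + 9 * (dk + 1);
}

// 26-connected components of foreground among the 26 neighbours == 1?
bool cond_fg_3d(const Nbhd &nb) {
  bool seen[27];
  std::memset(seen, 0, sizeof(seen));
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb.b[s] || seen[s]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int ci = c % 3, cj = (c / 3) % 3, ck = c / 9;
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || seen[t] || !nb.b[t]) continue;
        int ti = t % 3, tj = (t / 3) % 3, tk = t / 9;
        if (std::abs(ti - ci) <= 1 && std::abs(tj - cj) <= 1 &&
            std::abs(tk - ck) <= 1) {
          seen[t] = true;
          stack[top++] = t;
        }
      }
    }
  }
  return ncomp == 1;
}

// 6-connected components of background within the 18-neighbourhood that
// contain a face neighbour == 1?
bool cond_bg_3d(const Nbhd &nb) {
  // membership of the 18-neighbourhood (chebyshev 1, not a 3D corner)
  auto in18 = [](int i, int j, int k) {
    int a = std::abs(i - 1), b2 = std::abs(j - 1), c = std::abs(k - 1);
    if (a + b2 + c == 0) return false;
    return a + b2 + c <= 2; // excludes the 8 corners (sum 3)
  };
  bool seen[27];
  std::memset(seen, 0, sizeof(seen));
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    int si = s % 3, sj = (s / 3) % 3, sk = s / 9;
    if (!in18(si, sj, sk) || nb.b[s] || seen[s]) continue;
    // component must touch a face neighbour of the centre
    bool touches = false;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int ci = c % 3, cj = (c / 3) % 3, ck = c / 9;
      if (std::abs(ci - 1) + std::abs(cj - 1) + std::abs(ck - 1) == 1)
        touches = true;
      for (int t = 0; t < 27; ++t) {
        int ti = t % 3, tj = (t / 3) % 3, tk = t / 9;
        if (seen[t] || nb.b[t] || !in18(ti, tj, tk)) continue;
        if (std::abs(ti - ci) + std::abs(tj - cj) + std::abs(tk - ck) == 1) {
          seen[t] = true;
          stack[top++] = t;
        }
      }
    }
    if (touches) {
      ++ncomp;
      if (ncomp > 1) return false;
    }
  }
  return ncomp == 1;
}

// 2D (8, 4) simple test on the central slice of the neighbourhood
bool cond_fg_2d(const Nbhd &nb) {
  bool seen[9];
  std::memset(seen, 0, sizeof(seen));
  int ncomp = 0, stack[9];
  auto at = [&](int s) { return nb.b[lidx(s % 3 - 1, s / 3 - 1, 0)]; };
  for (int s = 0; s < 9; ++s) {
    if (s == 4 || !at(s) || seen[s]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int ci = c % 3, cj = c / 3;
      for (int t = 0; t < 9; ++t) {
        if (t == 4 || seen[t] || !at(t)) continue;
        int ti = t % 3, tj = t / 3;
        if (std::abs(ti - ci) <= 1 && std::abs(tj - cj) <= 1) {
          seen[t] = true;
          stack[top++] = t;
        }
      }
    }
  }
  return ncomp == 1;
}

bool cond_bg_2d(const Nbhd &nb) {
  bool seen[9];
  std::memset(seen, 0, sizeof(seen));
  int ncomp = 0, stack[9];
  auto at = [&](int s) { return nb.b[lidx(s % 3 - 1, s / 3 - 1, 0)]; };
  for (int s = 0; s < 9; ++s) {
    int si = s % 3, sj = s / 3;
    if (s == 4 || at(s) || seen[s]) continue;
    bool touches = false;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int ci = c % 3, cj = c / 3;
      if (std::abs(ci - 1) + std::abs(cj - 1) == 1) touches = true;
      for (int t = 0; t < 9; ++t) {
        int ti = t % 3, tj = t / 3;
        if (t == 4 || seen[t] || at(t)) continue;
        if (std::abs(ti - ci) + std::abs(tj - cj) == 1) {
          seen[t] = true;
          stack[top++] = t;
        }
      }
    }
    (void)si; (void)sj;
    if (touches) {
      ++ncomp;
      if (ncomp > 1) return false;
    }
  }
  return ncomp == 1;
}

class Vol {
public:
  Vol(std::vector<uint8_t> &v, int n1, int n2, int n3)
      : v_(v), n1_(n1), n2_(n2), n3_(n3) {}
  inline bool at(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= n1_ || j >= n2_ || k >= n3_)
      return false;
    return v_[i + (R_xlen_t)n1_ * (j + (R_xlen_t)n2_ * k)] != 0;
  }
  inline void clear(R_xlen_t idx) { v_[idx] = 0; }
  void nbhd(int i, int j, int k, Nbhd &nb) const {
    int p = 0;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          // careful: our lidx order is di fastest; build accordingly
          nb.b[lidx(di, dj, dk)] = at(i + di, j + dj, k + dk);
          ++p;
        }
  }
  int nb_count(int i, int j, int k, bool two_d) const {
    int c = 0;
    int dkmax = two_d ? 0 : 1;
    for (int dk = -dkmax; dk <= dkmax; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          if (at(i + di, j + dj, k + dk)) ++c;
        }
    return c;
  }

private:
  std::vector<uint8_t> &v_;
  int n1_, n2_, n3_;
};

inline bool simple_point(const Vol &vol, int i, int j, int k, bool two_d) {
  Nbhd nb;
  vol.nbhd(i, j, k, nb);
  if (two_d) return cond_fg_2d(nb) && cond_bg_2d(nb);
  return cond_fg_3d(nb) && cond_bg_3d(nb);
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector vol, IntegerVector dim,
                       NumericVector priority, bool two_d) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<uint8_t> img(n);
  std::vector<R_xlen_t> fg;
  for (R_xlen_t t = 0; t < n; ++t) {
    img[t] = vol[t] ? 1 : 0;
    if (img[t]) fg.push_back(t);
  }
  Vol V(img, n1, n2, n3);
  // within each directional sub-iteration, visit candidates in order of
  // increasing distance-transform value so the surviving curve is medial
  std::stable_sort(fg.begin(), fg.end(), [&](R_xlen_t a, R_xlen_t b) {
    return priority[a] < priority[b];
  });
  // six face directions (four in 2D): a sub-iteration only removes voxels
  // whose face neighbour in that direction is background, so erosion
  // proceeds one boundary layer at a time from each side and elongated
  // ridges are never consumed lengthwise
  const int dirs3[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                           {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  const int ndir = two_d ? 4 : 6;
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < ndir; ++d) {
      // snapshot this direction's border voxels first: newly exposed
      // voxels wait for the next sub-iteration, so erosion proceeds one
      // layer per sweep from every side (deletions are still verified
      // sequentially against the current image to preserve topology)
      cand.clear();
      for (size_t t = 0; t < fg.size(); ++t) {
        R_xlen_t idx = fg[t];
        if (!img[idx]) continue;
        int i = (int)(idx % n1);
        int j = (int)((idx / n1) % n2);
        int k = (int)(idx / ((R_xlen_t)n1 * n2));
        if (!V.at(i + dirs3[d][0], j + dirs3[d][1], k + dirs3[d][2]))
          cand.push_back(idx);
      }
      for (size_t t = 0; t < cand.size(); ++t) {
        R_xlen_t idx = cand[t];
        int i = (int)(idx % n1);
        int j = (int)((idx / n1) % n2);
        int k = (int)(idx / ((R_xlen_t)n1 * n2));
        int nc = V.nb_count(i, j, k, two_d);
        if (nc <= 1) continue; // curve endpoint (or isolated voxel): keep
        if (simple_point(V, i, j, k, two_d)) {
          V.clear(idx);
          changed = true;
        }
      }
    }
    if (changed) {
      // drop deleted entries to shrink later passes
      fg.erase(std::remove_if(fg.begin(), fg.end(),
                              [&](R_xlen_t a) { return !img[a]; }),
               fg.end());
    }
  }
  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = img[t] != 0;
  out.attr("dim") = dim;
  return out;
}

// Number of foreground neighbours (26- or 8-connectivity) per voxel.
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count(LogicalVector vol, IntegerVector dim,
                                 bool two_d) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<uint8_t> img(n);
  for (R_xlen_t t = 0; t < n; ++t) img[t] = vol[t] ? 1 : 0;
  Vol V(img, n1, n2, n3);
  IntegerVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    if (!img[t]) { out[t] = NA_INTEGER; continue; }
    int i = (int)(t % n1);
    int j = (int)((t / n1) % n2);
    int k = (int)(t / ((R_xlen_t)n1 * n2));
    out[t] = V.nb_count(i, j, k, two_d);
  }
  out.attr("dim") = dim;
  return out;
}
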