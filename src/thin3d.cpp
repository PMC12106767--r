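// 3D curve thinning: iterative removal of simple border points with six
// directional subiterations and endpoint preservation, yielding a
// 26-connected medial curve skeleton (the AnalyzeSkeleton-style input).
// A voxel is simple (its removal preserves topology) iff the object voxels
// in its 26-neighbourhood form one 26-component adjacent to it and the
// background voxels in its 18-neighbourhood form one 6-component
// 6-adjacent to it (Malandain & Bertrand characterization).
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

bool tables_ready = false;
// 27 cells of the 3x3x3 cube; cell 13 is the center
int cdx[27], cdy[27], cdz[27];
bool adj26[27][27]; // Chebyshev distance 1
bool adj6[27][27];  // Manhattan distance 1
bool inN18[27];     // at most two nonzero offsets
bool inN6[27];      // exactly one nonzero offset (face neighbours)

void build_tables() {
  int c = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        cdx[c] = dx; cdy[c] = dy; cdz[c] = dz; ++c;
      }
  for (int a = 0; a < 27; ++a) {
    int nz = (cdx[a] != 0) + (cdy[a] != 0) + (cdz[a] != 0);
    inN18[a] = (a != 13) && nz <= 2;
    inN6[a] = nz == 1;
    for (int b = 0; b < 27; ++b) {
      int ddx = std::abs(cdx[a] - cdx[b]);
      int ddy = std::abs(cdy[a] - cdy[b]);
      int ddz = std::abs(cdz[a] - cdz[b]);
      int cheb = std::max(ddx, std::max(ddy, ddz));
      adj26[a][b] = (a != b) && cheb == 1;
      adj6[a][b] = (ddx + ddy + ddz) == 1;
    }
  }
  tables_ready = true;
}

// nb[27]: object occupancy of the cube around p (nb[13] = 1)
inline int count_obj_neighbours(const uint8_t nb[27]) {
  int n = 0;
  for (int a = 0; a < 27; ++a)
    if (a != 13 && nb[a]) ++n;
  return n;
}

bool is_simple(const uint8_t nb[27]) {
  // C*: 26-components of object voxels in N26 (all are adjacent to center)
  int comp = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int a = 0; a < 27; ++a) {
    if (a == 13 || !nb[a] || seen[a]) continue;
    ++comp;
    if (comp > 1) return false;
    int top = 0;
    stack[top++] = a;
    seen[a] = true;
    while (top) {
      int u = stack[--top];
      for (int b = 0; b < 27; ++b)
        if (b != 13 && nb[b] && !seen[b] && adj26[u][b]) {
          seen[b] = true;
          stack[top++] = b;
        }
    }
  }
  if (comp != 1) return false;
  // C_bar: 6-components of background voxels in N18 that touch a face
  // neighbour of the center
  bool seenb[27] = {false};
  int compb = 0;
  for (int a = 0; a < 27; ++a) {
    if (!inN6[a] || nb[a] || seenb[a]) continue; // seed from face neighbours
    ++compb;
    if (compb > 1) return false;
    int top = 0;
    stack[top++] = a;
    seenb[a] = true;
    while (top) {
      int u = stack[--top];
      for (int b = 0; b < 27; ++b)
        if (inN18[b] && !nb[b] && !seenb[b] && adj6[u][b]) {
          seenb[b] = true;
          stack[top++] = b;
        }
    }
  }
  return compb == 1;
}

} // namespace

// [[Rcpp::export]]
IntegerVector thin3d_cpp(IntegerVector mask, IntegerVector dims) {
  if (!tables_ready) build_tables();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int p1 = n1 + 2, p2 = n2 + 2, p3 = n3 + 2;
  const long NP = (long)p1 * p2 * p3;
  std::vector<uint8_t> g(NP, 0);
  std::vector<long> obj;
  obj.reserve(1024);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i)
        if (mask[i + (long)n1 * (j + (long)n2 * k)]) {
          long pi = (i + 1) + (long)p1 * ((j + 1) + (long)p2 * (k + 1));
          g[pi] = 1;
          obj.push_back(pi);
        }
  long noff[27];
  {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          noff[c++] = dx + (long)p1 * (dy + (long)p2 * dz);
  }
  const long dir[6] = {1, -1, (long)p1, -(long)p1, (long)p1 * p2, -(long)p1 * p2};
  uint8_t nb[27];
  std::vector<long> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (long pi : obj) {
        if (!g[pi] || g[pi + dir[d]]) continue; // not a border point for d
        for (int a = 0; a < 27; ++a) nb[a] = g[pi + noff[a]];
        if (count_obj_neighbours(nb) < 2) continue; // endpoint/isolated kept
        if (is_simple(nb)) cand.push_back(pi);
      }
      for (long pi : cand) { // sequential recheck preserves topology
        if (!g[pi]) continue;
        for (int a = 0; a < 27; ++a) nb[a] = g[pi + noff[a]];
        if (count_obj_neighbours(nb) < 2) continue;
        if (is_simple(nb)) {
          g[pi] = 0;
          changed = true;
        }
      }
    }
    if (changed) { // compact the object list
      size_t w = 0;
      for (size_t r = 0; r < obj.size(); ++r)
        if (g[obj[r]]) obj[w++] = obj[r];
      obj.resize(w);
    }
  }
  IntegerVector out((long)n1 * n2 * n3);
  for (long pi : obj) {
    long rem = pi;
    int i = (int)(rem % p1) - 1;
    rem /= p1;
    int j = (int)(rem % p2) - 1;
    int k = (int)(rem / p2) - 1;
    out[i + (long)n1 * (j + (long)n2 * k)] = 1;
  }
  out.attr("dim") = dims;
  return out;
}

// Sums of `vol` over all box windows of per-axis sides (start positions);
// output dims are dims - sides + 1.
// [[Rcpp::export]]
NumericVector box_sum3d_cpp(NumericVector vol, IntegerVector dims,
                            IntegerVector sides) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int s1 = sides[0], s2 = sides.size() > 1 ? sides[1] : sides[0];
  int s3 = sides.size() > 2 ? sides[2] : sides[0];
  if (s1 < 1 || s1 > n1 || s2 < 1 || s2 > n2 || s3 < 1 || s3 > n3)
    stop("window side must be between 1 and the volume dimension per axis");
  const int m1 = n1 - s1 + 1, m2 = n2 - s2 + 1, m3 = n3 - s3 + 1;
  // pass along x
  std::vector<double> a((long)m1 * n2 * n3);
  for (long jk = 0; jk < (long)n2 * n3; ++jk) {
    const double *src = &vol[jk * n1];
    double *dst = &a[jk * m1];
    double s = 0;
    for (int t = 0; t < s1; ++t) s += src[t];
    dst[0] = s;
    for (int t = 1; t < m1; ++t) {
      s += src[t + s1 - 1] - src[t - 1];
      dst[t] = s;
    }
  }
  // pass along y
  std::vector<double> b((long)m1 * m2 * n3);
  for (int k = 0; k < n3; ++k) {
    for (int i = 0; i < m1; ++i) {
      double s = 0;
      for (int t = 0; t < s2; ++t) s += a[i + (long)m1 * (t + (long)n2 * k)];
      b[i + (long)m1 * (0 + (long)m2 * k)] = s;
      for (int t = 1; t < m2; ++t) {
        s += a[i + (long)m1 * ((t + s2 - 1) + (long)n2 * k)] -
             a[i + (long)m1 * ((t - 1) + (long)n2 * k)];
        b[i + (long)m1 * (t + (long)m2 * k)] = s;
      }
    }
  }
  // pass along z
  NumericVector out((long)m1 * m2 * m3);
  const long sl = (long)m1 * m2;
  for (long ij = 0; ij < sl; ++ij) {
    double s = 0;
    for (int t = 0; t < s3; ++t) s += b[ij + sl * t];
    out[ij] = s;
    for (int t = 1; t < m3; ++t) {
      s += b[ij + sl * (t + s3 - 1)] - b[ij + sl * (t - 1)];
      out[ij + sl * t] = s;
    }
  }
  out.attr("dim") = IntegerVector::create(m1, m2, m3);
  return out;
}

// Per-voxel size of the 26-connected component each foreground voxel
// belongs to (0 on background). Iterative flood fill.
// [[Rcpp::export]]
IntegerVector component_sizes_cpp(IntegerVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long N = (long)n1 * n2 * n3;
  std::vector<int> comp(N, 0); // 0 = unvisited/background
  IntegerVector out(N);
  std::vector<long> stack, members;
  int cid = 0;
  for (long s = 0; s < N; ++s) {
    if (!mask[s] || comp[s]) continue;
    ++cid;
    stack.clear();
    members.clear();
    stack.push_back(s);
    comp[s] = cid;
    while (!stack.empty()) {
      long v = stack.back();
      stack.pop_back();
      members.push_back(v);
      int i = (int)(v % n1);
      int j = (int)((v / n1) % n2);
      int k = (int)(v / ((long)n1 * n2));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int ii = i + dx, jj = j + dy, kk = k + dz;
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
              continue;
            long w = ii + (long)n1 * (jj + (long)n2 * kk);
            if (mask[w] && !comp[w]) {
              comp[w] = cid;
              stack.push_back(w);
            }
          }
    }
    for (long v : members) out[v] = (int)members.size();
  }
  out.attr("dim") = dims;
  return out;
}
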