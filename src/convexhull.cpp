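// Incremental (beneath-beyond) convex hull in dimension 2..8, with facet
// half-space and facet-vertex output so that volumes, membership tests and
// polytope intersections can be computed downstream.
//
// Points are assumed to be in general position up to a scale-relative
// tolerance; rank-deficient inputs must be screened by the caller (the R
// wrapper checks the affine rank and reports an undefined hull instead of
// calling in here). Facets store fixed-size arrays (d <= 8) to avoid
// per-facet heap allocation: the facet list turns over heavily while the
// hull is built.

#include <RcppArmadillo.h>
#include <array>
#include <algorithm>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const int DMAX = 8;

struct Facet {
  std::array<int, DMAX> verts;      // d vertex indices (rows of P)
  std::array<double, DMAX> normal;  // outward normal (not unit)
  double offset;                    // n . x <= offset on the hull
  bool alive;
};

// Null vector of the (d-1) x d matrix M (rows = edge vectors of a facet)
// by Gaussian elimination with partial pivoting. Returns false when M is
// rank-deficient relative to its scale (degenerate facet).
bool nullVector(double M[DMAX - 1][DMAX], int d, double* n) {
  int rows = d - 1;
  double scale = 0.0;
  for (int r = 0; r < rows; ++r)
    for (int c = 0; c < d; ++c) scale = std::max(scale, std::abs(M[r][c]));
  if (scale == 0.0) return false;
  const double eps = 1e-12 * scale;

  int pivCol[DMAX - 1];
  bool used[DMAX] = {false};
  for (int r = 0; r < rows; ++r) {
    // find the largest pivot among unused columns, searching rows >= r
    int bestR = -1, bestC = -1;
    double best = eps;
    for (int rr = r; rr < rows; ++rr)
      for (int c = 0; c < d; ++c) {
        if (used[c]) continue;
        if (std::abs(M[rr][c]) > best) { best = std::abs(M[rr][c]); bestR = rr; bestC = c; }
      }
    if (bestR < 0) return false;  // rank < d-1
    if (bestR != r)
      for (int c = 0; c < d; ++c) std::swap(M[r][c], M[bestR][c]);
    used[bestC] = true;
    pivCol[r] = bestC;
    for (int rr = 0; rr < rows; ++rr) {
      if (rr == r) continue;
      double f = M[rr][bestC] / M[r][bestC];
      if (f != 0.0)
        for (int c = 0; c < d; ++c) M[rr][c] -= f * M[r][c];
    }
  }
  // the single unused column is the free variable
  int freeCol = -1;
  for (int c = 0; c < d; ++c) if (!used[c]) freeCol = c;
  for (int c = 0; c < d; ++c) n[c] = 0.0;
  n[freeCol] = 1.0;
  for (int r = 0; r < rows; ++r)
    n[pivCol[r]] = -M[r][freeCol] / M[r][pivCol[r]];
  return true;
}

// Hyperplane through the d points P[vs, ], oriented away from `interior`.
bool facetPlane(const arma::mat& P, const std::array<int, DMAX>& vs, int d,
                const double* interior, double tol, Facet& f) {
  double M[DMAX - 1][DMAX];
  for (int i = 1; i < d; ++i)
    for (int c = 0; c < d; ++c)
      M[i - 1][c] = P(vs[i], c) - P(vs[0], c);
  double n[DMAX];
  if (!nullVector(M, d, n)) return false;
  double norm = 0.0;
  for (int c = 0; c < d; ++c) norm += n[c] * n[c];
  norm = std::sqrt(norm);
  if (!(norm > 0.0) || !std::isfinite(norm)) return false;
  double b = 0.0, side = 0.0;
  for (int c = 0; c < d; ++c) { n[c] /= norm; b += n[c] * P(vs[0], c); }
  for (int c = 0; c < d; ++c) side += n[c] * interior[c];
  side -= b;
  if (std::abs(side) < tol * 1e-3) return false;  // interior on the plane
  if (side > 0) { b = -b; for (int c = 0; c < d; ++c) n[c] = -n[c]; }
  for (int c = 0; c < d; ++c) f.normal[c] = n[c];
  f.offset = b;
  return true;
}

double factorial(int k) {
  double f = 1.0;
  for (int i = 2; i <= k; ++i) f *= i;
  return f;
}

}  // namespace

// [[Rcpp::export(name = ".qhull_cpp")]]
List qhull_cpp(const arma::mat& P) {
  const int n = P.n_rows, d = P.n_cols;
  if (d < 2 || d > DMAX) stop("qhull_cpp requires dimension in 2..%d", DMAX);
  if (n < d + 1) stop("qhull_cpp requires at least d + 1 points");

  const double scale = std::max(1.0, arma::abs(P).max());
  const double tol = 1e-9 * scale * std::sqrt((double)d);

  // --- initial simplex: greedily maximise distance from the affine hull ---
  std::vector<int> simp;
  simp.push_back(0);
  {
    double best = -1.0; int bi = -1;
    for (int i = 1; i < n; ++i) {
      double dist = arma::norm(P.row(i) - P.row(0));
      if (dist > best) { best = dist; bi = i; }
    }
    if (best <= tol) stop("all points coincide");
    simp.push_back(bi);
  }
  while ((int)simp.size() < d + 1) {
    arma::mat B((int)simp.size() - 1, d);
    for (size_t i = 1; i < simp.size(); ++i)
      B.row(i - 1) = P.row(simp[i]) - P.row(simp[0]);
    arma::mat Q = arma::orth(B.t());
    double best = -1.0; int bi = -1;
    for (int i = 0; i < n; ++i) {
      arma::vec v = (P.row(i) - P.row(simp[0])).t();
      arma::vec r = v - Q * (Q.t() * v);
      double dist = arma::norm(r);
      if (dist > best) { best = dist; bi = i; }
    }
    if (best <= tol) stop("points are affinely rank-deficient");
    simp.push_back(bi);
  }

  double interior[DMAX] = {0};
  for (int i = 0; i <= d; ++i)
    for (int c = 0; c < d; ++c) interior[c] += P(simp[i], c);
  for (int c = 0; c < d; ++c) interior[c] /= (d + 1);

  std::vector<Facet> facets;
  facets.reserve(256);
  for (int omit = 0; omit <= d; ++omit) {
    Facet f;
    int k = 0;
    for (int i = 0; i <= d; ++i) if (i != omit) f.verts[k++] = simp[i];
    f.alive = true;
    if (!facetPlane(P, f.verts, d, interior, tol, f))
      stop("degenerate initial simplex facet");
    facets.push_back(f);
  }

  // --- insert remaining points ---
  std::vector<bool> inSimplex(n, false);
  for (int i = 0; i <= d; ++i) inSimplex[simp[i]] = true;

  std::vector<int> visible;
  // flat ridge buffer: (d-1) sorted vertex ids per ridge
  std::vector<int> ridgeBuf;
  std::vector<int> ridgeIdx;
  size_t deadCount = 0;

  for (int p = 0; p < n; ++p) {
    if (inSimplex[p]) continue;
    if (deadCount > 64 && deadCount * 2 > facets.size()) {
      std::vector<Facet> live;
      live.reserve(facets.size() - deadCount);
      for (size_t f = 0; f < facets.size(); ++f)
        if (facets[f].alive) live.push_back(facets[f]);
      facets.swap(live);
      deadCount = 0;
    }
    double x[DMAX];
    for (int c = 0; c < d; ++c) x[c] = P(p, c);
    visible.clear();
    for (size_t f = 0; f < facets.size(); ++f) {
      if (!facets[f].alive) continue;
      double dot = -facets[f].offset;
      for (int c = 0; c < d; ++c) dot += facets[f].normal[c] * x[c];
      if (dot > tol) visible.push_back((int)f);
    }
    if (visible.empty()) continue;  // beneath every facet: interior point

    // horizon ridges: (d-1)-subsets belonging to exactly one visible facet
    const int rlen = d - 1;
    ridgeBuf.clear(); ridgeIdx.clear();
    for (int fi : visible) {
      const std::array<int, DMAX>& vs = facets[fi].verts;
      for (int omit = 0; omit < d; ++omit) {
        size_t at = ridgeBuf.size();
        for (int i = 0; i < d; ++i) if (i != omit) ridgeBuf.push_back(vs[i]);
        std::sort(ridgeBuf.begin() + at, ridgeBuf.end());
        ridgeIdx.push_back((int)(at / rlen));
      }
    }
    std::sort(ridgeIdx.begin(), ridgeIdx.end(),
              [&](int a, int b) {
                const int* ra = &ridgeBuf[(size_t)a * rlen];
                const int* rb = &ridgeBuf[(size_t)b * rlen];
                return std::lexicographical_compare(ra, ra + rlen,
                                                    rb, rb + rlen);
              });
    auto sameRidge = [&](int a, int b) {
      const int* ra = &ridgeBuf[(size_t)a * rlen];
      const int* rb = &ridgeBuf[(size_t)b * rlen];
      return std::equal(ra, ra + rlen, rb);
    };
    for (int fi : visible) facets[fi].alive = false;
    deadCount += visible.size();

    size_t i = 0, m = ridgeIdx.size();
    while (i < m) {
      size_t j = i + 1;
      while (j < m && sameRidge(ridgeIdx[i], ridgeIdx[j])) ++j;
      if (j - i == 1) {  // horizon ridge -> new facet with apex p
        Facet f;
        const int* rv = &ridgeBuf[(size_t)ridgeIdx[i] * rlen];
        for (int c = 0; c < rlen; ++c) f.verts[c] = rv[c];
        f.verts[rlen] = p;
        f.alive = true;
        if (facetPlane(P, f.verts, d, interior, tol, f))
          facets.push_back(f);
        // degenerate sliver facets (zero (d-1)-measure) are skipped
      }
      i = j;
    }
  }

  // --- collect output ---
  int nf = 0;
  for (size_t f = 0; f < facets.size(); ++f) if (facets[f].alive) ++nf;
  NumericMatrix normals(nf, d);
  NumericVector offsets(nf);
  IntegerMatrix facetVerts(nf, d);
  std::vector<int> vertexFlag(n, 0);
  double vol = 0.0;
  arma::mat S(d, d);
  int row = 0;
  for (size_t f = 0; f < facets.size(); ++f) {
    if (!facets[f].alive) continue;
    const Facet& fc = facets[f];
    for (int c = 0; c < d; ++c) normals(row, c) = fc.normal[c];
    offsets[row] = fc.offset;
    for (int i = 0; i < d; ++i) {
      facetVerts(row, i) = fc.verts[i] + 1;
      vertexFlag[fc.verts[i]] = 1;
      for (int c = 0; c < d; ++c) S(i, c) = P(fc.verts[i], c) - interior[c];
    }
    vol += std::abs(arma::det(S));
    ++row;
  }
  vol /= factorial(d);

  IntegerVector verts;
  for (int i = 0; i < n; ++i) if (vertexFlag[i]) verts.push_back(i + 1);

  NumericVector interiorOut(d);
  for (int c = 0; c < d; ++c) interiorOut[c] = interior[c];

  return List::create(
      _["volume"] = vol,
      _["vertices"] = verts,
      _["normals"] = normals,
      _["offsets"] = offsets,
      _["facets"] = facetVerts,
      _["interior"] = interiorOut);
}
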