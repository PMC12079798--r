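// Vietoris-Rips persistent homology from a dense dissimilarity matrix.
//
// Strategy: enumerate all simplices of dimension <= maxdim + 1 whose diameter
// (largest pairwise dissimilarity) is <= the cutoff, sort them in filtration
// order, and reduce the boundary matrix over GF(2) with the standard pairing
// algorithm (sparse columns, pivot-to-column map).  Classes still alive at the
// cutoff receive death = cutoff.  Intended problem sizes are a few hundred
// points for dimension 1; fixtures are far smaller.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

struct Simplex {
  double diam;
  int dim;
  int v[4];  // vertex ids, ascending; unused slots = -1
};

// filtration order: diameter, then dimension (faces precede cofaces at equal
// diameter), then lexicographic on vertices for determinism
bool filt_less(const Simplex& a, const Simplex& b) {
  if (a.diam != b.diam) return a.diam < b.diam;
  if (a.dim != b.dim) return a.dim < b.dim;
  for (int i = 0; i <= a.dim; ++i)
    if (a.v[i] != b.v[i]) return a.v[i] < b.v[i];
  return false;
}

inline double diam_of(const std::vector<double>& D, int n, const int* v,
                      int k) {
  double d = 0.0;
  for (int i = 0; i <= k; ++i)
    for (int j = i + 1; j <= k; ++j)
      d = std::max(d, D[v[i] * n + v[j]]);
  return d;
}

}  // namespace

// [[Rcpp::export(name = ".rips_pairs_cpp")]]
DataFrame rips_pairs_cpp(NumericMatrix dist, int maxdim, double cutoff) {
  const int n = dist.nrow();
  if (dist.ncol() != n) stop("dissimilarity matrix must be square");
  std::vector<double> D(dist.begin(), dist.end());  // column-major, symmetric

  const int topdim = maxdim + 1;
  std::vector<Simplex> simplices;

  // vertices
  for (int i = 0; i < n; ++i) {
    Simplex s;
    s.diam = 0.0;
    s.dim = 0;
    s.v[0] = i;
    s.v[1] = s.v[2] = s.v[3] = -1;
    simplices.push_back(s);
  }
  // edges
  std::vector<std::pair<int, int> > edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (D[i * n + j] <= cutoff) {
        Simplex s;
        s.diam = D[i * n + j];
        s.dim = 1;
        s.v[0] = i;
        s.v[1] = j;
        s.v[2] = s.v[3] = -1;
        simplices.push_back(s);
        edges.push_back(std::make_pair(i, j));
      }
  // triangles
  if (topdim >= 2) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (D[i * n + j] > cutoff) continue;
        for (int k = j + 1; k < n; ++k) {
          if (D[i * n + k] > cutoff || D[j * n + k] > cutoff) continue;
          Simplex s;
          s.dim = 2;
          s.v[0] = i;
          s.v[1] = j;
          s.v[2] = k;
          s.v[3] = -1;
          s.diam = diam_of(D, n, s.v, 2);
          simplices.push_back(s);
        }
      }
  }
  // tetrahedra
  if (topdim >= 3) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (D[i * n + j] > cutoff) continue;
        for (int k = j + 1; k < n; ++k) {
          if (D[i * n + k] > cutoff || D[j * n + k] > cutoff) continue;
          for (int l = k + 1; l < n; ++l) {
            if (D[i * n + l] > cutoff || D[j * n + l] > cutoff ||
                D[k * n + l] > cutoff)
              continue;
            Simplex s;
            s.dim = 3;
            s.v[0] = i;
            s.v[1] = j;
            s.v[2] = k;
            s.v[3] = l;
            s.diam = diam_of(D, n, s.v, 3);
            simplices.push_back(s);
          }
        }
      }
  }
  if (topdim > 3) stop("dimensions above 2 are not supported");

  std::sort(simplices.begin(), simplices.end(), filt_less);
  const int m = (int)simplices.size();

  // vertex tuple -> filtration index, for boundary lookup
  std::map<std::vector<int>, int> index_of;
  for (int j = 0; j < m; ++j) {
    std::vector<int> key(simplices[j].v, simplices[j].v + simplices[j].dim + 1);
    index_of[key] = j;
  }

  std::vector<std::vector<int> > reduced(m);  // reduced columns, kept sparse
  std::vector<int> pivot_owner(m, -1);        // pivot row -> column index
  std::vector<char> paired(m, 0);

  std::vector<double> births, deaths;
  std::vector<int> dims;

  std::vector<int> col, tmp;
  for (int j = 0; j < m; ++j) {
    const Simplex& s = simplices[j];
    col.clear();
    if (s.dim > 0) {
      std::vector<int> face(s.dim);
      for (int drop = 0; drop <= s.dim; ++drop) {
        int t = 0;
        for (int i = 0; i <= s.dim; ++i)
          if (i != drop) face[t++] = s.v[i];
        col.push_back(index_of[face]);
      }
      std::sort(col.begin(), col.end());
    }
    // reduce: repeatedly add the column owning our current pivot
    while (!col.empty()) {
      int low = col.back();
      int owner = pivot_owner[low];
      if (owner < 0) break;
      // symmetric difference col ^= reduced[owner]
      const std::vector<int>& other = reduced[owner];
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(), other.begin(),
                                    other.end(), std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (!col.empty()) {
      int low = col.back();
      pivot_owner[low] = j;
      reduced[j] = col;
      paired[low] = 1;
      paired[j] = 1;
      double b = simplices[low].diam, d = s.diam;
      if (d > b) {  // zero-length bars are empty intervals, dropped
        births.push_back(b);
        deaths.push_back(d);
        dims.push_back(simplices[low].dim);
      }
    }
  }
  // unpaired creators: classes alive at the cutoff, death capped
  for (int j = 0; j < m; ++j) {
    if (!paired[j] && simplices[j].dim <= maxdim) {
      double b = simplices[j].diam;
      if (cutoff > b) {
        births.push_back(b);
        deaths.push_back(cutoff);
        dims.push_back(simplices[j].dim);
      }
    }
  }

  return DataFrame::create(Named("dimension") = dims, Named("birth") = births,
                           Named("death") = deaths);
}
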