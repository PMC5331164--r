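#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Assemble the global stiffness of a regular hex8 voxel lattice directly in
// deduplicated CSC form. All voxel elements are geometrically identical, so
// each element contributes one of a few precomputed 24x24 stiffness blocks
// selected by its phase; void voxels contribute nothing. Only nodes attached
// to at least one non-void element carry DOFs (3 per node). The sparsity
// pattern is the full 27-node neighbourhood of each active node, which is a
// tight superset of the true pattern on this lattice.
//
// phase: integer vector, length nx*ny*nz, x-fastest, codes 0..3 (0 = void)
// dims:  c(nx, ny, nz)
// ke:    list of 24x24 numeric matrices indexed by phase code (ke[[code]])
// Returns list(p, i, x, active_nodes) where active_nodes are 0-based lattice
// node ids in ascending order; DOF d of active node rank a is 3*a + d.
// [[Rcpp::export]]
List assemble_voxel_stiffness(IntegerVector phase, IntegerVector dims,
                              List ke) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nnx = nx + 1, nny = ny + 1, nnz = nz + 1;
  const int64_t nnodes = (int64_t)nnx * nny * nnz;
  const int64_t nelem = (int64_t)nx * ny * nz;

  // local node order: x fastest, then y, then z
  const int loff_i[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  const int loff_j[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int loff_k[8] = {0, 0, 0, 0, 1, 1, 1, 1};

  // unpack element stiffness blocks per phase (may hold R_NilValue slots)
  std::vector<const double*> kptr(ke.size() + 1, nullptr);
  for (int c = 1; c <= ke.size(); ++c) {
    if (c - 1 < ke.size() && !Rf_isNull(ke[c - 1])) {
      NumericMatrix m = ke[c - 1];
      if (m.nrow() != 24 || m.ncol() != 24)
        stop("element stiffness block must be 24x24");
      kptr[c] = REAL(m);
    }
  }

  // mark active nodes
  std::vector<char> active(nnodes, 0);
  {
    const int* ph = INTEGER(phase);
    int64_t e = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++e) {
          if (ph[e] == 0) continue;
          if (!kptr[ph[e]]) stop("missing material for a present phase");
          for (int a = 0; a < 8; ++a) {
            int64_t n = (int64_t)(i + loff_i[a]) +
                        (int64_t)nnx * ((j + loff_j[a]) +
                        (int64_t)nny * (k + loff_k[a]));
            active[n] = 1;
          }
        }
  }

  // rank active nodes (rank = position in ascending node-id order)
  std::vector<int> rank(nnodes, -1);
  int nact = 0;
  for (int64_t n = 0; n < nnodes; ++n)
    if (active[n]) rank[n] = nact++;
  if (nact == 0) stop("grid has no non-void elements");
  IntegerVector active_nodes(nact);
  {
    int a = 0;
    for (int64_t n = 0; n < nnodes; ++n)
      if (active[n]) active_nodes[a++] = (int)n;
  }

  const int64_t ndof = 3LL * nact;

  // column pattern: for each active node, its active neighbours within the
  // 27-neighbourhood in ascending node-id order (dz, dy, dx loops)
  std::vector<int64_t> colptr(ndof + 1, 0);
  std::vector<int> nbr_cnt(nact, 0);
  {
    int a = 0;
    for (int64_t n = 0; n < nnodes; ++n) {
      if (!active[n]) continue;
      int i = (int)(n % nnx), j = (int)((n / nnx) % nny), k = (int)(n / ((int64_t)nnx * nny));
      int cnt = 0;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nnx || jj >= nny || kk >= nnz)
              continue;
            int64_t m = (int64_t)ii + (int64_t)nnx * (jj + (int64_t)nny * kk);
            if (active[m]) ++cnt;
          }
      nbr_cnt[a] = cnt;
      ++a;
    }
    for (int aa = 0; aa < nact; ++aa) {
      int64_t rows = 3LL * nbr_cnt[aa];
      for (int d = 0; d < 3; ++d)
        colptr[3LL * aa + d + 1] = colptr[3LL * aa + d] + rows;
    }
  }
  int64_t nnzK = colptr[ndof];
  if (nnzK > INT64_C(2000000000)) stop("stiffness pattern too large");

  IntegerVector ri((R_xlen_t)nnzK);
  NumericVector xv((R_xlen_t)nnzK);
  std::fill(xv.begin(), xv.end(), 0.0);
  int* rip = INTEGER(ri);
  double* xvp = REAL(xv);

  // fill row indices (sorted within each column by construction)
  {
    int a = 0;
    for (int64_t n = 0; n < nnodes; ++n) {
      if (!active[n]) continue;
      int i = (int)(n % nnx), j = (int)((n / nnx) % nny), k = (int)(n / ((int64_t)nnx * nny));
      // gather neighbour dof ranks once
      std::vector<int> nbr;
      nbr.reserve(27);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nnx || jj >= nny || kk >= nnz)
              continue;
            int64_t m = (int64_t)ii + (int64_t)nnx * (jj + (int64_t)nny * kk);
            if (active[m]) nbr.push_back(rank[m]);
          }
      for (int d = 0; d < 3; ++d) {
        int64_t pos = colptr[3LL * a + d];
        for (size_t q = 0; q < nbr.size(); ++q)
          for (int r = 0; r < 3; ++r)
            rip[pos++] = 3 * nbr[q] + r;
      }
      ++a;
    }
  }

  // scatter element blocks
  {
    const int* ph = INTEGER(phase);
    int64_t e = 0;
    int enode_rank[8];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++e) {
          int code = ph[e];
          if (code == 0) continue;
          const double* K = kptr[code];
          for (int a = 0; a < 8; ++a) {
            int64_t n = (int64_t)(i + loff_i[a]) +
                        (int64_t)nnx * ((j + loff_j[a]) +
                        (int64_t)nny * (k + loff_k[a]));
            enode_rank[a] = rank[n];
          }
          for (int b = 0; b < 8; ++b) {         // column node
            for (int c = 0; c < 3; ++c) {        // column axis
              int64_t col = 3LL * enode_rank[b] + c;
              const int* lo = rip + colptr[col];
              const int* hi = rip + colptr[col + 1];
              for (int a = 0; a < 8; ++a) {      // row node
                int row0 = 3 * enode_rank[a];
                const int* it = std::lower_bound(lo, hi, row0);
                int64_t pos = colptr[col] + (it - lo);
                // Ke is column-major 24x24: entry (3a+r, 3b+c)
                const double* kc = K + 24 * (3 * b + c) + 3 * a;
                xvp[pos] += kc[0];
                xvp[pos + 1] += kc[1];
                xvp[pos + 2] += kc[2];
              }
            }
          }
        }
  }

  // colptr as double to avoid int overflow for very large patterns
  NumericVector pv(ndof + 1);
  for (int64_t c = 0; c <= ndof; ++c) pv[(R_xlen_t)c] = (double)colptr[c];

  return List::create(_["p"] = pv, _["i"] = ri, _["x"] = xv,
                      _["active_nodes"] = active_nodes,
                      _["ndof"] = (double)ndof);
}
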