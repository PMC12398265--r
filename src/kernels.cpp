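// Hot kernels: all-vs-all superposed RMSD between frame stacks, and
// Shrake-Rupley SASA. Both are exact (no approximations beyond the
// documented test-sphere resolution for SASA).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Superposed (Kabsch) RMSD between two flattened frame stacks.
// A: m x 3n, B: k x 3n; rows are frames with xyz interleaved
// (x1,y1,z1,x2,...). Returns m x k grid of minimal RMSD, in input units.
// [[Rcpp::export]]
arma::mat cpp_rmsd_grid(const arma::mat& A, const arma::mat& B) {
  const arma::uword n = A.n_cols / 3;
  const arma::uword m = A.n_rows, k = B.n_rows;

  // reshape & centre each frame once
  std::vector<arma::mat> fa(m), fb(k);
  arma::vec ga(m), gb(k); // squared norms of centred frames
  for (arma::uword i = 0; i < m; ++i) {
    arma::mat X(n, 3);
    for (arma::uword a = 0; a < n; ++a)
      for (arma::uword d = 0; d < 3; ++d) X(a, d) = A(i, 3 * a + d);
    X.each_row() -= arma::mean(X, 0);
    fa[i] = X; ga(i) = arma::accu(X % X);
  }
  for (arma::uword j = 0; j < k; ++j) {
    arma::mat X(n, 3);
    for (arma::uword a = 0; a < n; ++a)
      for (arma::uword d = 0; d < 3; ++d) X(a, d) = B(j, 3 * a + d);
    X.each_row() -= arma::mean(X, 0);
    fb[j] = X; gb(j) = arma::accu(X % X);
  }

  arma::mat out(m, k);
  arma::mat U, V; arma::vec s;
  for (arma::uword i = 0; i < m; ++i) {
    for (arma::uword j = 0; j < k; ++j) {
      arma::mat H = fa[i].t() * fb[j];        // 3x3 cross-covariance
      arma::svd(U, s, V, H);
      double d = arma::det(V * U.t());
      double tr = s(0) + s(1) + (d < 0 ? -s(2) : s(2));
      double msd = (ga(i) + gb(j) - 2.0 * tr) / double(n);
      out(i, j) = msd > 0 ? std::sqrt(msd) : 0.0;
    }
  }
  return out;
}

// Shrake-Rupley SASA, one conformation.
// coords: n x 3 (nm), radii: n (nm). Test points on a deterministic
// golden-spiral sphere. Neighbour search restricted to pairs within
// r_i + r_j + 2*probe. Returns per-atom accessible area in nm^2.
// [[Rcpp::export]]
arma::vec cpp_sasa(const arma::mat& coords, const arma::vec& radii,
                   const double probe, const int n_points) {
  const arma::uword n = coords.n_rows;
  const double golden = M_PI * (3.0 - std::sqrt(5.0));

  // unit sphere test points
  arma::mat sph(n_points, 3);
  for (int i = 0; i < n_points; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * i;
    sph(i, 0) = r * std::cos(phi);
    sph(i, 1) = r * std::sin(phi);
    sph(i, 2) = z;
  }

  arma::vec ext = radii + probe;          // expanded radii
  arma::vec out(n, arma::fill::zeros);

  for (arma::uword i = 0; i < n; ++i) {
    // neighbours that can occlude atom i
    std::vector<arma::uword> nb;
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i) continue;
      double cut = radii(i) + radii(j) + 2.0 * probe;
      double d2 = arma::accu(arma::square(coords.row(i) - coords.row(j)));
      if (d2 < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      arma::rowvec pt = coords.row(i) + ext(i) * sph.row(p);
      bool buried = false;
      for (arma::uword q = 0; q < nb.size(); ++q) {
        arma::uword j = nb[q];
        double d2 = arma::accu(arma::square(pt - coords.row(j)));
        if (d2 < ext(j) * ext(j)) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    out(i) = 4.0 * M_PI * ext(i) * ext(i) * double(acc) / double(n_points);
  }
  return out;
}
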