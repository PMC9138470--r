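// Hot loops: pairwise superposed RMSD over an atom selection, and
// residue-level heavy-atom contact statistics across frames.
// Coordinates use the bio3d layout: one frame per row, columns
// (x1, y1, z1, x2, y2, z2, ...), units nm.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Minimal Kabsch RMSD between two 3 x n coordinate blocks (already centred).
static double kabsch_rmsd(const arma::mat &a, const arma::mat &b) {
  arma::mat H = a * b.t();           // 3 x 3 covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  // proper rotation: flip the smallest singular value if det < 0
  double trace = (d < 0.0) ? (s(0) + s(1) - s(2)) : (s(0) + s(1) + s(2));
  double n = static_cast<double>(a.n_cols);
  double e = arma::accu(arma::square(a)) + arma::accu(arma::square(b));
  double msd = (e - 2.0 * trace) / n;
  return msd > 0.0 ? std::sqrt(msd) : 0.0;
}

static arma::mat frame_block(const NumericMatrix &xyz, int frame,
                             const IntegerVector &idx0) {
  arma::mat m(3, idx0.size());
  for (int k = 0; k < idx0.size(); ++k) {
    int c = 3 * idx0[k];
    m(0, k) = xyz(frame, c);
    m(1, k) = xyz(frame, c + 1);
    m(2, k) = xyz(frame, c + 2);
  }
  m.each_col() -= arma::mean(m, 1);
  return m;
}

// [[Rcpp::export]]
NumericMatrix cpp_rmsd_matrix(NumericMatrix xyz, IntegerVector idx0) {
  int nf = xyz.nrow();
  NumericMatrix out(nf, nf);
  std::vector<arma::mat> blocks;
  blocks.reserve(nf);
  for (int i = 0; i < nf; ++i) blocks.push_back(frame_block(xyz, i, idx0));
  for (int i = 0; i < nf; ++i) {
    for (int j = i + 1; j < nf; ++j) {
      double r = kabsch_rmsd(blocks[i], blocks[j]);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pair_rmsd(NumericMatrix xyz, IntegerVector frames_a,
                            IntegerVector frames_b, IntegerVector idx0) {
  int n = frames_a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    arma::mat a = frame_block(xyz, frames_a[i], idx0);
    arma::mat b = frame_block(xyz, frames_b[i], idx0);
    out[i] = kabsch_rmsd(a, b);
  }
  return out;
}

// Contact statistics between two residue sets.
// atom_res: 1-based residue index per atom; heavy: 1 = heavy atom.
// resA/resB: 1-based residue ids of the two regions.
// Returns per-frame contact counts (unordered residue pairs, pairs in
// both A and B counted once) and the weighted contact frequency matrix
// |A| x |B| (weights assumed normalised by the caller).
// [[Rcpp::export]]
List cpp_contact_stats(NumericMatrix xyz, IntegerVector atom_res,
                       LogicalVector heavy, IntegerVector resA,
                       IntegerVector resB, double cutoff, int min_seq_sep,
                       NumericVector weights) {
  int nf = xyz.nrow();
  int nA = resA.size(), nB = resB.size();
  double cut2 = cutoff * cutoff;

  // heavy-atom indices per residue of interest
  std::map<int, std::vector<int> > atoms;
  for (int r : resA) atoms[r];
  for (int r : resB) atoms[r];
  for (int a = 0; a < atom_res.size(); ++a) {
    if (!heavy[a]) continue;
    auto it = atoms.find(atom_res[a]);
    if (it != atoms.end()) it->second.push_back(a);
  }

  NumericVector counts(nf);
  NumericMatrix freq(nA, nB);

  for (int f = 0; f < nf; ++f) {
    double w = weights[f];
    int nfr = 0;
    for (int ia = 0; ia < nA; ++ia) {
      int ra = resA[ia];
      const std::vector<int> &aa = atoms[ra];
      for (int ib = 0; ib < nB; ++ib) {
        int rb = resB[ib];
        if (std::abs(ra - rb) < min_seq_sep) continue;
        if (ra == rb) continue;
        // unordered pairs when both residues belong to both sets
        bool dup = ra > rb &&
          std::binary_search(resA.begin(), resA.end(), rb) &&
          std::binary_search(resB.begin(), resB.end(), ra);
        const std::vector<int> &bb = atoms[rb];
        bool contact = false;
        for (size_t p = 0; p < aa.size() && !contact; ++p) {
          int ca = 3 * aa[p];
          for (size_t q = 0; q < bb.size(); ++q) {
            int cb = 3 * bb[q];
            double dx = xyz(f, ca) - xyz(f, cb);
            double dy = xyz(f, ca + 1) - xyz(f, cb + 1);
            double dz = xyz(f, ca + 2) - xyz(f, cb + 2);
            if (dx * dx + dy * dy + dz * dz < cut2) { contact = true; break; }
          }
        }
        if (contact) {
          freq(ia, ib) += w;
          if (!dup) ++nfr;
        }
      }
    }
    counts[f] = nfr;
  }
  return List::create(_["counts"] = counts, _["freq"] = freq);
}
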