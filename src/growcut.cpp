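#include <Rcpp.h>
using namespace Rcpp;

// GrowCut cellular automaton on a 3D scalar image, 26-connectivity,
// synchronous (Jacobi) updates. The image is expected on [0,1] so the
// attenuation g(d) = 1 - d is scale-free. Labels: 0 unlabeled, 1 foreground,
// 2 background. A neighbour q captures p iff g(|C_p - C_q|) * theta_q >
// theta_p (strict, so on ties the incumbent keeps its label). Seed voxels
// start at strength 1 and can never be captured.
// [[Rcpp::export]]
List growcut_core(NumericVector image, IntegerVector labels0,
                  NumericVector strength0, IntegerVector dim, int max_iters) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;

  std::vector<int> lab(labels0.begin(), labels0.end());
  std::vector<double> str(strength0.begin(), strength0.end());
  std::vector<int> nlab(n);
  std::vector<double> nstr(n);

  // offset order matters only for argmax ties among equal attackers; keep it
  // fixed (dx fastest) so an independent re-implementation can match exactly
  int offs[26][3];
  int m = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        offs[m][0] = dx; offs[m][1] = dy; offs[m][2] = dz; ++m;
      }

  // active-front bookkeeping: a voxel's next state depends only on its
  // 26-neighbourhood's current state, so after the first sweep only voxels
  // whose neighbourhood changed last sweep need re-examination; results are
  // identical to full synchronous sweeps.
  std::vector<char> active(n, 1), nactive(n, 0);

  int iter = 0;
  bool changed = (max_iters > 0);
  while (changed && iter < max_iters) {
    changed = false;
    std::fill(nactive.begin(), nactive.end(), 0);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int p = x + nx * (y + ny * z);
          if (!active[p]) { nlab[p] = lab[p]; nstr[p] = str[p]; continue; }
          int bl = lab[p];
          double bs = str[p];
          const double cp = image[p];
          for (int k = 0; k < 26; ++k) {
            const int qx = x + offs[k][0];
            const int qy = y + offs[k][1];
            const int qz = z + offs[k][2];
            if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
              continue;
            const int q = qx + nx * (qy + ny * qz);
            if (lab[q] == 0) continue;
            const double g = 1.0 - std::abs(cp - image[q]);
            const double attack = g * str[q];
            if (attack > bs) { bs = attack; bl = lab[q]; }
          }
          nlab[p] = bl;
          nstr[p] = bs;
          if (bl != lab[p] || bs != str[p]) {
            changed = true;
            // wake p and its neighbourhood for the next sweep
            for (int dz = -1; dz <= 1; ++dz)
              for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                  const int wx = x + dx, wy = y + dy, wz = z + dz;
                  if (wx < 0 || wx >= nx || wy < 0 || wy >= ny ||
                      wz < 0 || wz >= nz)
                    continue;
                  nactive[wx + nx * (wy + ny * wz)] = 1;
                }
          }
        }
    lab.swap(nlab);
    str.swap(nstr);
    active.swap(nactive);
    ++iter;
  }

  return List::create(
      _["labels"] = IntegerVector(lab.begin(), lab.end()),
      _["strengths"] = NumericVector(str.begin(), str.end()),
      _["iterations"] = iter,
      _["converged"] = !changed);
}

// Flood reachability inside a binary mask from a set of start voxels,
// 26-connectivity; used to keep only mask components touching the seeds.
// [[Rcpp::export]]
LogicalVector flood_reach(LogicalVector mask, LogicalVector start,
                          IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<char> vis(n, 0);
  std::vector<int> stack;
  stack.reserve(1024);
  for (int i = 0; i < n; ++i)
    if (start[i] && mask[i]) { vis[i] = 1; stack.push_back(i); }
  while (!stack.empty()) {
    const int p = stack.back();
    stack.pop_back();
    const int x = p % nx, y = (p / nx) % ny, z = p / (nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          const int qx = x + dx, qy = y + dy, qz = z + dz;
          if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
            continue;
          const int q = qx + nx * (qy + ny * qz);
          if (!vis[q] && mask[q]) { vis[q] = 1; stack.push_back(q); }
        }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = vis[i] != 0;
  return out;
}
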