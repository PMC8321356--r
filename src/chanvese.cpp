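#include <Rcpp.h>
using namespace Rcpp;

// Two-phase Chan-Vese evolution by semi-implicit Gauss-Seidel sweeps.
// Off-mask pixels are frozen (background phase) and excluded from the
// region means; they still act as neighbors with their fixed phi value.
// Convergence: RMS change of phi over the mask per sweep < tol.
//
// The piecewise-constant (binary-partition) energy of every visited state
// is tracked and the best state is returned: on noisy inputs the iteration
// can oscillate around a minimum without meeting the tolerance, and the
// final iterate is then not the best one seen. This also guarantees the
// returned mask never has higher energy than the initialization.
// [[Rcpp::export]]
List cv_evolve_cpp(NumericMatrix n, NumericMatrix phi0, LogicalMatrix mask,
                   double lambda1, double lambda2, double mu, double nu,
                   double dt, double tol, int n_max, double eps, double eta) {
    int nr = n.nrow(), nc = n.ncol();
    NumericMatrix phi = clone(phi0);
    double c1 = 0.0, c2 = 0.0;
    bool have_c = false;
    bool converged = false;
    int iter = 0;

    // region means over the binary partition {phi > 0} / {phi <= 0}:
    // c1, c2 are the average pixel values in the two regions, so a small
    // seeded defect phase keeps a mean of its own instead of being swamped
    // by a soft Heaviside weighting of the whole background
    auto update_means = [&]() {
        double s1 = 0, s2 = 0;
        long w1 = 0, w2 = 0;
        for (int j = 0; j < nc; ++j)
            for (int i = 0; i < nr; ++i) {
                if (!mask(i, j)) continue;
                if (phi(i, j) > 0) { s1 += n(i, j); ++w1; }
                else               { s2 += n(i, j); ++w2; }
            }
        // empty-phase guard: keep the previous mean if a phase vanishes
        if (w1 > 0) c1 = s1 / (double)w1; else if (!have_c) c1 = 0.0;
        if (w2 > 0) c2 = s2 / (double)w2; else if (!have_c) c2 = 0.0;
        have_c = true;
    };

    // binary-partition energy of the current state (diagnostic form:
    // 4-neighbor boundary-pair perimeter, defect phase = mask & phi > 0)
    auto state_energy = [&]() -> double {
        double fit = 0.0;
        long area = 0, per = 0;
        for (int j = 0; j < nc; ++j)
            for (int i = 0; i < nr; ++i) {
                bool in1 = mask(i, j) && phi(i, j) > 0;
                if (mask(i, j)) {
                    double d = n(i, j) - (in1 ? c1 : c2);
                    fit += (in1 ? lambda1 : lambda2) * d * d;
                }
                if (in1) ++area;
                if (i + 1 < nr) {
                    bool o = mask(i + 1, j) && phi(i + 1, j) > 0;
                    if (o != in1) ++per;
                }
                if (j + 1 < nc) {
                    bool o = mask(i, j + 1) && phi(i, j + 1) > 0;
                    if (o != in1) ++per;
                }
            }
        return fit + mu * (double)per + nu * (double)area;
    };

    // clamped (mirror) access
    auto P = [&](int i, int j) -> double {
        if (i < 0) i = 0; else if (i >= nr) i = nr - 1;
        if (j < 0) j = 0; else if (j >= nc) j = nc - 1;
        return phi(i, j);
    };

    update_means();
    NumericMatrix best_phi = clone(phi);
    double best_e = state_energy();
    double best_c1 = c1, best_c2 = c2;

    for (iter = 1; iter <= n_max; ++iter) {
        double diff2 = 0.0;
        long cnt = 0;
        for (int j = 0; j < nc; ++j) {
            for (int i = 0; i < nr; ++i) {
                if (!mask(i, j)) continue;
                double pc = phi(i, j);
                double pr_ = P(i, j + 1), pl = P(i, j - 1);
                double pd = P(i + 1, j), pu = P(i - 1, j);
                // curvature coefficients (eta inside the square root)
                double dxc, dyc;
                // A at (i, j): forward col diff, central row diff
                dyc = 0.5 * (pd - pu);
                double A_c = mu / std::sqrt(eta + (pr_ - pc) * (pr_ - pc) + dyc * dyc);
                // A at (i, j-1)
                dyc = 0.5 * (P(i + 1, j - 1) - P(i - 1, j - 1));
                double A_l = mu / std::sqrt(eta + (pc - pl) * (pc - pl) + dyc * dyc);
                // B at (i, j): central col diff, forward row diff
                dxc = 0.5 * (pr_ - pl);
                double B_c = mu / std::sqrt(eta + dxc * dxc + (pd - pc) * (pd - pc));
                // B at (i-1, j)
                dxc = 0.5 * (P(i - 1, j + 1) - P(i - 1, j - 1));
                double B_u = mu / std::sqrt(eta + dxc * dxc + (pc - pu) * (pc - pu));

                double delta = (eps / M_PI) / (eps * eps + pc * pc);
                double t1 = n(i, j) - c1, t2 = n(i, j) - c2;
                double num = pc + dt * delta *
                    (A_c * pr_ + A_l * pl + B_c * pd + B_u * pu
                     - nu - lambda1 * t1 * t1 + lambda2 * t2 * t2);
                double den = 1.0 + dt * delta * (A_c + A_l + B_c + B_u);
                double nv = num / den;
                diff2 += (nv - pc) * (nv - pc);
                ++cnt;
                phi(i, j) = nv;
            }
        }
        update_means();
        double e = state_energy();
        if (e < best_e - 1e-12) {
            best_e = e;
            best_phi = clone(phi);
            best_c1 = c1; best_c2 = c2;
        }
        if (cnt > 0 && std::sqrt(diff2 / (double)cnt) < tol) {
            converged = true;
            break;
        }
    }
    if (iter > n_max) iter = n_max;

    // Discrete polish of the best state: coordinate descent on the binary
    // mask against the same piecewise-constant energy (flip any pixel that
    // lowers it; region means refreshed between passes; each pass is
    // monotone). The continuous evolution can stall a few flips away from a
    // local optimum of the discrete energy, so a deterministic family of
    // restarts — the data/area threshold set of the evolved means, the
    // empty phase, two-sided quantile threshold sets, and the label
    // complement of the winner — is polished the same way and the best
    // state by energy is returned; the result therefore never has higher
    // energy than the best evolved state.
    auto memb_energy = [&](const std::vector<char>& m1v, double cc1,
                           double cc2) -> double {
        double fit = 0.0; long area = 0, per = 0;
        for (int j = 0; j < nc; ++j)
            for (int i = 0; i < nr; ++i) {
                bool a = m1v[j * nr + i] != 0;
                if (mask(i, j)) {
                    double d = n(i, j) - (a ? cc1 : cc2);
                    fit += (a ? lambda1 : lambda2) * d * d;
                }
                if (a) ++area;
                if (i + 1 < nr && (m1v[j * nr + i + 1] != 0) != a) ++per;
                if (j + 1 < nc && (m1v[(j + 1) * nr + i] != 0) != a) ++per;
            }
        return fit + mu * (double)per + nu * (double)area;
    };
    auto icm = [&](std::vector<char>& m1v, double& cc1, double& cc2) {
        const int di[] = {-1, 1, 0, 0}, dj[] = {0, 0, -1, 1};
        for (int pass = 0; pass < 50; ++pass) {
            long flips = 0;
            for (int j = 0; j < nc; ++j) {
                for (int i = 0; i < nr; ++i) {
                    if (!mask(i, j)) continue;
                    int nb = 0, k1 = 0;
                    for (int k = 0; k < 4; ++k) {
                        int r = i + di[k], c = j + dj[k];
                        if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
                        ++nb;
                        if (m1v[c * nr + r]) ++k1;
                    }
                    double t1 = n(i, j) - cc1, t2 = n(i, j) - cc2;
                    if (!m1v[j * nr + i]) {
                        double dE = lambda1 * t1 * t1 - lambda2 * t2 * t2
                            + nu + mu * (double)(nb - 2 * k1);
                        if (dE < -1e-12) { m1v[j * nr + i] = 1; ++flips; }
                    } else {
                        double dE = lambda2 * t2 * t2 - lambda1 * t1 * t1
                            - nu + mu * (double)(2 * k1 - nb);
                        if (dE < -1e-12) { m1v[j * nr + i] = 0; ++flips; }
                    }
                }
            }
            double s1 = 0, s2 = 0; long w1 = 0, w2 = 0;
            for (int j = 0; j < nc; ++j)
                for (int i = 0; i < nr; ++i) {
                    if (!mask(i, j)) continue;
                    if (m1v[j * nr + i]) { s1 += n(i, j); ++w1; }
                    else                 { s2 += n(i, j); ++w2; }
                }
            if (w1 > 0) cc1 = s1 / (double)w1;
            if (w2 > 0) cc2 = s2 / (double)w2;
            if (flips == 0) break;
        }
    };

    std::vector<char> cand(nr * nc, 0), best_m(nr * nc, 0);
    // candidate 1: best evolved state
    for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i)
            cand[j * nr + i] = mask(i, j) && best_phi(i, j) > 0;
    double cc1 = best_c1, cc2 = best_c2;
    icm(cand, cc1, cc2);
    best_m = cand;
    double bm_e = memb_energy(best_m, cc1, cc2);
    double bm_c1 = cc1, bm_c2 = cc2;
    // candidate 2: data/area threshold set of the evolved means
    for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
            double t1 = n(i, j) - best_c1, t2 = n(i, j) - best_c2;
            cand[j * nr + i] = mask(i, j) &&
                (lambda1 * t1 * t1 + nu < lambda2 * t2 * t2);
        }
    cc1 = best_c1; cc2 = best_c2;
    icm(cand, cc1, cc2);
    if (memb_energy(cand, cc1, cc2) < bm_e - 1e-12) {
        best_m = cand; bm_e = memb_energy(cand, cc1, cc2);
        bm_c1 = cc1; bm_c2 = cc2;
    }
    // candidate 3: empty defect phase
    std::fill(cand.begin(), cand.end(), 0);
    cc1 = best_c1; cc2 = best_c2;
    icm(cand, cc1, cc2);
    if (memb_energy(cand, cc1, cc2) < bm_e - 1e-12) {
        best_m = cand; bm_e = memb_energy(cand, cc1, cc2);
        bm_c1 = cc1; bm_c2 = cc2;
    }
    // candidates 4..6: upper-quantile threshold sets of the image values
    {
        std::vector<double> vals;
        vals.reserve((size_t)nr * nc);
        for (int j = 0; j < nc; ++j)
            for (int i = 0; i < nr; ++i)
                if (mask(i, j)) vals.push_back(n(i, j));
        std::sort(vals.begin(), vals.end());
        // nothing in the energy forces the defect phase to be the bright
        // one, so try both upper and lower threshold sets
        const double qs[] = {0.3, 0.5, 0.65, 0.8, 0.9, 0.97};
        for (double q : qs) {
            size_t pos = (size_t)(q * (double)(vals.size() - 1));
            double thr_hi = vals[pos];
            double thr_lo = vals[vals.size() - 1 - pos];
            for (int side = 0; side < 2; ++side) {
                for (int j = 0; j < nc; ++j)
                    for (int i = 0; i < nr; ++i)
                        cand[j * nr + i] = mask(i, j) &&
                            (side == 0 ? n(i, j) > thr_hi
                                       : n(i, j) < thr_lo);
                cc1 = best_c1; cc2 = best_c2;
                icm(cand, cc1, cc2);
                if (memb_energy(cand, cc1, cc2) < bm_e - 1e-12) {
                    best_m = cand; bm_e = memb_energy(cand, cc1, cc2);
                    bm_c1 = cc1; bm_c2 = cc2;
                }
            }
        }
    }

    // candidate 7: label complement of the winner so far — the two fit
    // terms are symmetric (only the area term breaks the tie), and the
    // evolution can settle on the majority side of the right partition
    {
        for (size_t k = 0; k < cand.size(); ++k) cand[k] = 0;
        for (int j = 0; j < nc; ++j)
            for (int i = 0; i < nr; ++i)
                cand[j * nr + i] = mask(i, j) && !best_m[j * nr + i];
        cc1 = bm_c2; cc2 = bm_c1;
        icm(cand, cc1, cc2);
        if (memb_energy(cand, cc1, cc2) < bm_e - 1e-12) {
            best_m = cand; bm_e = memb_energy(cand, cc1, cc2);
            bm_c1 = cc1; bm_c2 = cc2;
        }
    }

    // write the winning membership back into phi (keep magnitudes where the
    // sign already agrees, so the field stays informative)
    phi = best_phi;
    for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
            if (!mask(i, j)) continue;
            bool m = best_m[j * nr + i] != 0;
            if (m && !(phi(i, j) > 0)) phi(i, j) = 1.0;
            else if (!m && phi(i, j) > 0) phi(i, j) = -1.0;
        }
    best_e = bm_e;
    best_c1 = bm_c1; best_c2 = bm_c2;
    best_phi = phi;

    return List::create(_["phi"] = best_phi, _["c1"] = best_c1,
                        _["c2"] = best_c2, _["energy"] = best_e,
                        _["iterations"] = iter, _["converged"] = converged);
}

// Connected-component labeling (4- or 8-connectivity) by iterative flood
// fill in row-major scan order, so label 1 starts at the top-left-most
// (row-major) foreground pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<std::pair<int, int>> stack;
    int next = 0;
    const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
    const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
    const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
    int nn = (connectivity == 8) ? 8 : 4;
    const int* dr = (connectivity == 8) ? dr8 : dr4;
    const int* dc = (connectivity == 8) ? dc8 : dc4;

    for (int i = 0; i < nr; ++i) {        // row-major scan
        for (int j = 0; j < nc; ++j) {
            if (!mask(i, j) || lab(i, j) != 0) continue;
            ++next;
            stack.clear();
            stack.push_back({i, j});
            lab(i, j) = next;
            while (!stack.empty()) {
                auto [r, c] = stack.back();
                stack.pop_back();
                for (int k = 0; k < nn; ++k) {
                    int r2 = r + dr[k], c2 = c + dc[k];
                    if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
                    if (mask(r2, c2) && lab(r2, c2) == 0) {
                        lab(r2, c2) = next;
                        stack.push_back({r2, c2});
                    }
                }
            }
        }
    }
    return lab;
}
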