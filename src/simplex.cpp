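// Dense two-phase primal simplex with Bland's anti-cycling rule.
//
// Solves   min c'x   s.t.  A x {<=,=,>=} b,  lb <= x <= ub
// after conversion to computational standard form (shifted/split
// variables, slack/surplus/artificial columns).  Problem sizes in this
// package are small (at most a few hundred rows/columns), so a full
// tableau with Bland's rule is both fast enough and guaranteed to
// terminate; no basis factorization is needed.
//
// Status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PIV_TOL = 1e-9;    // pivot / reduced-cost tolerance
static const double FEAS_TOL = 1e-7;   // phase-1 objective tolerance
static const double BIGBND = 1e29;     // |bound| beyond this is "infinite"

// One simplex phase on tableau T (m x (N+1), last col = rhs) with
// reduced-cost row `cost` (length N+1, last entry = -objective).
// `allowed[j]` marks columns permitted to enter the basis.
//
// Pivoting: Dantzig rule (most negative reduced cost) with the most
// stable pivot among minimum-ratio rows; after a long degenerate stall
// (no objective change) it falls back to Bland's rule, which cannot
// cycle, until progress resumes.  Pivots below STAB_TOL are avoided
// unless nothing better exists.
//
// Returns 0 on optimality, 2 on unboundedness, 3 on iteration limit.
static const double STAB_TOL = 1e-7;   // preferred minimum pivot magnitude

static int simplex_phase(mat& T, rowvec& cost, uvec& basis,
                         const std::vector<bool>& allowed)
{
    const uword m = T.n_rows;
    const uword N = T.n_cols - 1;
    const uword maxit = 50000 + 200 * (m + N);
    const uword stall_limit = 2 * (m + N) + 50;

    uword stall = 0;
    bool bland = false;
    double last_obj = -cost[N];

    for (uword it = 0; it < maxit; ++it) {
        // entering column
        uword enter = N;
        if (bland) {
            for (uword j = 0; j < N; ++j) {
                if (allowed[j] && cost[j] < -PIV_TOL) { enter = j; break; }
            }
        } else {
            double most = -PIV_TOL;
            for (uword j = 0; j < N; ++j) {
                if (allowed[j] && cost[j] < most) { most = cost[j]; enter = j; }
            }
        }
        if (enter == N) return 0;  // optimal

        // minimum-ratio test, preferring pivots of decent magnitude
        double piv_floor = STAB_TOL;
        uword leave = m;
        for (int pass = 0; pass < 2 && leave == m; ++pass) {
            double best = datum::inf;
            for (uword i = 0; i < m; ++i) {
                double a = T(i, enter);
                if (a > piv_floor) {
                    double ratio = T(i, N) / a;
                    if (ratio < best) best = ratio;
                }
            }
            if (std::isfinite(best)) {
                double tie = PIV_TOL * (1.0 + std::fabs(best));
                for (uword i = 0; i < m; ++i) {
                    double a = T(i, enter);
                    if (a > piv_floor && T(i, N) / a <= best + tie) {
                        if (leave == m) { leave = i; continue; }
                        if (bland) {
                            if (basis[i] < basis[leave]) leave = i;
                        } else if (a > T(leave, enter)) {
                            leave = i;  // most stable pivot among ties
                        }
                    }
                }
            }
            piv_floor = PIV_TOL;  // second pass: accept small pivots
        }
        if (leave == m) return 2;  // unbounded direction

        // pivot on (leave, enter)
        T.row(leave) /= T(leave, enter);
        for (uword i = 0; i < m; ++i) {
            if (i != leave) {
                double f = T(i, enter);
                if (f != 0.0) T.row(i) -= f * T.row(leave);
            }
        }
        double f = cost[enter];
        if (f != 0.0) cost -= f * T.row(leave);
        basis[leave] = enter;

        // degeneracy bookkeeping: switch to Bland during long stalls
        double obj = -cost[N];
        if (obj < last_obj - 1e-12 * (1.0 + std::fabs(last_obj))) {
            last_obj = obj;
            stall = 0;
            bland = false;
        } else if (++stall > stall_limit) {
            bland = true;
        }
    }
    return 3;
}

// [[Rcpp::export(name = ".lp_simplex_cpp")]]
Rcpp::List lp_simplex_cpp(const arma::mat& A, const arma::vec& b,
                          const arma::ivec& sense, const arma::vec& c,
                          const arma::vec& lb, const arma::vec& ub)
{
    const uword m0 = A.n_rows;
    const uword nv = A.n_cols;

    // ---- expand variables to y >= 0 -----------------------------------
    // For each original variable record how it maps to expanded columns:
    //   kind 0: x = lb + y           (lb finite)
    //   kind 1: x = ub - y           (lb = -inf, ub finite)
    //   kind 2: x = y1 - y2          (free)
    std::vector<int> kind(nv);
    std::vector<uword> col1(nv), col2(nv);
    std::vector<double> offset(nv, 0.0), cap(nv, datum::inf);
    uword ny = 0;
    for (uword j = 0; j < nv; ++j) {
        bool lf = lb[j] > -BIGBND, uf = ub[j] < BIGBND;
        if (lf) {
            kind[j] = 0; offset[j] = lb[j]; col1[j] = ny++;
            if (uf) cap[j] = ub[j] - lb[j];
        } else if (uf) {
            kind[j] = 1; offset[j] = ub[j]; col1[j] = ny++;
        } else {
            kind[j] = 2; col1[j] = ny++; col2[j] = ny++;
        }
    }

    // upper-bound rows y <= cap for doubly bounded variables
    uword n_ub = 0;
    for (uword j = 0; j < nv; ++j) if (cap[j] < datum::inf) ++n_ub;

    const uword m = m0 + n_ub;
    mat As(m, ny, fill::zeros);
    vec bs(m, fill::zeros);
    ivec sn(m);
    vec cy(ny, fill::zeros);

    for (uword j = 0; j < nv; ++j) {
        switch (kind[j]) {
        case 0:
            As.submat(0, col1[j], m0 - 1, col1[j]) = A.col(j);
            cy[col1[j]] = c[j];
            break;
        case 1:
            As.submat(0, col1[j], m0 - 1, col1[j]) = -A.col(j);
            cy[col1[j]] = -c[j];
            break;
        case 2:
            As.submat(0, col1[j], m0 - 1, col1[j]) = A.col(j);
            As.submat(0, col2[j], m0 - 1, col2[j]) = -A.col(j);
            cy[col1[j]] = c[j];
            cy[col2[j]] = -c[j];
            break;
        }
    }
    for (uword i = 0; i < m0; ++i) {
        double rhs = b[i];
        for (uword j = 0; j < nv; ++j) rhs -= A(i, j) * offset[j];
        bs[i] = rhs;
        sn[i] = sense[i];
    }
    {
        uword r = m0;
        for (uword j = 0; j < nv; ++j) {
            if (cap[j] < datum::inf) {
                As(r, col1[j]) = 1.0;
                bs[r] = cap[j];
                sn[r] = -1;  // <=
                ++r;
            }
        }
    }

    // equilibrate rows (unit max coefficient) and normalize to bs >= 0
    for (uword i = 0; i < m; ++i) {
        double sc = norm(As.row(i), "inf");
        if (sc > PIV_TOL) { As.row(i) /= sc; bs[i] /= sc; }
        if (bs[i] < 0) { As.row(i) *= -1.0; bs[i] *= -1.0; sn[i] *= -1; }
    }

    // ---- slack / surplus / artificial columns -------------------------
    uword n_slack = 0, n_art = 0;
    for (uword i = 0; i < m; ++i) {
        if (sn[i] == -1) ++n_slack;               // <= : slack (basic)
        else if (sn[i] == 1) { ++n_slack; ++n_art; } // >= : surplus + artificial
        else ++n_art;                              // = : artificial
    }
    const uword N = ny + n_slack + n_art;
    mat T(m, N + 1, fill::zeros);
    T.cols(0, ny - 1) = As;
    T.col(N) = bs;

    uvec basis(m);
    std::vector<bool> is_art(N, false);
    {
        uword js = ny, ja = ny + n_slack;
        for (uword i = 0; i < m; ++i) {
            if (sn[i] == -1) {
                T(i, js) = 1.0; basis[i] = js; ++js;
            } else if (sn[i] == 1) {
                T(i, js) = -1.0; ++js;
                T(i, ja) = 1.0; is_art[ja] = true; basis[i] = ja; ++ja;
            } else {
                T(i, ja) = 1.0; is_art[ja] = true; basis[i] = ja; ++ja;
            }
        }
    }

    // ---- phase 1 ------------------------------------------------------
    std::vector<bool> allowed(N, true);
    rowvec cost(N + 1, fill::zeros);
    if (n_art > 0) {
        for (uword j = 0; j < N; ++j) if (is_art[j]) cost[j] = 1.0;
        for (uword i = 0; i < m; ++i)
            if (is_art[basis[i]]) cost -= T.row(i);
        int st = simplex_phase(T, cost, basis, allowed);
        if (st == 3) return Rcpp::List::create(Rcpp::Named("status") = 3);
        double p1 = -cost[N];
        if (p1 > FEAS_TOL)
            return Rcpp::List::create(Rcpp::Named("status") = 1);
        // drive remaining artificials out of the basis, drop redundant rows
        std::vector<uword> keep;
        for (uword i = 0; i < m; ++i) {
            if (!is_art[basis[i]]) { keep.push_back(i); continue; }
            uword piv = N;
            for (uword j = 0; j < N; ++j) {
                if (!is_art[j] && std::fabs(T(i, j)) > PIV_TOL) { piv = j; break; }
            }
            if (piv == N) continue;  // redundant row: drop
            T.row(i) /= T(i, piv);
            for (uword k = 0; k < m; ++k) {
                if (k != i) {
                    double f = T(k, piv);
                    if (f != 0.0) T.row(k) -= f * T.row(i);
                }
            }
            basis[i] = piv;
            keep.push_back(i);
        }
        if (keep.size() < m) {
            uvec ki(keep.size());
            for (uword i = 0; i < keep.size(); ++i) ki[i] = keep[i];
            T = T.rows(ki);
            basis = basis(ki);
        }
        for (uword j = 0; j < N; ++j) if (is_art[j]) allowed[j] = false;
    }

    // ---- phase 2 ------------------------------------------------------
    const uword m2 = T.n_rows;
    rowvec cost2(N + 1, fill::zeros);
    cost2.cols(0, ny - 1) = cy.t();
    for (uword i = 0; i < m2; ++i) {
        double cb = (basis[i] < ny) ? cy[basis[i]] : 0.0;
        if (cb != 0.0) cost2 -= cb * T.row(i);
    }
    int st = simplex_phase(T, cost2, basis, allowed);
    if (st == 3) return Rcpp::List::create(Rcpp::Named("status") = 3);
    if (st == 2) return Rcpp::List::create(Rcpp::Named("status") = 2);

    // ---- recover solution --------------------------------------------
    vec y(N, fill::zeros);
    for (uword i = 0; i < m2; ++i) y[basis[i]] = T(i, N);
    vec x(nv);
    for (uword j = 0; j < nv; ++j) {
        switch (kind[j]) {
        case 0: x[j] = offset[j] + y[col1[j]]; break;
        case 1: x[j] = offset[j] - y[col1[j]]; break;
        default: x[j] = y[col1[j]] - y[col2[j]];
        }
    }
    double obj = dot(c, x);
    return Rcpp::List::create(Rcpp::Named("status") = 0,
                              Rcpp::Named("objective") = obj,
                              Rcpp::Named("x") = x);
}
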