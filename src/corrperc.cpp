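#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Triangular lattice realized as a brick-offset grid of 2:1 rectangles
// stacked in columns along the signaling (y = row) direction: columns with
// odd 0-based index are shifted down by half a cell length.  Every cell
// then has a directly-above and directly-below neighbor in its own column
// plus two overlapping neighbors in each adjacent column.  Six lattice
// directions; the row step into an adjacent column depends on the parity
// of the source column.  k: 0=up, 1=down, 2=right-up, 3=right-down,
// 4=left-up, 5=left-down.
static inline void dir_target(int i, int j, int k, int &ti, int &tj) {
    const int p = j & 1; // 1 in shifted (odd) columns
    switch (k) {
    case 0: ti = i - 1;     tj = j;     break;
    case 1: ti = i + 1;     tj = j;     break;
    case 2: ti = i - 1 + p; tj = j + 1; break;
    case 3: ti = i + p;     tj = j + 1; break;
    case 4: ti = i - 1 + p; tj = j - 1; break;
    default: ti = i + p;    tj = j - 1; break;
    }
}

static inline bool in_bounds(int i, int j, int nr, int nc) {
    return i >= 0 && i < nr && j >= 0 && j < nc;
}

// 0-based in-bounds six-neighborhood of (i, j); deterministic k order.
// [[Rcpp::export]]
IntegerMatrix neighbor_sites_cpp(int i, int j, int n_rows, int n_cols) {
    if (!in_bounds(i, j, n_rows, n_cols))
        stop("site (%d, %d) outside a %d x %d lattice", i, j, n_rows, n_cols);
    std::vector<int> ri, rj;
    for (int k = 0; k < 6; ++k) {
        int ti, tj;
        dir_target(i, j, k, ti, tj);
        if (in_bounds(ti, tj, n_rows, n_cols)) { ri.push_back(ti); rj.push_back(tj); }
    }
    IntegerMatrix out(ri.size(), 2);
    for (size_t m = 0; m < ri.size(); ++m) { out(m, 0) = ri[m]; out(m, 1) = rj[m]; }
    return out;
}

struct DSU {
    std::vector<int> parent, rank_;
    explicit DSU(int n) : parent(n), rank_(n, 0) {
        for (int i = 0; i < n; ++i) parent[i] = i;
    }
    int find(int x) {
        while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
        return x;
    }
    void unite(int a, int b) {
        a = find(a); b = find(b);
        if (a == b) return;
        if (rank_[a] < rank_[b]) std::swap(a, b);
        parent[b] = a;
        if (rank_[a] == rank_[b]) ++rank_[a];
    }
};

// Union-find labeling of on-cells under the six-neighbor relation.
// Returns component labels (0 = off), sizes sorted by label, spanning flag
// (some component touches both row 0 and row n_rows-1).
// [[Rcpp::export]]
List label_clusters_cpp(IntegerMatrix states) {
    const int nr = states.nrow(), nc = states.ncol();
    const int n = nr * nc;
    DSU dsu(n);
    for (int i = 0; i < nr; ++i) {
        for (int j = 0; j < nc; ++j) {
            if (!states(i, j)) continue;
            for (int k = 0; k < 6; ++k) {
                int ti, tj;
                dir_target(i, j, k, ti, tj);
                if (in_bounds(ti, tj, nr, nc) && states(ti, tj))
                    dsu.unite(i + nr * j, ti + nr * tj);
            }
        }
    }
    std::vector<int> label(n, 0);
    std::vector<int> root2lab;
    std::vector<int> sizes;
    std::vector<bool> top, bottom;
    IntegerMatrix labels(nr, nc);
    std::vector<int> rootmap(n, -1);
    int next_lab = 0;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (!states(i, j)) continue;
            int root = dsu.find(i + nr * j);
            if (rootmap[root] < 0) {
                rootmap[root] = next_lab++;
                sizes.push_back(0);
                top.push_back(false);
                bottom.push_back(false);
            }
            int lab = rootmap[root];
            labels(i, j) = lab + 1;
            ++sizes[lab];
            if (i == 0) top[lab] = true;
            if (i == nr - 1) bottom[lab] = true;
        }
    }
    bool spanning = false;
    for (int l = 0; l < next_lab; ++l)
        if (top[l] && bottom[l]) { spanning = true; break; }
    return List::create(_["sizes"] = wrap(sizes),
                        _["spanning"] = spanning,
                        _["labels"] = labels);
}

// 8-connected labeling of a binary pixel field (image clusters).
// [[Rcpp::export]]
IntegerMatrix label_pixels8_cpp(IntegerMatrix binary) {
    const int nr = binary.nrow(), nc = binary.ncol();
    DSU dsu(nr * nc);
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (!binary(i, j)) continue;
            for (int dj = -1; dj <= 1; ++dj) {
                for (int di = -1; di <= 1; ++di) {
                    if (!di && !dj) continue;
                    int ti = i + di, tj = j + dj;
                    if (in_bounds(ti, tj, nr, nc) && binary(ti, tj))
                        dsu.unite(i + nr * j, ti + nr * tj);
                }
            }
        }
    }
    IntegerMatrix labels(nr, nc);
    std::vector<int> rootmap(nr * nc, -1);
    int next_lab = 0;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (!binary(i, j)) continue;
            int root = dsu.find(i + nr * j);
            if (rootmap[root] < 0) rootmap[root] = next_lab++;
            labels(i, j) = rootmap[root] + 1;
        }
    }
    return labels;
}

// Median filter for binary fields over a disc of the given pixel radius.
// Truncated at edges; strict majority of the in-window pixels, ties keep
// the center value (the exact median is then 1/2).
// [[Rcpp::export]]
IntegerMatrix median_filter_binary_cpp(IntegerMatrix x, double radius) {
    const int nr = x.nrow(), nc = x.ncol();
    const int ir = (int)std::floor(radius);
    const double r2 = radius * radius;
    std::vector<int> di, dj;
    for (int a = -ir; a <= ir; ++a)
        for (int b = -ir; b <= ir; ++b)
            if (a * a + b * b <= r2) { di.push_back(a); dj.push_back(b); }
    IntegerMatrix out(nr, nc);
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            int ones = 0, valid = 0;
            for (size_t m = 0; m < di.size(); ++m) {
                int ti = i + di[m], tj = j + dj[m];
                if (!in_bounds(ti, tj, nr, nc)) continue;
                ++valid;
                ones += x(ti, tj);
            }
            if (2 * ones > valid) out(i, j) = 1;
            else if (2 * ones == valid) out(i, j) = x(i, j);
            else out(i, j) = 0;
        }
    }
    return out;
}

struct Ev {
    double t;
    int id;
    long seq;
};
struct EvCmp {
    bool operator()(const Ev &a, const Ev &b) const { return a.t > b.t; }
};

// Event-driven correlated growth.  The top row (row 0) is seeded i.i.d.
// Bernoulli(phi_row[0]); cells divide at Gaussian intervals (mean
// tau_mean_off for off-cells, tau_mean_on for on-cells, sd tau_sd,
// resampled while <= 0); the earliest-dividing mother places its daughter
// uniformly among eligible neighbor sites (empty, or occupied by a cell
// that can be pushed one step further along the same lattice direction
// into an empty site).  The daughter's state is Bernoulli with probability
// q_row/r_row at the daughter's row given an on/off mother.  Displaced
// cells keep their state and pending division time.  Stops when the grid
// is full.  Uses the R RNG (respects set.seed).
// [[Rcpp::export]]
List grow_lattice_cpp(int gen_rows, int n_cols,
                      NumericVector phi_row,
                      NumericVector q_row, NumericVector r_row,
                      double tau_mean_off, double tau_mean_on,
                      double tau_sd, int max_stall_rounds = 50) {
    const int nr = gen_rows, nc = n_cols, n_total = nr * nc;
    if ((int)phi_row.size() != nr || (int)q_row.size() != nr || (int)r_row.size() != nr)
        stop("phi_row, q_row, r_row must have one entry per generated row");
    std::vector<int> grid(n_total, 0); // cell id + 1, 0 = empty
    std::vector<int> crow, ccol, cstate;
    std::vector<double> ctime;
    std::vector<long> cseq;
    std::priority_queue<Ev, std::vector<Ev>, EvCmp> pq;
    std::vector<int> lin_m, lin_d;
    std::vector<double> lin_t;

    auto tau_draw = [&](int state) {
        double mean = state ? tau_mean_on : tau_mean_off;
        if (tau_sd <= 0.0) return mean;
        double x;
        do { x = R::rnorm(mean, tau_sd); } while (x <= 0.0);
        return x;
    };
    auto add_cell = [&](int i, int j, int state, double next_t) {
        crow.push_back(i); ccol.push_back(j); cstate.push_back(state);
        ctime.push_back(next_t); cseq.push_back(0);
        int id = (int)crow.size() - 1;
        grid[i + nr * j] = id + 1;
        pq.push(Ev{next_t, id, 0});
        return id;
    };

    int filled = 0;
    for (int j = 0; j < nc; ++j) {
        int s = (unif_rand() < phi_row[0]) ? 1 : 0;
        add_cell(0, j, s, tau_draw(s));
        ++filled;
    }

    long stalls = 0;
    const long stall_cap = (long)max_stall_rounds * n_total;
    while (filled < n_total) {
        if (pq.empty()) stop("growth halted with an unfilled grid");
        Ev ev = pq.top(); pq.pop();
        int m = ev.id;
        if (ev.seq != cseq[m] || ev.t != ctime[m]) continue; // stale entry
        int mi = crow[m], mj = ccol[m];
        // eligible placements: target site, displacement flag
        int ei[6], ej[6], pi[6], pj[6];
        bool disp[6];
        int n_elig = 0;
        for (int k = 0; k < 6; ++k) {
            int t1i, t1j;
            dir_target(mi, mj, k, t1i, t1j);
            if (!in_bounds(t1i, t1j, nr, nc)) continue;
            if (!grid[t1i + nr * t1j]) {
                ei[n_elig] = t1i; ej[n_elig] = t1j; disp[n_elig] = false;
                ++n_elig;
            } else {
                int t2i, t2j;
                dir_target(t1i, t1j, k, t2i, t2j);
                if (in_bounds(t2i, t2j, nr, nc) && !grid[t2i + nr * t2j]) {
                    ei[n_elig] = t1i; ej[n_elig] = t1j;
                    pi[n_elig] = t2i; pj[n_elig] = t2j; disp[n_elig] = true;
                    ++n_elig;
                }
            }
        }
        if (n_elig == 0) {
            // Deferred division.  Occupancy only ever grows, so a mother
            // with no eligible site can never regain one: dropping it from
            // the queue is an exact shortcut for redrawing its division
            // time forever.
            if (++stalls > stall_cap)
                stop("growth stalled: no eligible site after %ld deferred divisions", stalls);
            continue;
        }
        int pick = (int)(unif_rand() * n_elig);
        if (pick == n_elig) pick = n_elig - 1;
        if (disp[pick]) {
            int occ = grid[ei[pick] + nr * ej[pick]] - 1;
            grid[pi[pick] + nr * pj[pick]] = occ + 1;
            grid[ei[pick] + nr * ej[pick]] = 0;
            crow[occ] = pi[pick]; ccol[occ] = pj[pick];
        }
        int di = ei[pick], dj = ej[pick];
        double p_on = cstate[m] ? q_row[di] : r_row[di];
        int ds = (unif_rand() < p_on) ? 1 : 0;
        add_cell(di, dj, ds, ev.t + tau_draw(ds));
        ++filled;
        lin_m.push_back(cstate[m]);
        lin_d.push_back(ds);
        lin_t.push_back(ev.t);
        cseq[m] += 1;
        ctime[m] = ev.t + tau_draw(cstate[m]);
        pq.push(Ev{ctime[m], m, cseq[m]});
        if ((filled & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }

    IntegerMatrix states(nr, nc);
    for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
            int id = grid[i + nr * j] - 1;
            states(i, j) = cstate[id];
        }
    int nl = (int)lin_m.size();
    IntegerMatrix lineage(nl, 2);
    NumericVector times(nl);
    for (int a = 0; a < nl; ++a) {
        lineage(a, 0) = lin_m[a];
        lineage(a, 1) = lin_d[a];
        times[a] = lin_t[a];
    }
    return List::create(_["states"] = states,
                        _["lineage"] = lineage,
                        _["times"] = times);
}
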