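#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact Gillespie simulation of a two-type (sensitive/resistant), two-phase
// linear birth-death process with full lineage-tree recording.
//
// Tree encoding (1-based indices on the R side):
//   parent[i]  index of the parent node, 0 for the root
//   nmut[i]    Poisson(m) neutral mutations on the branch leading into node i
//   type[i]    0 sensitive, 1 resistant
//   founder[i] TRUE where a sensitive parent produced this resistant daughter
//   btime[i]   time at which the cell came into existence
//   alive[i]   TRUE for cells alive when the simulation stopped
// Nodes are created in chronological order, so parent[i] < i always holds;
// the statistic extractors below rely on that ordering.
//
// det_rule: 1 = stop phase 1 at first passage of size det_value,
//           2 = stop phase 1 at fixed time det_value.
// end_rule: 0 = no phase 2; 1 = phase 2 for fixed duration end_value;
//           2 = phase 2 until first passage of total size end_value.
// Phase switches at a fixed time use the memorylessness of the exponential
// clock: the pending waiting time is discarded at the boundary.

// [[Rcpp::export]]
List cpp_simulate_tree(NumericVector phase1, NumericVector phase2,
                       double m, double nu,
                       int det_rule, double det_value,
                       int end_rule, double end_value,
                       double max_population, double max_events) {
    if (phase1.size() != 4 || phase2.size() != 4)
        stop("rate vectors must be (b_s, d_s, b_r, d_r)");

    double bs = phase1[0], ds = phase1[1], br = phase1[2], dr = phase1[3];

    std::vector<int> parent(1, 0), nmut(1, 0), type(1, 0);
    std::vector<char> alive(1, 1), founder(1, 0);
    std::vector<double> btime(1, 0.0);

    // per-type alive lists with O(1) swap-removal
    std::vector<int> liveS, liveR;
    std::vector<int> poslist(1, 0);
    liveS.push_back(0);

    double t = 0.0, t_detect = NA_REAL;
    int phase = 1;
    bool extinct = false;
    double nev = 0.0;

    auto removeLive = [&](int node) {
        std::vector<int> &lst = type[node] == 0 ? liveS : liveR;
        int p = poslist[node];
        int last = lst.back();
        lst[p] = last;
        poslist[last] = p;
        lst.pop_back();
    };
    auto addLive = [&](int node) {
        std::vector<int> &lst = type[node] == 0 ? liveS : liveR;
        poslist[node] = (int) lst.size();
        lst.push_back(node);
    };

    auto enterPhase2 = [&]() {
        t_detect = t;
        phase = 2;
        bs = phase2[0]; ds = phase2[1]; br = phase2[2]; dr = phase2[3];
    };

    if (det_rule == 1 && det_value <= 1) {
        // detection size of one: the ancestor itself
        if (end_rule == 0)
            det_rule = -1;  // nothing to simulate
        else
            enterPhase2();
    }

    bool done = (det_rule == -1);
    while (!done) {
        R_CheckUserInterrupt();
        double nS = (double) liveS.size(), nR = (double) liveR.size();
        double ntot = nS + nR;
        if (ntot == 0.0) {
            if (phase == 1) { extinct = true; }
            break;
        }
        double totrate = nS * (bs + ds) + nR * (br + dr);
        if (totrate <= 0.0) {
            // frozen population (all rates zero for the types present)
            if (phase == 1 && det_rule == 2) {
                t = det_value;
                if (end_rule == 0) break;
                enterPhase2();
                continue;
            }
            if (phase == 2 && end_rule == 1) {
                t = t_detect + end_value;
                break;
            }
            stop("all event rates are zero and no fixed-time stop applies");
        }
        double dt = R::rexp(1.0 / totrate);

        if (phase == 1 && det_rule == 2 && t + dt >= det_value) {
            t = det_value;
            if (end_rule == 0) break;
            enterPhase2();
            continue;
        }
        if (phase == 2 && end_rule == 1 && t + dt >= t_detect + end_value) {
            t = t_detect + end_value;
            break;
        }
        t += dt;
        nev += 1.0;
        if (nev > max_events)
            stop("event budget exceeded (max_events = %g)", max_events);

        double u = unif_rand() * totrate;
        bool isBirth; int node;
        if (u < nS * bs) {
            isBirth = true;
            node = liveS[(int) std::min(unif_rand() * nS, nS - 1.0)];
        } else if (u < nS * (bs + ds)) {
            isBirth = false;
            node = liveS[(int) std::min(unif_rand() * nS, nS - 1.0)];
        } else if (u < nS * (bs + ds) + nR * br) {
            isBirth = true;
            node = liveR[(int) std::min(unif_rand() * nR, nR - 1.0)];
        } else {
            isBirth = false;
            node = liveR[(int) std::min(unif_rand() * nR, nR - 1.0)];
        }

        if (isBirth) {
            removeLive(node);
            alive[node] = 0;  // becomes an internal node (an ancestor)
            for (int c = 0; c < 2; ++c) {
                int ctype = type[node];
                char cfound = 0;
                if (ctype == 0 && nu > 0.0 && unif_rand() < nu) {
                    ctype = 1; cfound = 1;
                }
                parent.push_back(node + 1);
                nmut.push_back((int) R::rpois(m));
                type.push_back(ctype);
                founder.push_back(cfound);
                btime.push_back(t);
                alive.push_back(1);
                poslist.push_back(0);
                addLive((int) parent.size() - 1);
            }
            if (ntot + 1.0 > max_population)
                stop("population exceeded max_population = %g", max_population);
            if (phase == 1 && det_rule == 1 && ntot + 1.0 >= det_value) {
                if (end_rule == 0) break;
                enterPhase2();
            } else if (phase == 2 && end_rule == 2 && ntot + 1.0 >= end_value) {
                break;
            }
        } else {
            removeLive(node);
            alive[node] = 0;  // dead leaf: no children, not alive
        }
    }

    if (det_rule == -1)
        t_detect = 0.0;
    else if (phase == 1 && !extinct && end_rule == 0)
        t_detect = t;  // single-phase run: detection is the stopping point

    int n = (int) parent.size();
    return List::create(
        _["parent"] = IntegerVector(parent.begin(), parent.end()),
        _["nmut"] = IntegerVector(nmut.begin(), nmut.end()),
        _["type"] = IntegerVector(type.begin(), type.end()),
        _["founder"] = LogicalVector(founder.begin(), founder.end()),
        _["btime"] = NumericVector(btime.begin(), btime.end()),
        _["alive"] = LogicalVector(alive.begin(), alive.end()),
        _["nAlive"] = (int) (liveS.size() + liveR.size()),
        _["detectionTime"] = t_detect,
        _["finalTime"] = t,
        _["extinct"] = extinct,
        _["nEvents"] = nev,
        _["nNodes"] = n);
}

// Number of alive descendant leaves below (and including) every node.
// Relies on parent[i] < i+1 (children are created after their parent).

// [[Rcpp::export]]
IntegerVector cpp_alive_descendants(IntegerVector parent, LogicalVector alive) {
    int n = parent.size();
    IntegerVector cnt(n);
    for (int i = n - 1; i >= 0; --i) {
        int c = cnt[i] + (alive[i] ? 1 : 0);
        cnt[i] = c;
        if (parent[i] > 0) cnt[parent[i] - 1] += c;
    }
    return cnt;
}

// Root-to-leaf accumulated mutation burden and division count for every
// alive leaf. A node's division count is the number of ancestral division
// (internal) nodes on its path, i.e. its edge depth.

// [[Rcpp::export]]
List cpp_leaf_paths(IntegerVector parent, IntegerVector nmut,
                    LogicalVector alive) {
    int n = parent.size();
    std::vector<int> burden(n), depth(n), nchild(n, 0);
    for (int i = 0; i < n; ++i) {
        if (parent[i] > 0) {
            burden[i] = burden[parent[i] - 1] + nmut[i];
            depth[i] = depth[parent[i] - 1] + 1;
            nchild[parent[i] - 1]++;
        } else {
            burden[i] = nmut[i];
            depth[i] = 0;
        }
    }
    std::vector<int> jb, ld;
    for (int i = 0; i < n; ++i) {
        if (alive[i] && nchild[i] == 0) {
            jb.push_back(burden[i]);
            ld.push_back(depth[i]);
        }
    }
    return List::create(
        _["burden"] = IntegerVector(jb.begin(), jb.end()),
        _["divisions"] = IntegerVector(ld.begin(), ld.end()));
}
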