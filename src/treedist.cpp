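#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Zhang-Shasha tree edit distance between two ordered trees given in
// postorder.  type*: node type codes (0 unpaired, 1 pair, 2 virtual root),
// lml*: leftmost-leaf index of each node (1-based postorder ids),
// kr*: LR keyroots in increasing postorder.  del_cost is indexed by type
// (insertion cost equals deletion cost), sub_cost is a type x type matrix.
// [[Rcpp::export]]
double zs_tree_edit(IntegerVector type1, IntegerVector lml1, IntegerVector kr1,
                    IntegerVector type2, IntegerVector lml2, IntegerVector kr2,
                    NumericVector del_cost, NumericMatrix sub_cost) {
    const int n1 = type1.size(), n2 = type2.size();
    if (n1 == 0 || n2 == 0) stop("empty postorder vector");

    // treedist[i][j], 1-based subtree roots; row 0 / col 0 unused
    std::vector<double> td((n1 + 1) * (n2 + 1), 0.0);
    const int tdw = n2 + 1;
    // forest-distance scratch indexed from 0..n1 x 0..n2
    std::vector<double> fd((n1 + 1) * (n2 + 1), 0.0);
    const int fdw = n2 + 1;

    for (int ki = 0; ki < kr1.size(); ++ki) {
        const int i1 = kr1[ki];
        const int li = lml1[i1 - 1];
        for (int kj = 0; kj < kr2.size(); ++kj) {
            const int j1 = kr2[kj];
            const int lj = lml2[j1 - 1];

            fd[(li - 1) * fdw + (lj - 1)] = 0.0;
            for (int di = li; di <= i1; ++di)
                fd[di * fdw + (lj - 1)] =
                    fd[(di - 1) * fdw + (lj - 1)] + del_cost[type1[di - 1]];
            for (int dj = lj; dj <= j1; ++dj)
                fd[(li - 1) * fdw + dj] =
                    fd[(li - 1) * fdw + (dj - 1)] + del_cost[type2[dj - 1]];

            for (int di = li; di <= i1; ++di) {
                const double c_del = del_cost[type1[di - 1]];
                for (int dj = lj; dj <= j1; ++dj) {
                    const double a = fd[(di - 1) * fdw + dj] + c_del;
                    const double b = fd[di * fdw + (dj - 1)] + del_cost[type2[dj - 1]];
                    double best = std::min(a, b);
                    if (lml1[di - 1] == li && lml2[dj - 1] == lj) {
                        const double c = fd[(di - 1) * fdw + (dj - 1)] +
                            sub_cost(type1[di - 1], type2[dj - 1]);
                        best = std::min(best, c);
                        fd[di * fdw + dj] = best;
                        td[di * tdw + dj] = best;
                    } else {
                        const double c =
                            fd[(lml1[di - 1] - 1) * fdw + (lml2[dj - 1] - 1)] +
                            td[di * tdw + dj];
                        fd[di * fdw + dj] = std::min(best, c);
                    }
                }
            }
        }
    }
    return td[n1 * tdw + n2];
}
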