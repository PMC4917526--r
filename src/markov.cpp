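#include <Rcpp.h>
using namespace Rcpp;

// Sample one state in 0..3 from a length-4 probability row using u in [0,1).
static inline int pick_state(const double* p, double u) {
    double acc = 0.0;
    for (int s = 0; s < 3; ++s) {
        acc += p[s];
        if (u < acc) return s;
    }
    return 3;
}

//' Generate an order-k Markov chain over the DNA alphabet.
//'
//' States are encoded 0=A, 1=C, 2=G, 3=T. `trans` has 4^k rows (contexts,
//' lexicographic over the previous k states) and 4 columns; each row sums
//' to 1. The first k states are drawn i.i.d. from `init`. Uses R's RNG so
//' results are reproducible under set.seed().
//'
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_markov_chain(int n, NumericVector init, NumericMatrix trans) {
    if (n < 1) stop("chain length must be positive");
    int ncontext = trans.nrow();
    int k = 0;
    for (int m = 1; m < ncontext; m *= 4) ++k;
    if (ncontext != (int) std::pow(4.0, k))
        stop("transition matrix must have 4^k rows");
    IntegerVector out(n);
    // flatten rows for cache-friendly access
    std::vector<double> tr(ncontext * 4);
    for (int r = 0; r < ncontext; ++r)
        for (int c = 0; c < 4; ++c) tr[r * 4 + c] = trans(r, c);
    double p0[4] = { init[0], init[1], init[2], init[3] };

    int ctx = 0, filled = std::min(k, n);
    for (int i = 0; i < filled; ++i) {
        int s = pick_state(p0, unif_rand());
        out[i] = s;
        ctx = ctx * 4 + s;
    }
    for (int i = filled; i < n; ++i) {
        int s = pick_state(&tr[ctx * 4], unif_rand());
        out[i] = s;
        ctx = (ctx * 4 + s) % ncontext;
    }
    return out;
}
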