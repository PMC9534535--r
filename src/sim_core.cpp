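// Hot loop of the two-layer LIF simulation. Spike propagation is done by
// accumulating weight-matrix columns of the (few) units that spiked on the
// previous step, which is much cheaper than dense mat-vec products at the
// spike densities the Bernoulli encoder produces.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct LayerState {
  arma::vec v, i, refrac_count;
  arma::uvec counts;
  LayerState(int n, double rest)
      : v(n, arma::fill::value(rest)), i(n, arma::fill::zeros),
        refrac_count(n, arma::fill::zeros), counts(n, arma::fill::zeros) {}
};

// One LIF step; overwrites `spiked` with the indices of units that fired.
void lif_update(LayerState &st, const arma::vec &ext,
                std::vector<arma::uword> &spiked, double decay_i,
                double decay_v, double dt, double thresh, double rest,
                double reset, double refrac) {
  spiked.clear();
  const arma::uword n = st.v.n_elem;
  for (arma::uword u = 0; u < n; ++u) {
    st.i[u] = st.i[u] * decay_i + ext[u];
    if (st.refrac_count[u] > 0) {
      st.v[u] = reset;
      st.refrac_count[u] = std::max(st.refrac_count[u] - dt, 0.0);
    } else {
      st.v[u] = rest + (st.v[u] - rest) * decay_v + st.i[u] * dt;
      if (st.v[u] >= thresh) {
        st.v[u] = reset;
        st.refrac_count[u] = refrac;
        st.counts[u] += 1;
        spiked.push_back(u);
      }
    }
  }
}

} // namespace

// raster: timesteps x n_in binary matrix of encoder spikes.
// w_ff_t:  n_out x n_in feedforward weights, TRANSPOSED so that column j
//          holds the fan-out of input unit j.
// lat_in:  n_in x n_in lateral kernel of the input layer (column j = fan-out
//          of unit j; kernels are symmetric, but we index columns).
// lat_out: n_out x n_out lateral kernel of the output layer.
// [[Rcpp::export]]
List sim_core_cpp(const arma::imat &raster, const arma::mat &w_ff_t,
                  const arma::mat &lat_in, const arma::mat &lat_out,
                  double amplitude, double dt, double thresh, double rest,
                  double reset, double refrac, double tc_decay,
                  double tc_i_decay) {
  const arma::uword n_in = raster.n_cols;
  const arma::uword n_out = w_ff_t.n_rows;
  if (w_ff_t.n_cols != n_in || lat_in.n_rows != n_in || lat_in.n_cols != n_in ||
      lat_out.n_rows != n_out || lat_out.n_cols != n_out)
    stop("configuration error: weight/raster shape mismatch");

  const double decay_v = std::exp(-dt / tc_decay);
  const double decay_i = std::exp(-dt / tc_i_decay);

  LayerState in(n_in, rest), out(n_out, rest);
  std::vector<arma::uword> sp_in, sp_out, prev_in, prev_out;
  arma::vec ext_in(n_in), ext_out(n_out);

  for (arma::uword t = 0; t < raster.n_rows; ++t) {
    ext_in.zeros();
    ext_out.zeros();
    for (arma::uword u = 0; u < n_in; ++u)
      if (raster(t, u)) ext_in[u] += amplitude;
    for (arma::uword j : prev_in) {
      ext_in += lat_in.col(j);
      ext_out += w_ff_t.col(j);
    }
    for (arma::uword j : prev_out) ext_out += lat_out.col(j);

    lif_update(in, ext_in, sp_in, decay_i, decay_v, dt, thresh, rest, reset,
               refrac);
    lif_update(out, ext_out, sp_out, decay_i, decay_v, dt, thresh, rest, reset,
               refrac);
    prev_in = sp_in;
    prev_out = sp_out;
  }

  return List::create(
      Named("input_counts") = IntegerVector(in.counts.begin(), in.counts.end()),
      Named("output_counts") =
          IntegerVector(out.counts.begin(), out.counts.end()));
}
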