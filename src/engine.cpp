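#include <Rcpp.h>
using namespace Rcpp;

// Truncated causal exponential-kernel convolution, one pass per column:
// y[t] = d*y[t-1] + x[t] - d^L * x[t-L]  (exact recursion of the finite kernel)
// [[Rcpp::export]]
NumericMatrix exp_filter(NumericMatrix x, double d, int L, double amplitude) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix y(n, m);
  const double dL = std::pow(d, L);
  for (int j = 0; j < m; ++j) {
    double acc = 0.0;
    for (int t = 0; t < n; ++t) {
      acc = d * acc + x(t, j);
      if (t >= L) acc -= dL * x(t - L, j);
      y(t, j) = amplitude * acc;
    }
  }
  return y;
}

// Core integrate-and-fire loop. Mirrors the per-step reference update
// (stepNetwork) exactly, including operation order, so the two agree to
// rounding error. Neuron layout: VIP, SST, PV, PYR blocks in that order.
// Weight matrix rows: vHPC, VIP, SST, PV, PYR; columns: VIP, SST, PV, PYR.
// [[Rcpp::export]]
List engine_run(NumericVector ampa, NumericVector nmda, NumericVector noise,
                NumericMatrix neuronNoise, NumericMatrix W,
                NumericMatrix Mpyr, IntegerVector nCells,
                double vdecay, NumericVector sdec, double nmdaScale,
                double threshold, double reset, double dt, bool recordV) {
  const int T = ampa.size();
  const int nVip = nCells[0], nSst = nCells[1], nPv = nCells[2],
            nPyr = nCells[3];
  const int nNeurons = nVip + nSst + nPv + nPyr;
  const int off[5] = {0, nVip, nVip + nSst, nVip + nSst + nPv, nNeurons};

  std::vector<double> v(nNeurons, 0.0), input(nNeurons, 0.0);
  std::vector<bool> refract(nNeurons, false), spiked(nNeurons, false);
  // class outputs: 0 VIP, 1 SST, 2 PV, 3 PYR_AMPA, 4 PYR_NMDA
  double out[5] = {0, 0, 0, 0, 0};
  std::vector<double> out2a(nPyr, 0.0), out2n(nPyr, 0.0), rec(nPyr, 0.0),
      drivePyr(nPyr, 0.0);

  IntegerMatrix spikeCounts(4, T);
  NumericMatrix vrec = recordV ? NumericMatrix(nNeurons, T)
                               : NumericMatrix(0, 0);

  for (int t = 0; t < T; ++t) {
    const double dAmpa = t == 0 ? 0.0 : ampa[t - 1];
    const double dNmda = t == 0 ? 0.0 : nmda[t - 1];
    const double dNoise = t == 0 ? 0.0 : noise[t - 1];
    const double vhBase = dAmpa + nmdaScale * dNmda + dNoise;

    // recurrent pyramidal drive through the connectivity matrix
    for (int j = 0; j < nPyr; ++j)
      drivePyr[j] = out2a[j] + nmdaScale * out2n[j];
    for (int i = 0; i < nPyr; ++i) {
      double s = 0.0;
      for (int j = 0; j < nPyr; ++j) s += Mpyr(i, j) * drivePyr[j];
      rec[i] = W(4, 3) * s;
    }

    for (int x = 0; x < 4; ++x) {
      const double inh = W(1, x) * out[0] + W(2, x) * out[1] +
                         W(3, x) * out[2];
      const double vh = W(0, x) * vhBase;
      if (x < 3) {
        const double exc = W(4, x) * (out[3] + nmdaScale * out[4]);
        for (int i = off[x]; i < off[x + 1]; ++i)
          input[i] = -inh + exc + vh +
                     (t == 0 ? 0.0 : neuronNoise(i, t - 1));
      } else {
        for (int i = off[3]; i < off[4]; ++i)
          input[i] = -inh + rec[i - off[3]] + vh +
                     (t == 0 ? 0.0 : neuronNoise(i, t - 1));
      }
    }

    for (int i = 0; i < nNeurons; ++i) {
      v[i] = v[i] * vdecay + dt * input[i];
      if (refract[i]) v[i] = reset;
      if (!R_finite(v[i]))
        stop("non-finite membrane voltage at step %d", t + 1);
      spiked[i] = v[i] >= threshold;
    }

    int cnt[4] = {0, 0, 0, 0};
    for (int x = 0; x < 4; ++x)
      for (int i = off[x]; i < off[x + 1]; ++i)
        if (spiked[i]) ++cnt[x];

    out[0] = out[0] * sdec[0] + (double)cnt[0] / nVip;
    out[1] = out[1] * sdec[1] + (double)cnt[1] / nSst;
    out[2] = out[2] * sdec[2] + (double)cnt[2] / nPv;
    out[3] = out[3] * sdec[3] + (double)cnt[3] / nPyr;
    out[4] = out[4] * sdec[4] + (double)cnt[3] / nPyr;
    for (int j = 0; j < nPyr; ++j) {
      const double fired = spiked[off[3] + j] ? 1.0 : 0.0;
      out2a[j] = out2a[j] * sdec[3] + fired;
      out2n[j] = out2n[j] * sdec[4] + fired;
    }
    for (int x = 0; x < 4; ++x) spikeCounts(x, t) = cnt[x];
    for (int i = 0; i < nNeurons; ++i) refract[i] = spiked[i];
    if (recordV)
      for (int i = 0; i < nNeurons; ++i) vrec(i, t) = v[i];
  }

  List res = List::create(Named("spikeCounts") = spikeCounts);
  if (recordV) res["v"] = vrec;
  return res;
}
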