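#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire feedforward network: input cells driven by a
// per-frame current, projecting to one output cell through excitatory
// (optionally depressing) synapses that deliver instantaneous membrane
// kicks. Uses R's RNG so seeds set in R apply.
// [[Rcpp::export]]
List lifNetworkCpp(NumericMatrix drive, IntegerVector frameOfStep,
                   double dt, double tauM, double vRest, double vReset,
                   double vThresh, double refrac, double noiseSd,
                   bool depression, double u, double tauRec,
                   double synWeight) {
  const int nIn = drive.nrow();
  const int nSteps = frameOfStep.size();
  const int nFrames = drive.ncol();
  IntegerVector counts(nFrames);
  IntegerVector inputSpikes(nIn);
  std::vector<double> V(nIn, vRest), R(nIn, 1.0), refCount(nIn, 0.0);
  double Vout = vRest, refOut = 0.0;
  long outSpikes = 0;
  const double leak = dt / tauM;
  const double recover = dt / tauRec;

  for (int t = 0; t < nSteps; ++t) {
    const int f = frameOfStep[t] - 1;
    double kick = 0.0;
    for (int i = 0; i < nIn; ++i) {
      if (depression) R[i] += (1.0 - R[i]) * recover;
      if (refCount[i] > 0) {
        refCount[i] -= dt;
        continue;
      }
      V[i] += leak * (-(V[i] - vRest) + drive(i, f));
      if (noiseSd > 0) V[i] += noiseSd * R::norm_rand();
      if (V[i] >= vThresh) {
        V[i] = vReset;
        refCount[i] = refrac;
        inputSpikes[i]++;
        if (depression) {
          kick += synWeight * u * R[i];
          R[i] *= (1.0 - u);
        } else {
          kick += synWeight;
        }
      }
    }
    if (refOut > 0) {
      refOut -= dt;
      continue;
    }
    Vout += leak * (-(Vout - vRest)) + kick;
    if (noiseSd > 0) Vout += noiseSd * R::norm_rand();
    if (Vout >= vThresh) {
      Vout = vReset;
      refOut = refrac;
      counts[f] += 1;
      ++outSpikes;
    }
  }
  return List::create(_["counts"] = counts,
                      _["inputSpikes"] = inputSpikes,
                      _["outputSpikes"] = (double)outSpikes);
}
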