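// Branch-free double-precision exp via 2^k * P(r) range reduction with a
// degree-10 Taylor polynomial on |r| <= ln(2)/2; relative error below ~1e-12.
// Written so compilers can auto-vectorize the activation loops that call it.
#ifndef AGENTNET_FASTEXP_H
#define AGENTNET_FASTEXP_H

#include <cstdint>
#include <cstring>

static inline double fexp(double x) {
  // clamp: exp(-746) underflows, inputs > 300 are saturated by callers
  x = x > 300.0 ? 300.0 : (x < -700.0 ? -700.0 : x);
  const double log2e = 1.4426950408889634074;
  const double ln2_hi = 6.93147180369123816490e-01;
  const double ln2_lo = 1.90821492927058770002e-10;
  double kd = x * log2e;
  // round to nearest via the 2^52 trick (branch-free)
  double kshift = kd + 6755399441055744.0;   // 1.5 * 2^52
  std::int64_t ki;
  std::memcpy(&ki, &kshift, 8);
  ki = static_cast<std::int32_t>(ki & 0xffffffff);
  kd = static_cast<double>(ki);
  double r = x - kd * ln2_hi - kd * ln2_lo;
  // exp(r), |r| <= 0.3466, Taylor to r^10/10!
  double p = 1.0 / 3628800.0;
  p = p * r + 1.0 / 362880.0;
  p = p * r + 1.0 / 40320.0;
  p = p * r + 1.0 / 5040.0;
  p = p * r + 1.0 / 720.0;
  p = p * r + 1.0 / 120.0;
  p = p * r + 1.0 / 24.0;
  p = p * r + 1.0 / 6.0;
  p = p * r + 0.5;
  p = p * r + 1.0;
  p = p * r + 1.0;
  // scale by 2^k through the exponent bits
  std::int64_t bits = (ki + 1023LL) << 52;
  double scale;
  std::memcpy(&scale, &bits, 8);
  return p * scale;
}

#endif
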