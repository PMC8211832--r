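// Clamp the BLAS thread pool: the package's gemms are small and frequent,
// so thread fan-out (or oversubscription under CPU quotas) costs more than
// it gains.  Resolved dynamically so any BLAS without the OpenBLAS entry
// point is left untouched.
#include <Rcpp.h>
#ifndef _WIN32
#include <dlfcn.h>
#endif

// [[Rcpp::export(name = ".set_blas_threads")]]
void set_blas_threads(int n) {
#ifndef _WIN32
  typedef void (*setter)(int);
  setter fn = reinterpret_cast<setter>(dlsym(RTLD_DEFAULT,
                                             "openblas_set_num_threads"));
  if (fn) fn(n);
#endif
}
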