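.onLoad <- function(libname, pkgname) {
  # small, frequent matrix products: a fanned-out BLAS pool is pure overhead
  # (and oversubscribes CPU-limited containers); honor an explicit user
  # setting, otherwise run BLAS single-threaded
  if (Sys.getenv("OPENBLAS_NUM_THREADS") == "") {
    .set_blas_threads(1L)
  }
  invisible()
}
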