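# Study-scale trained models, built lazily once per test session and shared
# by the quantitative checks (training is the expensive part; everything
# downstream reuses the same fitted study).

.trained <- new.env(parent = emptyenv())

trained_ca <- function() {
  if (is.null(.trained$ca)) .trained$ca <- desk_study("ca", seed = 101)
  .trained$ca
}

trained_vicsek <- function() {
  if (is.null(.trained$vm)) .trained$vm <- desk_study("vicsek", seed = 202)
  .trained$vm
}
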