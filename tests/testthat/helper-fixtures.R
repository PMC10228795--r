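# shared test fixtures, built in code

# zero-activation parameter set: every Hill production term switched off,
# leaving a linear system with a closed-form fixed point
zero_activation_params <- function(kdeg_JNK = 2, kdeg_JAK = 4, kdeg_UPD = 0.5) {
  dimensionless_params(kact_EIG = 0, kact_JNK = 0, kact_JAK = 0,
                       kact_UPD = 0, kdeg_JNK = kdeg_JNK,
                       kdeg_JAK = kdeg_JAK, kdeg_UPD = kdeg_UPD)
}

small_cfg <- function(n = 20L, ...) model_config(n_compartments = n, ...)

# small scans reused by several test files (kept cheap: ~seconds)
tiny_scan <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_scan(sampling_config(n_sets = 8, seed = 11),
                         model_config(n_compartments = 40, t_max = 200))
    cache
  }
})
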