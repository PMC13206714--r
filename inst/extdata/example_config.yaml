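# Example configuration for run_pipeline() / scripts/teatrace.R.
# Keys mirror the arguments of teatrace::pipeline_config().
seed: 1
out_dir: teatrace_run
n_per_origin:
  FR: 22
  GMEX: 18
  YTS: 23
n_time_points: 400
n_wavelengths: 150
noise_sd: 0.002
n_interferents: 1
n_validation: 7
methods: [lda, plsda, tsnerf]
run_l9: false
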