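# Small demonstration run: short recordings, few measurements.
seed: 42
output_dir: fccsfret-run
calibration:
  duration: 4
  box_side: 4
fccs:
  n_measurements: 3
  duration: 2
  kd_true: 300
flim:
  n_donor: 3
  n_roi: 3
  n_photons: 20000
ktr:
  n_rows: 7
  n_cols: 8
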