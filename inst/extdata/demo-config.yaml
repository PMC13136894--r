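# Demonstration configuration for run_pipeline(): all-synthetic, small
# problem sizes so the five stages finish in tens of seconds.
seed: 1
stages: [droplets, flim, qpcr, fidelity, digital]
droplets:
  n_droplets: 10
  pc: 19.1
  noise_frac: 0.05
flim:
  tau_in: 3.0
  tau_out: 3.6
qpcr:
  A: 2922
  k: 0.71
  noise_sd_ct: 0.3
fidelity:
  n_oligos: 5
  oligo_length: 150
  overlap: 20
  q: 0.00151
  n_reads: 2000
  n_trials: 200000
digital:
  rows: 10
  cols: 25
  concentrations: [0.25, 0.5, 1, 2]
  true_fractions: [0.0002, 0.0005, 0.02, 0.05]
  control_pseudo_rate: 0.000179
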