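# Production run settings, methane dimer (16e,24o): 300k shots, 4 batches of
# 8.5k samples, 5 recovery steps.  The extrapolation ladder uses batch sizes
# of 5.5k, 6.5k, 7.5k and 8.5k.
system: methane dimer
active_space: [16, 24]
shots: 300000
epsilon: 0.01
K: 4
batch_size: 8500
steps: 5
energy_tol: 1.0e-6
mode: noisy
extrapolation_batch_sizes: [5500, 6500, 7500, 8500]
solver:
  tol: 1.0e-8
  max_iter: 200
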