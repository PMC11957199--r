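# Production run settings, methane dimer (16e,16o): 200k shots, 10 batches
# of 20k samples, 10 recovery steps.  The extrapolation ladder uses batch
# sizes of 9k, 11k and 14k instead of the full 20k.
system: methane dimer
active_space: [16, 16]
shots: 200000
epsilon: 0.01
K: 10
batch_size: 20000
steps: 10
energy_tol: 1.0e-6
mode: noisy
extrapolation_batch_sizes: [9000, 11000, 14000]
solver:
  tol: 1.0e-8
  max_iter: 200
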