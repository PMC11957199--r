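# Production run settings, water dimer (16e,12o): 200k shots, 10 batches of
# 10k samples, 10 recovery steps; the batch subspaces saturate the full
# 245,025-determinant space.
system: water dimer
active_space: [16, 12]
shots: 200000
epsilon: 0.01
K: 10
batch_size: 10000
steps: 10
energy_tol: 1.0e-6
mode: noisy
solver:
  tol: 1.0e-8
  max_iter: 200
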