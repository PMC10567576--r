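# Example configuration for the `bars` analysis pipeline: synthesize a
# nanobar field with the fabricated geometry, register the lattice and
# write membrane-normalized end/side ratios.
analysis: bars
seed: 11
out_dir: curvadh-out
synth:
  integrin_E: 1.9        # planted integrin end enrichment
  wrap_range: [0.7, 1.3] # per-bar uneven-wrapping confound
  dim: 320               # field side in pixels (0.1 um/px)
params:
  pitch_band: [2, 10]    # lattice search band, um
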