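# Half-length slit culture, published optimized parameters.
# Coordinates: um; slit origin at a corner; z = 0 at the substrate.
preset: optimized
confinement:
  kind: slit
  length: 2000
  width: 200
  height: 100
cell_density: 1.0e-4
astrocyte_fraction: 0.2
min_cell_spacing: 10
anchor_density: 2.0e-3
min_anchor_spacing: 10
seed: 11
snapshot_every: 50
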