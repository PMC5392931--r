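# Default three-compartment yeast cell model used for whole-cell NH_X
# deconvolution. Volume fractions are fractions of total cell volume
# (including dry matter); the remaining volume is assumed NH_X-free.
acid_base:
  pKa: 9.25
  temperature_K: 303.15
compartments:
  - name: cytosol
    volume_fraction: 0.70
    pH: 6.5
  - name: vacuole
    volume_fraction: 0.14
    pH: 4.5
  - name: mitochondria
    volume_fraction: 0.01
    pH: 7.5
sensitivity_box:
  vacuole_fraction: [0.14, 0.25]
  cytosol_pH: [6.0, 7.0]
  vacuole_pH: [4.0, 5.5]
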