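# Synthetic genotyping-array manifest emulating the minor-allele-frequency
# spectrum and mean marker spacing of a dense commercial genome-wide array
# (common-variant skewed, ~1 marker per 2 kb).  Replace with a manifest
# derived from a real chip design for platform-specific studies.
maf_edges: [0.0, 0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5]
proportions: [0.01, 0.02, 0.10, 0.13, 0.21, 0.20, 0.18, 0.15]
mean_spacing_bp: 2000
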