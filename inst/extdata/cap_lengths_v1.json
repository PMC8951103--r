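{
  "version": 1,
  "comment": "Bond lengths (Angstrom) for caps placed along the former bond vector. 'hydrogen': X-H length by stub element. 'methyl': X-C single-bond length by stub element; the methyl C-H length and tetrahedral geometry are fixed.",
  "hydrogen": { "C": 1.09, "N": 1.01, "O": 0.96, "S": 1.34, "P": 1.42, "default": 1.09 },
  "methyl":   { "C": 1.54, "N": 1.47, "O": 1.43, "S": 1.81, "P": 1.85, "default": 1.54 },
  "methyl_CH": 1.09,
  "tetrahedral_angle_deg": 109.471
}
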