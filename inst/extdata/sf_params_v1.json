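{
  "version": 1,
  "comment": "Empirical pairwise scoring-function parameter sets. Terms are functions of the surface distance d = r - R_i - R_j (Angstrom): gauss1 = exp(-((d - gauss1_offset)/gauss1_width)^2); gauss2 likewise; repulsion = d^2 for d < 0; hydrophobic and hbond are piecewise-linear ramps equal to 1 below 'lo', 0 above 'hi'. The score is the weighted sum over intermolecular heavy-atom pairs with d < cutoff; optional conformational-entropy scaling divides by (1 + w_rot * n_rot).",
  "vina_default": {
    "weights": {
      "gauss1": -0.035579,
      "gauss2": -0.005156,
      "repulsion": 0.840245,
      "hydrophobic": -0.035069,
      "hbond": -0.587439
    },
    "gauss1_offset": 0.0,
    "gauss1_width": 0.5,
    "gauss2_offset": 3.0,
    "gauss2_width": 2.0,
    "hydrophobic_lo": 0.5,
    "hydrophobic_hi": 1.5,
    "hbond_lo": -0.7,
    "hbond_hi": 0.0,
    "cutoff": 8.0,
    "w_rot": 0.05846
  },
  "vinardo_default": {
    "weights": {
      "gauss1": -0.045,
      "gauss2": 0.0,
      "repulsion": 0.8,
      "hydrophobic": -0.035,
      "hbond": -0.6
    },
    "gauss1_offset": 0.0,
    "gauss1_width": 0.8,
    "gauss2_offset": 3.0,
    "gauss2_width": 2.0,
    "hydrophobic_lo": 0.0,
    "hydrophobic_hi": 2.5,
    "hbond_lo": -0.6,
    "hbond_hi": 0.0,
    "cutoff": 8.0,
    "w_rot": 0.05846
  }
}
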