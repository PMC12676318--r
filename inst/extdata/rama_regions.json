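{
  "comment": "Coarse Ramachandran region map: polygons in (phi, psi) degrees. A residue inside any 'favored' polygon is favored; inside any 'allowed' polygon (but no favored one) is allowed; otherwise an outlier. Boundaries are inclusive toward the more favorable class.",
  "version": "coarse-1.0",
  "favored": [
    {
      "name": "alpha_right",
      "phi": [-120, -120, -30, -30],
      "psi": [-80, -5, -5, -80]
    },
    {
      "name": "beta_sheet",
      "phi": [-170, -170, -50, -50],
      "psi": [80, 180, 180, 80]
    }
  ],
  "allowed": [
    {
      "name": "alpha_right_ext",
      "phi": [-180, -180, -20, -20],
      "psi": [-120, 40, 40, -120]
    },
    {
      "name": "beta_ext",
      "phi": [-180, -180, -30, -30],
      "psi": [50, 180, 180, 50]
    },
    {
      "name": "beta_ext_wrap",
      "phi": [-180, -180, -40, -40],
      "psi": [-180, -150, -150, -180]
    },
    {
      "name": "alpha_left",
      "phi": [20, 20, 100, 100],
      "psi": [-30, 90, 90, -30]
    }
  ]
}
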