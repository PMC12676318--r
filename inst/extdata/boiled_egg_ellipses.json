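{
  "comment": "BOILED-Egg classifier ellipses in (TPSA, WLOGP) space. 'white' bounds predicted passive gastrointestinal absorption (HIA); 'yolk' bounds predicted blood-brain-barrier penetration (BBB). Angles in degrees, axes are full widths.",
  "version": "boiled-egg-1.0",
  "white": {
    "center_tpsa": 71.051,
    "center_wlogp": 2.292,
    "width_tpsa": 142.081,
    "height_wlogp": 8.740,
    "angle_deg": -1.031325
  },
  "yolk": {
    "center_tpsa": 38.117,
    "center_wlogp": 3.177,
    "width_tpsa": 82.061,
    "height_wlogp": 5.557,
    "angle_deg": -0.171887
  }
}
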