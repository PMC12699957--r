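{
  "movement": "neutral_hold",
  "angles": {
    "left_elbow": 160,
    "right_elbow": 160,
    "left_knee": 170,
    "right_knee": 170,
    "left_arm_elevation": 160,
    "right_arm_elevation": 160,
    "left_leg_elevation": 170,
    "right_leg_elevation": 170,
    "trunk_tilt": 0
  },
  "Dst": 90,
  "Sst": 60
}
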