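name: hindbrain
steps:
- action: approach
  site: hindbrain
- action: descend_coarse
- action: descend_fine
- action: await_touchdown
- action: advance_along_axis
  distance: 4
- action: await_puncture
- action: retract
  distance: 2
- action: repeat
  k: 2
  steps:
  - action: pulse
    pressure: 180
    duration: 0.1
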