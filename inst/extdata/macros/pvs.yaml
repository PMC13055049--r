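name: pvs
steps:
- action: approach
  site: pvs
- action: descend_coarse
- action: descend_fine
- action: await_touchdown
- action: advance_along_axis
  distance: 4
- action: await_puncture
- action: retract
  distance: 2
- action: repeat
  k: 3
  steps:
  - action: pulse
    pressure: 150
    duration: 0.1
  - action: operator_checkpoint
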