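name: doc
steps:
- action: approach
  site: doc_mid
- action: descend_coarse
- action: descend_fine
- action: await_touchdown
- action: advance_along_axis
  distance: 5
- action: await_puncture
- action: retract
  distance: 3
- action: pulse
  pressure: 200
  duration: 0.1
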