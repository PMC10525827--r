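- embryo_id: example
  embryonic_day: 16
  group: plain
  baseline_duration: 120.0
  post_duration: 120.0
  stimuli:
  - kind: Touch
    onset_frame: 6000
    release_frame: 6050
  - kind: Pinch
    onset_frame: 19550
    release_frame: 19600
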