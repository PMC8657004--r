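{
  "muscle": [[37.0, 1.0], [44.0, 8.9]],
  "fat": [[37.0, 1.0], [44.0, 2.0]],
  "tumor": [[37.0, 1.0], [44.0, 1.0]]
}
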