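# Example chemistry-table overrides. Any subset of the four blocks may be
# given; unlisted entries keep their bundled defaults.
vdw:
  C: 1.70
  ZN: 1.39
masses:
  C: 12.011
hi_element:
  SE: -0.5
hi_atom:
  "SER:OG": -0.5
  "MET:SD": 0.5
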