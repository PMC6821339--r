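name: S1
gains:
  - {trait: DryMatter, value: 20, mode: percent}
  - {trait: DOYFS1, value: 44, mode: absolute}
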