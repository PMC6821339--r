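name: S2
gains:
  - {trait: DryMatter, value: 20, mode: percent}
  - {trait: Cellulose, value: 5, mode: percent}
  - {trait: Lignin, value: -5, mode: percent}
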