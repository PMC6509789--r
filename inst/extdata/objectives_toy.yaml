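# Growth / H2 / CO2-export trade-off study on the toy phototroph.
objectives:
  - {reaction: BIOSYN, direction: max, label: growth}
  - {reaction: EX_h2, direction: max, label: H2}
  - {reaction: EX_co2, direction: max, label: CO2}
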