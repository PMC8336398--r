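# Example run configuration. Every omitted field falls back to the shipped
# Belgian reference defaults; this file only overrides a few for illustration.
fiscal:
  discount_rate: 0.03
  retirement_age: 65
scenarios: [gp, al_w, a10_w, a10_plus_w]
output:
  dir: results
  rounding: euro
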