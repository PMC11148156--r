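template: Q0SBK1
clusters:
  P:
  - Y91
  - Y471
  - R472
  T:
  - G165
  - V166
  - I427
  H:
  - H390
  - G392
  W:
  - D151
  - Y169
  - R278
  - E378
  - Q425
  A:
  - M282
  - L381
  - L438
  - V436
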