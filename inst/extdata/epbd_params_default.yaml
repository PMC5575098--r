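D:
  AT: 0.05
  GC: 0.075
a:
  AT: 4.2
  GC: 6.9
K_u:
  AA: 0.025
  AC: 0.025
  AG: 0.025
  AT: 0.025
  CA: 0.025
  CC: 0.025
  CG: 0.025
  CT: 0.025
  GA: 0.025
  GC: 0.025
  GG: 0.025
  GT: 0.025
  TA: 0.025
  TC: 0.025
  TG: 0.025
  TT: 0.025
K_v:
  AA: 0.025
  AC: 0.025
  AG: 0.025
  AT: 0.025
  CA: 0.025
  CC: 0.025
  CG: 0.025
  CT: 0.025
  GA: 0.025
  GC: 0.025
  GG: 0.025
  GT: 0.025
  TA: 0.025
  TC: 0.025
  TG: 0.025
  TT: 0.025
rho: 2.0
beta_anh: 0.35
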