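# Dye-pair registry.  AEDANS-DABM and MIANS-DDPM carry their measured
# Forster critical distances directly; the last entry shows the
# photophysics route (R0 derived from quantum yield and overlap integral).
AEDANS-DABM:
  R0: 40
MIANS-DDPM:
  R0: 29
example-computed:
  quantum_yield: 0.47
  overlap_integral: 5.713e+14
  kappa2: 0.6666667
  refractive_index: 1.4
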