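# Default site map for the skeletal troponin crystal structures
# (PDB 1YVO / 1YTZ, author numbering).  Both entries deposit more than
# one copy of TnC; list is scanned copy by copy.  Override with your own
# map if your file uses different chain ids.
atom: CA
offsets: {sTnC: 0, sTnI: 0, sTnT: 0}
copies:
  - {sTnC: A, sTnI: B, sTnT: C}
  - {sTnC: D, sTnI: E, sTnT: F}
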