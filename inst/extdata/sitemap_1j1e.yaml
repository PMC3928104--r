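# Default site map for the cardiac troponin core-domain crystal structure
# (PDB 1J1E, author numbering).  The asymmetric unit holds two copies of
# the complex; both are listed so metrics can scan copies.  Chain
# assignments follow the deposited entry (TnC/TnI/TnT per copy) and can
# be overridden by supplying your own map.
atom: CA
offsets: {cTnC: 0, cTnI: 0, cTnT: 0}
copies:
  - {cTnC: A, cTnI: B, cTnT: C}
  - {cTnC: D, cTnI: E, cTnT: F}
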