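>EB1c_Q15691_191-260 human EB1 (MAPRE1) C-terminal domain, residues 191-260
DEAAELMQQVNVLKLTVEDLEKERDFYFGKLRNIELICQENEGENDPVLQRIVDILYATD
EGFVIPDEGG
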