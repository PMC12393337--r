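resname,role,atom
CNF,ring,CG
CNF,ring,CD1
CNF,ring,CE1
CNF,ring,CZ
CNF,ring,CE2
CNF,ring,CD2
CNF,nitrile_C,CM
CNF,nitrile_N,NN
HC4,ring,C1
HC4,ring,C2
HC4,ring,C3
HC4,ring,C4
HC4,ring,C5
HC4,ring,C6
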