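@<TRIPOS>MOLECULE
WAT
 3 2 1 0 0
SMALL
USER_CHARGES

@<TRIPOS>ATOM
      1 O1           0.0000     0.0000     0.0000 ow     1 WAT   -0.834000
      2 H1           0.9572     0.0000     0.0000 hw     1 WAT    0.417000
      3 H2          -0.2399     0.9266     0.0000 hw     1 WAT    0.417000
@<TRIPOS>BOND
     1     1     2 1
     2     1     3 1
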