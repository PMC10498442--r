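@<TRIPOS>MOLECULE
DIC
 5 4 1 0 0
SMALL
USER_CHARGES

@<TRIPOS>ATOM
      1 C1           0.0000     0.0000     0.0000 cc     1 DIC   -0.200000
      2 H1           0.6235     0.6235     0.6235 hc     1 DIC    0.150000
      3 H2          -0.6235    -0.6235     0.6235 cl     1 DIC    0.150000
      4 Cl1          1.0219    -1.0219    -1.0219 cl     1 DIC   -0.050000
      5 Cl2         -1.0219     1.0219    -1.0219 cl     1 DIC   -0.050000
@<TRIPOS>BOND
     1     1     2 1
     2     1     3 1
     3     1     4 1
     4     1     5 1
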