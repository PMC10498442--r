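@<TRIPOS>MOLECULE
CHL
 5 4 1 0 0
SMALL
USER_CHARGES

@<TRIPOS>ATOM
      1 C1           0.0000     0.0000     0.0000 cc     1 CHL    0.179000
      2 H1           0.0000     0.0000     1.0800 hc     1 CHL    0.082000
      3 Cl1          1.6688     0.0000    -0.5900 cl     1 CHL   -0.087000
      4 Cl2         -0.8344     1.4452    -0.5900 cl     1 CHL   -0.087000
      5 Cl3         -0.8344    -1.4452    -0.5900 cl     1 CHL   -0.087000
@<TRIPOS>BOND
     1     1     2 1
     2     1     3 1
     3     1     4 1
     4     1     5 1
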