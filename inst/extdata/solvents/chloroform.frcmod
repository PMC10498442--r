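chloroform solvent template (starting-point parameters)
MASS
cc    12.0110
hc     1.0080
cl    35.4530

BOND
cc-cl     300.0000     1.7700
cc-hc     300.0000     1.0800

ANGLE

DIHE

NONBON
  cc       1.7000       0.1000
  hc       1.2000       0.1000
  cl       1.7500       0.1000

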