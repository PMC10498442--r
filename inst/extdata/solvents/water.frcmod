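water solvent template (starting-point parameters)
MASS
ow    15.9990
hw     1.0080

BOND
ow-hw     553.0000     0.9572

ANGLE

DIHE

NONBON
  ow       1.5200       0.1000
  hw       1.2000       0.1000

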