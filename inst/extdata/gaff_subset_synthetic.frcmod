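SYNTHETIC parameter subset for the amberconv toy fixtures (values in plausible general-force-field ranges; written by this package, not extracted from any distributed force field)
MASS
OW   16.00000
HW    1.00800
c3   12.01000
hc    1.00800
ca   12.01000

BOND
HW-OW   553.0000    0.95720
c3-hc   337.3000    1.09200
c3-c3   300.9000    1.53500
ca-ca   478.4000    1.38700

ANGLE
HW-OW-HW   100.0000   104.5200
hc-c3-hc    39.4300   107.5800
c3-c3-c3    63.2100   110.6300
ca-ca-ca    67.1800   120.0000

DIHE
X -c3-c3-X     1    1.40000      0.000    3.0
X -ca-ca-X     1    3.62500    180.000    2.0

IMPROPER

NONBON
  OW     1.768246     0.152073
  HW     0.000000     0.000000
  c3     1.908000     0.109400
  hc     1.528652     0.013358
  ca     1.908000     0.086000

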