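# Fitted beef-liver parameter set for the dynamic conductivity model
# (two-needle electrode geometry).  Values accept unit suffixes and are
# normalised to strict SI on read.
sigma0: 0.065 S/m
sigmaMax: 0.1483 S/m
Emin: 20000 V/m
Emax: 40000 V/m
tauRelax: 100 us
Apg: 0.35
tauPg: 15 us
AT: 0.125
tauT: 1.75 s
alphaP: 0.0015 m/V
alphaT: 25.0 m/V
AC: 0.0005 1/m2
R: 15 Ohm
C: 1.2e-07 F
dtMin: 2 us
dtMax: 0.99 s
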