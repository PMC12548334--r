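# Synthetic anomalous dispersion table: Tb L3 region (edge 7.514 keV)
# Cromer-Liberman-style logarithmic approach of f-prime to the edge;
# representative magnitudes only, NOT a beamline calibration.
# columns: energy_keV  f_prime_e  f_doubleprime_e
7.404000  -9.6188  3.3000
7.414000  -10.0000  3.3227
7.424000  -10.4214  3.3455
7.434000  -10.8926  3.3682
7.444000  -11.4267  3.3909
7.454000  -12.0433  3.4136
7.464000  -12.7726  3.4364
7.469000  -13.1940  3.4477
7.474000  -13.6652  3.4591
7.479000  -14.1993  3.4705
7.484000  -14.8159  3.4818
7.489000  -15.5452  3.4932
7.494000  -16.4378  3.5045
7.498000  -17.3303  3.5136
7.502000  -18.4811  3.5227
7.505000  -19.6318  3.5295
7.507000  -20.6370  3.5341
7.509000  -21.9829  3.5386
7.510000  -22.8755  3.5409
7.511000  -24.0262  3.5432
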