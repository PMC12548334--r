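# Synthetic anomalous dispersion table: Lu L3 region (edge 9.244 keV)
# Cromer-Liberman-style logarithmic approach of f-prime to the edge;
# representative magnitudes only, NOT a beamline calibration.
# columns: energy_keV  f_prime_e  f_doubleprime_e
9.134000  -9.1188  3.1000
9.144000  -9.5000  3.1227
9.154000  -9.9214  3.1455
9.164000  -10.3926  3.1682
9.174000  -10.9267  3.1909
9.184000  -11.5433  3.2136
9.194000  -12.2726  3.2364
9.199000  -12.6940  3.2477
9.204000  -13.1652  3.2591
9.209000  -13.6993  3.2705
9.214000  -14.3159  3.2818
9.219000  -15.0452  3.2932
9.224000  -15.9378  3.3045
9.228000  -16.8303  3.3136
9.232000  -17.9811  3.3227
9.235000  -19.1318  3.3295
9.237000  -20.1370  3.3341
9.239000  -21.4829  3.3386
9.240000  -22.3755  3.3409
9.241000  -23.5262  3.3432
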