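# Full (ODE-capable) parameter set for the RDX-sensing DsRed riboswitch,
# identified by least-squares fitting of the five-species rate equations to
# plate-reader time series. P and K_D are derived (k1_plus/k1_minus and
# k2_minus/k2_plus); p0 defaults to the basal steady state k5/k4.
k1_plus: 3.293e-5
k1_minus: 4.442e-6
k2_plus: 6.962e-6
k2_minus: 2.239e-6
k3: 1.209e-4
k4: 7.342e-6
k5: 1.299e-3
r_tot: 3.481
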