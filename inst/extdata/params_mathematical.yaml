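# Analytic-only parameter set for the RDX-sensing DsRed riboswitch,
# identified by fitting the quasi-steady-state closed form: P from the
# octanol-water partition ratio of RDX, K_D from a cell-free binding assay.
# p0 defaults to the basal steady state k5/k4.
k1_minus: 8.059e-8
k3: 1.244e-4
k4: 7.342e-6
k5: 1.299e-3
P: 7.413
K_D: 0.3216
r_tot: 3.512
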