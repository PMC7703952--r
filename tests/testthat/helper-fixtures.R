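# Parameter fixtures built in code: the two calibrated reference sets.
comp_params <- function(p0 = NULL) {
  riboswitch_params(k1_plus = 3.293e-5, k1_minus = 4.442e-6,
                    k2_plus = 6.962e-6, k2_minus = 2.239e-6,
                    k3 = 1.209e-4, k4 = 7.342e-6, k5 = 1.299e-3,
                    r_tot = 3.481, p0 = p0)
}

math_params <- function(p0 = NULL) {
  riboswitch_params(k1_minus = 8.059e-8, k3 = 1.244e-4, k4 = 7.342e-6,
                    k5 = 1.299e-3, P = 7.413, K_D = 0.3216,
                    r_tot = 3.512, p0 = p0)
}

# basal mono-exponential, the c_tot = 0 closed form
basal_curve <- function(t, k4, k5, p0) k5 / k4 + (p0 - k5 / k4) * exp(-k4 * t)
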