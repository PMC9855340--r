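# GammaMed Plus HDR Ir-192 line source.
#
# Physical parameters (active length, dose rate constant, half-life) are the
# published consensus values for this source and are user-overridable: copy
# this file, edit, and pass the path to load_source_spec() or --source.
# The radial and anisotropy entries are the fitted analytic parameters of
# g_L(r) = h r^i / (1 + j r^k) and of the sigmoid-sum anisotropy form; each
# anisotropy entry is the quad (c1, c2, c3, c4) of c(r) = c1 r^c2 + c3 r + c4.
# Unused table entries are exactly zero.
name: GammaMedPlus-Ir192
active_length_cm: 0.35
dose_rate_constant: 1.118   # cGy / (h * U)
half_life_days: 73.83
delta_g_percent: 0.5        # mean |fit - Monte Carlo| of g_L, percent
delta_F_percent: 0.9        # mean |fit - Monte Carlo| of F,  percent
radial:
  h: 1.001
  i: 7.69e-3
  j: 2.1e-4
  k: 2.63
anisotropy:
  k:       [-2.30569, -1.98e-2, 2.847e-2, 2.27378]
  a:       [0.0, 0.0, -3.25e-1, 11.5962]
  b:       [4.97e-1, -1.46, 5.2e-1, 24.586]
  e:       [-1.7e-3, -2.96, 0.0, 1.469]
  a_prime: [0.0, 0.0, -6.3265e-1, 17.0192]
  b_prime: [-14.54, -1.5588e-1, -4.47e-1, 39.889]
  e_prime: [-1.14e-1, -1.057, -1.81e-2, 1.2924]
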