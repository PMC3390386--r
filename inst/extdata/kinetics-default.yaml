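# Default gating kinetics of the low-threshold (T-type) Ca2+ current.
#
# Functional family: logistic steady-state curves and a sigmoidal
# inactivation time constant,
#   m_inf(V)  = 1 / (1 + exp(-(V - m.half)/m.slope)),  exponent m.exponent
#   h_inf(V)  = 1 / (1 + exp( (V - h.half)/h.slope))
#   tau_h(V)  = tau_h.base + tau_h.amplitude / (1 + exp((V - tau_h.half)/tau_h.slope))
# with activation treated as instantaneous (m = m_inf(V)) and h the single
# slow state.
#
# These constants are data, not code: pass an alternative file to
# gating_kinetics() to change them. The defaults are this package's
# calibrated parameterization of the T-type family, fixed so that a
# single-compartment cell with leak reversal -63 mV reproduces the
# experimentally reported subthreshold-oscillation regime: an oscillatory
# region covering roughly half of the g_l in [0.15, 0.4], g_Ca in [0.2, 1.4]
# mS/cm^2 box with a diagonal onset boundary; a soft (small-amplitude,
# quasi-sinusoidal) oscillation onset whose peak-to-peak amplitude grows
# from below 1 mV at the boundary to the mid-teens deep in the region,
# inside the 0.5-25 mV experimental range; and intrinsic frequencies of
# roughly 6-13 Hz that rise with g_Ca.
version: 2
m:
  half: -58.0      # mV, half-activation
  slope: 10.0      # mV
  exponent: 3      # dimensionless
h:
  half: -70.0      # mV, half-inactivation
  slope: 8.0       # mV
tau_h:
  base: 45.0       # ms, floor at depolarized potentials
  amplitude: 450.0 # ms, added at hyperpolarized potentials
  half: -68.0      # mV
  slope: 9.0       # mV
E_Ca: 120.0        # mV, Ca2+ reversal potential
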