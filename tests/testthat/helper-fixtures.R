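# Shared fixtures, built in code.

# canonical pyruvate-run kinetics (apparent mode) and its acquisition
fig1a_truth <- function() kinetic_params(10.7e-5, 30, 16, "apparent", S0 = 1)
fig1a_acq <- function() acquisition_params(8, 2, 120)

# a short noiseless series for quick structural tests
quick_series <- function(n = 20, k = 5.278e-5, T1s = 9, T1p = 17) {
  evolve_closed_form(kinetic_params(k, T1s, T1p, "apparent", S0 = 1),
                     times = seq(0, by = 2, length.out = n))
}

# descending 13C axis covering the default peak windows
c13_axis <- function(step = 0.01, from = 200, to = 80) {
  seq(from, to, by = -step)
}

lactate_doublet <- function(amplitude = 1, linewidth_Hz = 2) {
  peak_definition("lactate", 183.5, c(181, 186), multiplicity = "doublet",
                  J_Hz = 55, linewidth_Hz = linewidth_Hz,
                  amplitude = amplitude)
}

# maximum absolute deviation between unit-peak-normalized traces
max_dev_unit_peak <- function(a, b) {
  max(abs(a / max(a) - b / max(b)))
}
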