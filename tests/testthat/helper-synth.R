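# shared fixtures built in code

default_protocol <- function() test_protocol()

# constant-section geometry with a chosen total area (mm^2)
geom_with_area <- function(a0 = 0.3, n = 3) {
  w <- sqrt(4 * a0 / pi)  # circle of that area: width = height
  specimen_geometry(widths = rep(w, n), heights = rep(w, n))
}

# a noise-free synthetic specimen plus everything needed to analyze it
make_specimen <- function(E = 25, uts = 3, toe = 0.05, noise_sd = 0,
                          drag = 0, seed = 1L, a0 = 0.3, slack = 0.05) {
  geom <- geom_with_area(a0)
  params <- constitutive_params(E, uts, toe_strain = toe, noise_sd = noise_sd,
                                drag_amplitude = drag, seed = seed)
  protocol <- default_protocol()
  list(trace = gen_trace(params, geom, protocol, slack_mm = slack),
       geom = geom, params = params, protocol = protocol)
}

# direct stress-strain curve from strain/stress arrays (unit gauge/area
# bookkeeping handled so eng_stress equals `stress` exactly)
curve_from_arrays <- function(strain, stress, a0 = 0.5, gauge = 5) {
  tr <- tensile_trace(time = seq_along(strain) * 0.05,
                      extension = strain * gauge,
                      load = stress * 2 * a0)
  to_stress_strain(tr, 1, gauge, a0)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
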