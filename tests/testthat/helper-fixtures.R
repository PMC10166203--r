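# shared fixtures: everything is generated in code at test time

# constant-property set with puree-like magnitudes (admits the analytic
# conduction oracle and exact conservation checks)
const_props <- function(rho = 1070, mu = 40, k = 0.58, cp = 3860) {
  thermo_properties(rho, mu, k, cp, valid_range = c(200, 500), name = "const")
}

# mesh builders that swallow the headspace-snap message
quiet_mesh <- function(geometry = can_geometry(), nr = 12, nz = 24) {
  suppressMessages(build_mesh(geometry, nr = nr, nz = nz))
}

# default can without headspace (fully filled) for symmetric benchmarks
solid_mesh <- function(nr = 12, nz = 24) {
  build_mesh(can_geometry(headspace_height = 0), nr = nr, nz = nz)
}

# Horner-form polynomial oracle, independent of the package's evaluator
horner <- function(coeffs, x) {
  out <- 0
  for (c in rev(coeffs)) out <- out * x + c
  out
}

run_steps <- function(state, schedule, config, n) {
  for (k in seq_len(n)) state <- advance(state, schedule, config)
  state
}
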