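# bench-like assemblies and closed-form datasets used across test files

bench_assembly <- function(R = 667.9, bore = 0.37, rho = 1) {
  csf_assembly(
    needle_spec("test needle", "22G", length = 9, resistance = R),
    manometer_spec(bore),
    fluid_properties(density = rho))
}

# exact graduation-crossing dataset from the closed-form rise curve
closed_form_dataset <- function(p = 13, tau = 72, heights = 1:12, rho = 1) {
  h_eq <- p / rho
  rise_dataset(time_to_fraction(heights / h_eq, tau), heights,
               needle = sprintf("closed form P=%g tau=%g", p, tau))
}
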