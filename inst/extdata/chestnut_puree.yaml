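# Default can/product configuration: sweetened chestnut puree in a #9121 tin.
# Polynomial coefficients are in kelvin, highest order first (constant last).
properties:
  name: chestnut_puree
  density:
    coefficients: [-3.5e-9, -0.4472664761, 1225.5567102981]
    units: "kg/m^3"
    argument: "K"
  viscosity:
    coefficients: [-1.387024283936e-8, 2.59069861904587e-5, -0.019355480214816,
                   7.23213374403098, -1351.86899336611, 101200.919774749]
    units: "Pa s"
    argument: "K"
  conductivity:
    coefficients: [4.531e-6, -0.00272, 0.982]
    units: "W/(m K)"
    argument: "K"
  specific_heat:
    value: 3860
    units: "J/(kg K)"
  valid_range_K: [303.15, 400.15]
  extrapolation_policy: extrapolate
geometry:
  inner_diameter: {value: 98.9, units: mm}
  height: {value: 121, units: mm}
  wall_thickness: {value: 0.2, units: mm}
  headspace: {value: 5, units: mm}
schedule:
  notation: "10-86-24/121"
  come_up_start_C: 68
  cooling_water_C: 25
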