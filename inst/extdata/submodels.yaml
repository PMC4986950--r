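# Sub-model coefficient file for the forest flammability simulator.
#
# Every block records: the functional form used (formula id), its
# coefficients, the input ranges over which the form is considered valid,
# and a provenance note. Coefficients are package defaults chosen from the
# standard physics of each process and calibrated once to give realistic
# eucalypt-forest magnitudes; they are deliberately external to the code so
# that laboratory refits can replace them without touching the engine.

flame:
  # Temperature sustained inside a flame envelope (degrees C).
  temperature_c: 950.0
  provenance: "typical fine-fuel diffusion flame temperature"

plume:
  # T(d) = ambient + (T_flame - ambient) * (L / d) ^ decay_exponent, d > L;
  # T(d) = T_flame for 0 <= d <= L. Classic buoyant-plume far-field scaling.
  formula: power_decay
  decay_exponent: 1.667
  provenance: "point-source plume temperature scaling, exponent 5/3"

flame_angle:
  # angle = atan( g * L / (wind_coef * U^2) ), vertical (pi/2) at U = 0;
  # slope rotates the effective angle: angle - slope_coef * slope_radians,
  # clamped to [min_angle, pi/2]. Downslope (negative slope) steepens the
  # plume relative to the overhead fuel column.
  formula: froude_tilt
  wind_coef: 1.0
  slope_coef: 1.0
  min_angle: 0.05
  provenance: "Froude-number flame-tilt form; buoyancy vs wind shear"

flame_merge:
  # L_merged = per_leaf_length * n ^ exponent, exponent <= 1.
  formula: power_law
  exponent: 0.5
  provenance: "sublinear growth from mutual air entrainment between flames"

time_to_ignition:
  # t_ig = a * IC / (T - t_ref) ^ power for T >= endotherm, else no ignition.
  # Increasing in the ignitability coefficient, decreasing in plume
  # temperature, diverging toward the reference temperature t_ref.
  formula: hyperbolic
  a: 60.0
  t_ref: 100.0
  power: 1.0
  valid_range:
    ic: [0.1, 200.0]
    temperature_c: [100.0, 1400.0]
  provenance: "piloted-ignition delay inversely proportional to excess temperature"

flame_duration:
  # dur = a * (width_mm * thickness_mm) ^ area_exponent * exp(moisture_coef * m)
  # with m in %ODW. Depends on leaf cross-section only through the product.
  formula: area_power
  a: 1.2
  area_exponent: 0.6
  moisture_coef: 0.002
  valid_range:
    area_mm2: [0.05, 200.0]
    moisture_odw: [20.0, 300.0]
  provenance: "cross-section area and moisture dominate sustainability of leaf flaming"

leaf_flame_length:
  # fl = a * length_m ^ length_exponent * width_m ^ width_exponent
  #        * exp(-moisture_coef * m). Vanishes for degenerate leaves.
  formula: dimension_power
  a: 5.0
  length_exponent: 0.8
  width_exponent: 0.4
  moisture_coef: 0.003
  valid_range:
    leaf_length_m: [0.005, 0.6]
    moisture_odw: [20.0, 300.0]
  provenance: "leaf length, width and moisture dominate combustibility of single leaves"

microclimate:
  # u(z) = u_open * exp(-attenuation_per_lai * LAI_above(z)); only foliage in
  # non-burning strata above z attenuates. WRF = u_open / u(wrf_height).
  formula: exponential_lai
  attenuation_per_lai: 0.6
  wrf_height: 1.5
  # One-sided leaf area = shape factor * length * width per leaf form.
  leaf_area_shape:
    flat: 0.7853981634   # ellipse, pi/4
    round: 1.0       # projected area of a terete leaf
  provenance: "canopy-flow exponential attenuation in cumulative leaf area"

surface_fire:
  # Litter-bed pilot flame:
  # L = a * load ^ load_exponent * exp(-dfmc_coef * dfmc) * (1 + wind_coef * u)
  # with load in t/ha, dfmc a fraction of ODW, u in m/s at reference height.
  # dur = dur_a * load ^ dur_exponent seconds.
  formula: litter_power
  a: 0.1
  load_exponent: 0.75
  dfmc_coef: 5.0
  wind_coef: 0.3
  dur_a: 3.0
  dur_exponent: 0.8
  reference_height: 1.5
  # Approximate domain of the laboratory data behind the litter model;
  # inputs outside the box are clamped to its boundary and flagged.
  # Bounds are provisional pending transcription from the source data.
  domain:
    fuel_load: [1.0, 25.0]
    dfmc: [0.03, 0.15]
    wind: [0.0, 8.0]
    slope: [-30.0, 30.0]
  provenance: "power-law litter flame length, exponential moisture damping"

propagation:
  time_step_s: 1.0
  max_steps: 600
  # Plume axis taken from the flame tip for inter-stratum transfer
  # (alternative: flame mid-point).
  plume_origin: tip

default_traits:
  # Live moisture (%ODW) by functional group when not measured.
  moisture:
    standard: 100.0
    mesic_herb: 150.0
    very_green: 200.0
  # Minimum piloted ignition temperature (degrees C) by leaf aromaticity.
  ignition_temperature:
    aromatic: 220.0
    non_aromatic: 260.0
  # Grasses/ferns with a measured silica-free ash content (%): linear
  # relation, provisional coefficients.
  ash_relation:
    intercept: 220.0
    slope: 2.0
  # Proportion of dead foliage when not estimated in the field.
  percent_dead:
    c4_grass: 0.5
    default: 0.0

treatments:
  # Group means for the structure-only treatment are unweighted over the
  # species table; switch to composition weighting here.
  group_mean_weighting: equal

sensitivity:
  k_folds: 10
  n_runs: 1000
  n_lambda: 100
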