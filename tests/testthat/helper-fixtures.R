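# Shared fixtures (built in code) and test-only oracle implementations that
# re-evaluate the configured sub-model relations independently of the
# package code paths.

fixture_species <- function(stratum = "elevated", name = "shrub",
                            thickness = 3e-4, width = 0.01, length = 0.05,
                            moisture = 100, dead = 0.05, endo = 260,
                            packing = 60, clump_d = 0.3, clump_s = 0.2,
                            form = "flat", group = "dicotyledon",
                            composition = 1) {
  ffm_species(name, stratum, form, thickness, width, length, moisture, dead,
              endo, packing, clump_d, clump_s, group, composition)
}

fixture_stratum <- function(stratum = "elevated", species = NULL,
                            plant_sep = 2, base_c = 0.5, base_e = 0.6,
                            top = 2, top_e = 1.8, width = 1.5) {
  if (is.null(species)) species <- fixture_species(stratum)
  ffm_stratum(stratum, species, plant_sep, base_c, base_e, top, top_e, width)
}

# a small three-strata site on which fire reliably climbs out of the litter
fixture_site <- function(site_id = "fx1", surface_fuel = 18) {
  ns <- fixture_stratum("near_surface",
                        fixture_species("near_surface", "grass",
                                        thickness = 3e-4, width = 0.005,
                                        length = 0.3, moisture = 100,
                                        dead = 0.3, endo = 260,
                                        packing = 120, clump_d = 0.25,
                                        clump_s = 0.1,
                                        group = "monocotyledon"),
                        plant_sep = 0.7, base_c = 0, base_e = 0,
                        top = 0.4, top_e = 0.35, width = 0.4)
  el <- fixture_stratum("elevated",
                        fixture_species("elevated", "shrub"),
                        plant_sep = 2, base_c = 0.5, base_e = 0.6,
                        top = 2, top_e = 1.8, width = 1.5)
  ca <- fixture_stratum("canopy",
                        fixture_species("canopy", "eucalypt",
                                        thickness = 4e-4, width = 0.02,
                                        length = 0.12, moisture = 100,
                                        dead = 0, endo = 220,
                                        packing = 400, clump_d = 1,
                                        clump_s = 0.5),
                        plant_sep = 8, base_c = 10, base_e = 11,
                        top = 18, top_e = 17, width = 4.5)
  ffm_site(site_id, list(ns, el, ca), surface_fuel)
}

fixture_weather <- function(slope = 0, wind = 10, temp = 30, rh = 40,
                            dfmc = 0.06) {
  ffm_weather(slope, wind, temp, rh, dfmc)
}

# ---- independent oracle evaluations of the configured relations ----

oracle_cfg <- function() {
  yaml::read_yaml(system.file("extdata", "submodels.yaml", package = "ffmr"))
}

oracle_tig <- function(temp, ic, endo, oc = oracle_cfg()) {
  co <- oc$time_to_ignition
  if (temp < endo || temp <= co$t_ref) return(Inf)
  co$a * ic / (temp - co$t_ref)^co$power
}

oracle_duration <- function(width_m, thick_m, moisture, oc = oracle_cfg()) {
  co <- oc$flame_duration
  co$a * ((width_m * 1000) * (thick_m * 1000))^co$area_exponent *
    exp(co$moisture_coef * moisture)
}

oracle_flame_length <- function(len_m, width_m, moisture,
                                oc = oracle_cfg()) {
  co <- oc$leaf_flame_length
  max(0, co$a * len_m^co$length_exponent * width_m^co$width_exponent *
        exp(-co$moisture_coef * moisture))
}

oracle_angle <- function(L, u, slope = 0, oc = oracle_cfg()) {
  co <- oc$flame_angle
  base <- if (abs(u) <= 0 || L <= 0) pi / 2 else
    atan(9.81 * L / (co$wind_coef * u^2))
  min(pi / 2, max(co$min_angle, base - co$slope_coef * slope * pi / 180))
}

oracle_surface_length <- function(load, dfmc, u, oc = oracle_cfg()) {
  co <- oc$surface_fire
  clamp <- function(x, b) min(max(x, b[[1]]), b[[2]])
  load <- clamp(load, co$domain$fuel_load)
  dfmc <- clamp(dfmc, co$domain$dfmc)
  u <- clamp(abs(u), co$domain$wind)
  co$a * load^co$load_exponent * exp(-co$dfmc_coef * dfmc) *
    (1 + co$wind_coef * u)
}

# attenuated wind speed by direct layer-by-layer evaluation
oracle_wind_speed <- function(z, u_open, strata, oc = oracle_cfg()) {
  k <- oc$microclimate$attenuation_per_lai
  total <- 0
  for (s in strata) {
    lai_s <- stratum_lai(s)
    lo <- s$crown_base_centre_height
    hi <- s$crown_height
    frac <- if (hi <= lo) as.numeric(z < hi) else
      min(1, max(0, (hi - z) / (hi - lo)))
    total <- total + lai_s * frac
  }
  u_open * exp(-k * total)
}

# even-odd point-in-polygon test, coded independently of the package
oracle_in_poly <- function(px, pz, poly) {
  n <- nrow(poly)
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x1 <- poly[i, 1]; z1 <- poly[i, 2]
    x2 <- poly[j, 1]; z2 <- poly[j, 2]
    if ((z1 <= pz && z2 > pz) || (z2 <= pz && z1 > pz)) {
      xc <- x1 + (pz - z1) / (z2 - z1) * (x2 - x1)
      if (xc > px) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# chord length of a ray through a polygon by fine-grid sampling
oracle_chord <- function(origin_h, angle, poly, t_max, dt = 0.002) {
  ts <- seq(0, t_max, by = dt)
  xs <- ts * cos(angle)
  zs <- origin_h + ts * sin(angle)
  inside <- mapply(oracle_in_poly, xs, zs, MoreArgs = list(poly = poly))
  sum(inside) * dt
}
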