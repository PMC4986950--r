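# Leaf-scale flammability sub-models: ignitability (ignitability coefficient
# and time to ignition), sustainability (flame duration) and combustibility
# (leaf flame length). Coefficients come from the shared YAML configuration;
# every relation is clamped at zero so extrapolation outside the fitted trait
# ranges cannot produce negative durations or flame lengths.

#' Mean foliage moisture from live and dead components
#'
#' Foliage moisture entering the ignitability coefficient is the mean of live
#' and dead moisture contents weighted by the proportion of dead material in
#' the plant. The dead component is the site dead-fuel moisture content,
#' which affects suspended dead fuel as well as litter.
#'
#' @param live Live foliage moisture (%ODW), > 0.
#' @param dead Dead foliage moisture (%ODW), > 0.
#' @param percent_dead Proportion of dead foliage, in `[0, 1]`.
#' @return Mean moisture (%ODW).
#' @examples
#' mean_leaf_moisture(100, 10, 0.5)  # 55
#' @export
mean_leaf_moisture <- function(live, dead, percent_dead) {
  stopifnot(all(live > 0), all(dead > 0),
            all(percent_dead >= 0 & percent_dead <= 1))
  percent_dead * dead + (1 - percent_dead) * live
}

# sides presenting a free surface: a flat lamina has two, a terete
# (round) leaf one continuous surface
n_leaf_sides <- function(leaf_form) {
  sides <- c(flat = 2, round = 1)[leaf_form]
  if (anyNA(sides)) stop_invalid("unknown leaf_form '%s'",
                                 leaf_form[is.na(sides)][1])
  unname(sides)
}

#' Ignitability coefficient
#'
#' IC = moisture (%ODW) x thickness (mm) / number of sides on the leaf.
#' Higher IC means more water per unit heated surface, hence lower
#' ignitability.
#'
#' @param moisture Foliage moisture (%ODW), > 0 (see [mean_leaf_moisture()]).
#' @param thickness_mm Leaf thickness in millimetres, > 0.
#' @param leaf_form `"flat"` (2 sides) or `"round"` (1 side).
#' @return The ignitability coefficient (%ODW mm per side).
#' @examples
#' ignitability_coefficient(100, 0.2, "flat")  # 10
#' @export
ignitability_coefficient <- function(moisture, thickness_mm, leaf_form) {
  stopifnot(all(moisture > 0), all(thickness_mm > 0))
  moisture * thickness_mm / n_leaf_sides(leaf_form)
}

#' Time to ignition of a receiver leaf
#'
#' The heating time required for piloted ignition increases as the plume
#' temperature decreases and as leaf ignitability decreases (IC increases).
#' Below the leaf's minimum piloted ignition temperature (the endotherm) no
#' amount of heating ignites it and `Inf` is returned.
#'
#' The configured relation is `t_ig = a * IC / (T - t_ref)^power` for
#' `T >= ignition_temperature`.
#'
#' @param plume_temp Plume air temperature at the leaf (deg C).
#' @param ic Ignitability coefficient, > 0.
#' @param ignition_temperature The leaf endotherm (deg C).
#' @param config An [ffm_config()] list.
#' @return Seconds to ignition, or `Inf` when the plume is below the
#'   endotherm (no ignition).
#' @export
time_to_ignition <- function(plume_temp, ic, ignition_temperature,
                             config = ffm_config()) {
  co <- cfg_block(config, "time_to_ignition", c("a", "t_ref", "power"))
  stopifnot(all(ic > 0), is.numeric(co$a), is.numeric(co$t_ref))
  excess <- plume_temp - co$t_ref
  t_ig <- ifelse(plume_temp < ignition_temperature | excess <= 0,
                 Inf, co$a * ic / excess^co$power)
  t_ig
}

#' Flame duration of a burning leaf
#'
#' Sustainability of flaming: how long a single leaf burns. Driven by the
#' leaf cross-section area (width x thickness) and moisture; the configured
#' relation depends on width and thickness only through their product.
#'
#' @param width,thickness Leaf width and thickness in metres, > 0.
#' @param moisture Foliage moisture (%ODW).
#' @param config An [ffm_config()] list.
#' @return Flame duration in seconds, > 0.
#' @export
leaf_flame_duration <- function(width, thickness, moisture,
                                config = ffm_config()) {
  co <- cfg_block(config, "flame_duration",
                  c("a", "area_exponent", "moisture_coef"))
  stopifnot(all(width > 0), all(thickness > 0))
  area_mm2 <- (width * 1000) * (thickness * 1000)
  co$a * area_mm2^co$area_exponent * exp(co$moisture_coef * moisture)
}

#' Flame length of a burning leaf
#'
#' Combustibility: the flame length produced by a single burning leaf, driven
#' by leaf length, width and moisture content. Degenerate (zero-dimension)
#' leaves produce zero flame; the result is clamped at zero.
#'
#' @param length,width Leaf length and width in metres, >= 0.
#' @param moisture Foliage moisture (%ODW).
#' @param config An [ffm_config()] list.
#' @return Flame length in metres, >= 0.
#' @export
leaf_flame_length <- function(length, width, moisture,
                              config = ffm_config()) {
  co <- cfg_block(config, "leaf_flame_length",
                  c("a", "length_exponent", "width_exponent",
                    "moisture_coef"))
  stopifnot(all(length >= 0), all(width >= 0))
  pmax(0, co$a * length^co$length_exponent * width^co$width_exponent *
         exp(-co$moisture_coef * moisture))
}

#' Species-weighted leaf flammability summary for a stratum
#'
#' Collapses a stratum's species table into the composition-weighted mean
#' leaf flammability used for stratum-level donor/receiver tests: mean
#' moisture (dead component from site DFMC), ignitability coefficient,
#' endotherm, per-leaf flame duration and flame length, and mean clump
#' geometry.
#'
#' @param stratum An [ffm_stratum()].
#' @param dfmc Site dead fuel moisture content (fraction ODW).
#' @param config An [ffm_config()] list.
#' @return A list with fields `moisture`, `ic`, `ignition_temperature`,
#'   `flame_duration`, `flame_length`, `leaf_packing`, `clump_diameter`,
#'   `clump_separation`.
#' @export
stratum_leaf_flammability <- function(stratum, dfmc, config = ffm_config()) {
  sp <- stratum$species
  w <- sp$composition / sum(sp$composition)
  moist <- mean_leaf_moisture(sp$live_moisture, dfmc * 100, sp$percent_dead)
  ic <- ignitability_coefficient(moist, sp$leaf_thickness * 1000,
                                 sp$leaf_form)
  dur <- leaf_flame_duration(sp$leaf_width, sp$leaf_thickness, moist, config)
  fl <- leaf_flame_length(sp$leaf_length, sp$leaf_width, moist, config)
  list(
    moisture = sum(w * moist),
    ic = sum(w * ic),
    ignition_temperature = sum(w * sp$ignition_temperature),
    flame_duration = sum(w * dur),
    flame_length = sum(w * fl),
    leaf_packing = sum(w * sp$leaf_packing),
    clump_diameter = sum(w * sp$clump_diameter),
    clump_separation = sum(w * sp$clump_separation)
  )
}
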