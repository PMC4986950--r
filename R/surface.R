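# Surface litter pilot fire: the empirical litter-bed flame model that
# initiates the simulation. Its coefficients and the approximate domain of
# the laboratory data behind it are configuration entries; inputs outside
# the domain are clamped to the boundary and flagged.

#' Surface litter flame
#'
#' Produces the pilot flame from the surface fine fuel bed. Flame length
#' follows the configured litter relation (monotone increasing in fuel load,
#' decreasing in dead fuel moisture, increasing in wind); flame height is
#' derived through the wind-tilted flame angle, so height equals length only
#' at zero wind on flat ground. Inputs outside the configured validity
#' domain are clamped to the boundary and `in_domain` is set `FALSE`.
#'
#' @param fuel_load Surface fine fuel load (t/ha), > 0.
#' @param dfmc Dead fuel moisture content (fraction of oven-dry weight).
#' @param surface_wind Wind speed at the surface reference height (m/s,
#'   signed).
#' @param slope Slope (degrees, signed).
#' @param config An [ffm_config()] list.
#' @return A list of class `ffm_surface_fire` with `flame_length`,
#'   `flame_angle`, `flame_height`, `flame_duration` (s) and `in_domain`.
#' @examples
#' surface_flame(15, 0.07, 1.5, 0)
#' @export
surface_flame <- function(fuel_load, dfmc, surface_wind, slope = 0,
                          config = ffm_config()) {
  co <- cfg_block(config, "surface_fire",
                  c("a", "load_exponent", "dfmc_coef", "wind_coef",
                    "dur_a", "dur_exponent", "domain"))
  if (fuel_load <= 0) stop_invalid("surface fuel load must be > 0")
  dom <- co$domain
  clamp <- function(x, b) min(max(x, b[[1]]), b[[2]])
  load_c <- clamp(fuel_load, dom$fuel_load)
  dfmc_c <- clamp(dfmc, dom$dfmc)
  wind_c <- sign(surface_wind) * clamp(abs(surface_wind), dom$wind)
  slope_c <- clamp(slope, dom$slope)
  in_domain <- isTRUE(all.equal(
    c(load_c, dfmc_c, abs(wind_c), slope_c),
    c(fuel_load, dfmc, abs(surface_wind), slope)))

  L <- co$a * load_c^co$load_exponent * exp(-co$dfmc_coef * dfmc_c) *
    (1 + co$wind_coef * abs(wind_c))
  dur <- co$dur_a * load_c^co$dur_exponent
  ang <- flame_angle(L, wind_c, slope_c, config)
  structure(list(flame_length = L, flame_angle = ang,
                 flame_height = L * sin(ang), flame_duration = dur,
                 in_domain = in_domain),
            class = "ffm_surface_fire")
}

#' @export
print.ffm_surface_fire <- function(x, ...) {
  cat(sprintf(
    "Surface flame: length %.2f m, height %.2f m, duration %.0f s%s\n",
    x$flame_length, x$flame_height, x$flame_duration,
    if (x$in_domain) "" else " [inputs clamped to model domain]"))
  invisible(x)
}
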