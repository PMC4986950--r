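# Microclimate: stratum leaf area index and the vertical wind-speed profile
# (overstorey sheltering). Only foliage above a height shelters that height;
# the wind reduction factor (WRF) summarises the profile as open wind divided
# by the wind at 1.5 m.

#' Leaf area index of a stratum
#'
#' One-sided leaf area per unit ground area, built up mechanistically:
#' leaf area (shape factor x length x width) x leaves per clump x clumps per
#' crown (crown volume over clump cell volume) x crowns per ground area
#' (one per plant_separation squared). Species are combined by composition
#' weight.
#'
#' @param stratum An [ffm_stratum()].
#' @param config An [ffm_config()] list.
#' @return LAI (unitless), >= 0.
#' @export
stratum_lai <- function(stratum, config = ffm_config()) {
  co <- cfg_block(config, "microclimate", "leaf_area_shape")
  sp <- stratum$species
  w <- sp$composition / sum(sp$composition)
  shape <- unlist(co$leaf_area_shape)[sp$leaf_form]
  leaf_area <- shape * sp$leaf_length * sp$leaf_width
  centre_depth <- stratum$crown_height - stratum$crown_base_centre_height
  edge_depth <- stratum$crown_top_edge_height - stratum$crown_base_edge_height
  crown_volume <- pi / 4 * stratum$crown_width^2 *
    (centre_depth + edge_depth) / 2
  cell <- pi / 6 * (sp$clump_diameter + sp$clump_separation)^3
  clumps <- crown_volume / cell
  per_plant_area <- leaf_area * sp$leaf_packing * clumps
  sum(w * per_plant_area) / stratum$plant_separation^2
}

# vertical occupancy [z_low, z_high] of a stratum's foliage
stratum_span <- function(stratum) {
  c(stratum$crown_base_centre_height, stratum$crown_height)
}

# cumulative LAI above height z from the given strata, attributing each
# stratum's LAI uniformly over its vertical crown span
lai_above <- function(z, strata, lai) {
  if (length(strata) == 0) return(rep(0, length(z)))
  out <- numeric(length(z))
  for (i in seq_along(strata)) {
    span <- stratum_span(strata[[i]])
    depth <- span[2] - span[1]
    frac <- if (depth <= 0) as.numeric(z < span[2])
            else pmin(1, pmax(0, (span[2] - z) / depth))
    out <- out + lai[i] * frac
  }
  out
}

#' Vertical wind-speed profile under a vegetated canopy
#'
#' Wind above the canopy penetrates downward attenuated exponentially in the
#' cumulative leaf area index of the (non-burning) foliage above each height.
#' Speed at the canopy top equals the open wind; the magnitude is monotone
#' non-increasing downward; sign is preserved. The wind reduction factor is
#' `WRF = open_wind / speed(1.5 m)`, >= 1 whenever any foliage is present.
#'
#' @param open_wind Above-canopy wind speed (m/s, signed).
#' @param strata List of [ffm_stratum()] objects providing shelter (burning
#'   strata should be excluded by the caller).
#' @param heights Heights (m) at which to evaluate the profile.
#' @param config An [ffm_config()] list.
#' @return A list of class `ffm_wind_profile` with `open_wind`, `heights`,
#'   `speeds` and `wrf`, plus a `speed_at(z)` interpolator.
#' @export
wind_profile <- function(open_wind, strata, heights = NULL,
                         config = ffm_config()) {
  co <- cfg_block(config, "microclimate",
                  c("attenuation_per_lai", "wrf_height"))
  strata <- unname(as.list(strata))
  lai <- vapply(strata, stratum_lai, numeric(1), config = config)
  speed_at <- function(z) {
    open_wind * exp(-co$attenuation_per_lai * lai_above(z, strata, lai))
  }
  if (is.null(heights)) {
    heights <- sort(unique(c(0, co$wrf_height,
                             vapply(strata, stratum_span, numeric(2)))))
  }
  ref <- speed_at(co$wrf_height)
  wrf <- if (abs(open_wind) < 1e-12) 1 else abs(open_wind) / max(abs(ref), 1e-12)
  structure(list(open_wind = open_wind, heights = heights,
                 speeds = speed_at(heights), lai = lai, wrf = wrf,
                 speed_at = speed_at),
            class = "ffm_wind_profile")
}

#' @export
print.ffm_wind_profile <- function(x, ...) {
  cat(sprintf("Wind profile: open %.2f m/s, WRF %.2f\n", x$open_wind, x$wrf))
  invisible(x)
}
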