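# Domain types: species trait tables, stratum and site structure, weather
# records and observed flame-height intervals, with validators. Units are
# metres, degrees Celsius, %ODW for moisture, t/ha for surface fuel load and
# km/h for the raw wind record (converted to m/s at the module boundary).

#' Vegetation strata, ordered from the ground up
#' @export
FFM_STRATA <- c("near_surface", "elevated", "midstorey", "canopy")

# upper bound of the ambient temperature range the model is used over;
# ignition temperatures must exceed it
AMBIENT_MAX_C <- 37.6

kmh_to_ms <- function(v) v / 3.6

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Species leaf-trait table
#'
#' Builds and validates the per-species leaf trait table: morphology
#' (form, thickness, width, length), moisture (%ODW live, proportion dead),
#' chemistry (minimum piloted ignition temperature, the endotherm), and
#' within-crown clump geometry (leaves per clump, clump diameter and
#' separation). One row per species per stratum.
#'
#' @param name Species label.
#' @param stratum One of `r paste(FFM_STRATA, collapse = ", ")`.
#' @param leaf_form `"flat"` or `"round"` (terete).
#' @param leaf_thickness Leaf thickness in metres.
#' @param leaf_width,leaf_length Leaf width and length in metres.
#' @param live_moisture Live foliage moisture, percent of oven-dry weight.
#' @param percent_dead Proportion of dead foliage in the plant, in `[0, 1]`.
#' @param ignition_temperature Minimum piloted ignition temperature (deg C).
#' @param leaf_packing Mean number of leaves per foliage clump.
#' @param clump_diameter,clump_separation Clump geometry in metres.
#' @param taxon_group `"monocotyledon"` or `"dicotyledon"`.
#' @param composition Within-stratum composition weight; weights are
#'   normalised to sum to one per stratum.
#' @return A `data.frame` with one validated row per species.
#' @export
ffm_species <- function(name, stratum, leaf_form, leaf_thickness, leaf_width,
                        leaf_length, live_moisture = NA_real_,
                        percent_dead = NA_real_,
                        ignition_temperature = NA_real_,
                        leaf_packing, clump_diameter, clump_separation,
                        taxon_group = "dicotyledon", composition = 1) {
  df <- data.frame(
    name = as.character(name), stratum = as.character(stratum),
    leaf_form = as.character(leaf_form),
    leaf_thickness = as.numeric(leaf_thickness),
    leaf_width = as.numeric(leaf_width),
    leaf_length = as.numeric(leaf_length),
    live_moisture = as.numeric(live_moisture),
    percent_dead = as.numeric(percent_dead),
    ignition_temperature = as.numeric(ignition_temperature),
    leaf_packing = as.numeric(leaf_packing),
    clump_diameter = as.numeric(clump_diameter),
    clump_separation = as.numeric(clump_separation),
    taxon_group = as.character(taxon_group),
    composition = as.numeric(composition),
    stringsAsFactors = FALSE
  )
  # moisture, endotherm and percent-dead may still be NA here; they are
  # completed by apply_default_traits() and checked in full at stratum
  # assembly
  validate_species(df, allow_partial = TRUE)
  df
}

#' Validate a species trait table
#'
#' @param df A species trait `data.frame` as built by [ffm_species()].
#' @param allow_partial If `TRUE`, moisture, ignition temperature and
#'   percent-dead may be `NA` (to be filled by [apply_default_traits()]).
#' @return `df`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_species <- function(df, allow_partial = FALSE) {
  need <- c("name", "stratum", "leaf_form", "leaf_thickness", "leaf_width",
            "leaf_length", "leaf_packing", "clump_diameter",
            "clump_separation")
  for (f in need) {
    if (is.null(df[[f]]) || anyNA(df[[f]]))
      stop_invalid("species table: mandatory field '%s' is missing or NA", f)
  }
  if (!all(df$stratum %in% FFM_STRATA))
    stop_invalid("species table: unknown stratum '%s'",
                 setdiff(df$stratum, FFM_STRATA)[1])
  if (!all(df$leaf_form %in% c("flat", "round")))
    stop_invalid("species table: leaf_form must be 'flat' or 'round'")
  pos <- c("leaf_thickness", "leaf_width", "leaf_length", "clump_diameter")
  for (f in pos) {
    if (any(df[[f]] <= 0))
      stop_invalid("species table: '%s' must be > 0 (species '%s')",
                   f, df$name[df[[f]] <= 0][1])
  }
  if (any(df$clump_separation < 0))
    stop_invalid("species table: clump_separation must be >= 0")
  if (any(df$leaf_packing < 0))
    stop_invalid("species table: leaf_packing must be >= 0")
  flat <- df$leaf_form == "flat"
  if (any(flat & df$leaf_width < df$leaf_thickness))
    stop_invalid("species table: flat leaves need leaf_width >= leaf_thickness (species '%s')",
                 df$name[flat & df$leaf_width < df$leaf_thickness][1])
  # range checks apply to any supplied value; only NAs are negotiable
  if (any(df$live_moisture <= 0, na.rm = TRUE))
    stop_invalid("species table: live_moisture must be > 0 %%ODW")
  if (any(df$percent_dead < 0 | df$percent_dead > 1, na.rm = TRUE))
    stop_invalid("species table: percent_dead must lie in [0, 1]")
  if (any(df$ignition_temperature <= AMBIENT_MAX_C, na.rm = TRUE))
    stop_invalid("species table: ignition_temperature must exceed the ambient range (%.1f C)",
                 AMBIENT_MAX_C)
  if (!allow_partial &&
      (anyNA(df$live_moisture) || anyNA(df$percent_dead) ||
       anyNA(df$ignition_temperature)))
    stop_invalid("species table: live_moisture, percent_dead and ignition_temperature must be complete (see apply_default_traits)")
  invisible(df)
}

#' Fill missing trait values by functional-group rules
#'
#' Field trait tables rarely carry measured moisture, ignition temperature or
#' dead-fraction values for every species; standard values are applied by
#' functional group. Missing live moisture is filled by moisture class
#' (100 %ODW standard, 150 for herbs and some mesic species, 200 for very
#' green herbs and mesic species). Missing ignition temperature is filled by
#' aromaticity (220 deg C aromatic, 260 otherwise), or, for grasses and ferns
#' with a supplied silica-free ash content, by the configured linear ash
#' relation. Missing percent-dead is 0.5 for C4 grasses and 0 otherwise.
#'
#' Optional columns consulted: `moisture_class`
#' (`standard`/`mesic_herb`/`very_green`), `aromatic` (logical), `c4_grass`
#' (logical), `silica_free_ash` (percent, grasses/ferns only).
#'
#' @param df A species table, possibly with `NA` moisture, ignition
#'   temperature or percent-dead.
#' @param config An [ffm_config()] list supplying the `default_traits` block.
#' @return The completed, validated species table.
#' @examples
#' sp <- ffm_species("shrub", "elevated", "flat", 3e-4, 0.01, 0.05,
#'                   leaf_packing = 60, clump_diameter = 0.3,
#'                   clump_separation = 0.2)
#' sp$live_moisture <- NA
#' apply_default_traits(sp)$live_moisture  # 100
#' @export
apply_default_traits <- function(df, config = ffm_config()) {
  validate_species(df, allow_partial = TRUE)
  rules <- cfg_block(config, "default_traits",
                     c("moisture", "ignition_temperature", "percent_dead"))

  mclass <- df$moisture_class %||% rep("standard", nrow(df))
  mclass[is.na(mclass)] <- "standard"
  fill <- is.na(df$live_moisture)
  if (any(fill)) {
    m <- unlist(rules$moisture)[mclass[fill]]
    if (anyNA(m))
      stop_invalid("unknown moisture_class '%s'",
                   mclass[fill][is.na(m)][1])
    df$live_moisture[fill] <- as.numeric(m)
  }

  fill <- is.na(df$ignition_temperature)
  if (any(fill)) {
    ash <- df$silica_free_ash %||% rep(NA_real_, nrow(df))
    aromatic <- df$aromatic %||% rep(FALSE, nrow(df))
    aromatic[is.na(aromatic)] <- FALSE
    ash_rel <- rules$ash_relation
    use_ash <- fill & !is.na(ash)
    df$ignition_temperature[use_ash] <-
      ash_rel$intercept + ash_rel$slope * ash[use_ash]
    rest <- fill & is.na(ash)
    df$ignition_temperature[rest] <- ifelse(
      aromatic[rest],
      rules$ignition_temperature$aromatic,
      rules$ignition_temperature$non_aromatic)
  }

  fill <- is.na(df$percent_dead)
  if (any(fill)) {
    c4 <- df$c4_grass %||% rep(FALSE, nrow(df))
    c4[is.na(c4)] <- FALSE
    df$percent_dead[fill] <- ifelse(c4[fill],
                                    rules$percent_dead$c4_grass,
                                    rules$percent_dead$default)
  }

  validate_species(df)
  df
}

#' Stratum structure
#'
#' One vegetation stratum of a site: its species (with composition weights),
#' plant spacing, and the five crown-envelope heights that define the
#' symmetric hexagonal crown cross-section used for plume-pathway geometry.
#'
#' @param stratum Stratum label, one of [FFM_STRATA].
#' @param species Species trait table for this stratum (complete traits).
#' @param plant_separation Centre-to-centre plant spacing (m), > 0.
#' @param crown_base_centre_height,crown_base_edge_height Heights (m) of the
#'   crown base at the centreline and at the crown edge.
#' @param crown_height Height (m) of the top of the crown at the centreline.
#' @param crown_top_edge_height Height (m) of the crown top at the edge.
#' @param crown_width Crown width (m).
#' @return A list of class `ffm_stratum`.
#' @export
ffm_stratum <- function(stratum, species, plant_separation,
                        crown_base_centre_height, crown_base_edge_height,
                        crown_height, crown_top_edge_height, crown_width) {
  st <- structure(list(
    stratum = as.character(stratum),
    species = species,
    plant_separation = as.numeric(plant_separation),
    crown_base_centre_height = as.numeric(crown_base_centre_height),
    crown_base_edge_height = as.numeric(crown_base_edge_height),
    crown_height = as.numeric(crown_height),
    crown_top_edge_height = as.numeric(crown_top_edge_height),
    crown_width = as.numeric(crown_width)
  ), class = "ffm_stratum")
  validate_stratum(st)
  st
}

#' @rdname ffm_stratum
#' @param x An `ffm_stratum`.
#' @export
validate_stratum <- function(x) {
  if (!x$stratum %in% FFM_STRATA)
    stop_invalid("stratum: unknown label '%s'", x$stratum)
  validate_species(x$species)
  if (!all(x$species$stratum == x$stratum))
    stop_invalid("stratum '%s': species rows carry a different stratum label",
                 x$stratum)
  if (!(x$plant_separation > 0))
    stop_invalid("stratum '%s': plant_separation must be > 0", x$stratum)
  if (!(x$crown_width > 0))
    stop_invalid("stratum '%s': crown_width must be > 0", x$stratum)
  if (x$crown_base_centre_height < 0)
    stop_invalid("stratum '%s': crown_base_centre_height must be >= 0",
                 x$stratum)
  if (x$crown_base_edge_height < x$crown_base_centre_height)
    stop_invalid("stratum '%s': crown base at the edge must sit at or above the centre base",
                 x$stratum)
  if (x$crown_height < x$crown_base_edge_height)
    stop_invalid("stratum '%s': crown_height must be >= crown_base_edge_height",
                 x$stratum)
  if (x$crown_top_edge_height > x$crown_height)
    stop_invalid("stratum '%s': crown_top_edge_height must be <= crown_height",
                 x$stratum)
  if (x$crown_top_edge_height < x$crown_base_edge_height)
    stop_invalid("stratum '%s': crown top edge must be >= crown base edge",
                 x$stratum)
  invisible(x)
}

#' Site structure
#'
#' A site: up to one stratum per label (any may be absent) plus the surface
#' fine fuel load. Strata must be vertically ordered: crown heights
#' non-decreasing from near-surface to canopy.
#'
#' @param site_id Site identifier.
#' @param strata A list of [ffm_stratum()] objects.
#' @param surface_fuel_load Surface fine fuel load (t/ha), > 0.
#' @return A list of class `ffm_site`.
#' @export
ffm_site <- function(site_id, strata = list(), surface_fuel_load) {
  names(strata) <- vapply(strata, function(s) s$stratum, character(1))
  site <- structure(list(
    site_id = as.character(site_id),
    strata = strata,
    surface_fuel_load = as.numeric(surface_fuel_load)
  ), class = "ffm_site")
  validate_site(site)
  site
}

#' @rdname ffm_site
#' @param x An `ffm_site`.
#' @export
validate_site <- function(x) {
  if (!(x$surface_fuel_load > 0))
    stop_invalid("site '%s': surface_fuel_load must be > 0", x$site_id)
  labs <- vapply(x$strata, function(s) s$stratum, character(1))
  if (anyDuplicated(labs))
    stop_invalid("site '%s': more than one stratum labelled '%s'",
                 x$site_id, labs[duplicated(labs)][1])
  for (s in x$strata) validate_stratum(s)
  present <- FFM_STRATA[FFM_STRATA %in% labs]
  if (length(present) > 1) {
    hts <- vapply(present, function(l) x$strata[[l]]$crown_height, numeric(1))
    if (any(diff(hts) < 0))
      stop_invalid("site '%s': strata crown heights must be ordered near_surface <= elevated <= midstorey <= canopy",
                   x$site_id)
  }
  invisible(x)
}

# strata of a site in ground-up order
site_strata <- function(site) {
  labs <- FFM_STRATA[FFM_STRATA %in% names(site$strata)]
  site$strata[labs]
}

#' Weather record
#'
#' Exogenous drivers for one site burn. Wind and slope are signed relative to
#' the direction of fire spread: flanks burning at right angles to the wind
#' get zero wind, and downslope spread gets a negative slope.
#'
#' @param slope Slope (degrees, signed), `|slope| <= 45`.
#' @param wind_velocity Open (above-canopy) wind speed (km/h, signed).
#' @param air_temperature Air temperature (deg C).
#' @param relative_humidity Relative humidity (percent, in (0, 100]).
#' @param dfmc Dead fuel moisture content, a fraction of oven-dry weight.
#' @return A list of class `ffm_weather`.
#' @export
ffm_weather <- function(slope, wind_velocity, air_temperature,
                        relative_humidity, dfmc) {
  w <- structure(list(
    slope = as.numeric(slope),
    wind_velocity = as.numeric(wind_velocity),
    air_temperature = as.numeric(air_temperature),
    relative_humidity = as.numeric(relative_humidity),
    dfmc = as.numeric(dfmc)
  ), class = "ffm_weather")
  validate_weather(w)
  w
}

#' @rdname ffm_weather
#' @param x An `ffm_weather`.
#' @export
validate_weather <- function(x) {
  if (!(x$dfmc > 0))
    stop_invalid("weather: dfmc must be > 0 (fraction of oven-dry weight)")
  if (!(x$relative_humidity > 0 && x$relative_humidity <= 100))
    stop_invalid("weather: relative_humidity must lie in (0, 100]")
  if (abs(x$slope) > 45)
    stop_invalid("weather: |slope| must be <= 45 degrees")
  invisible(x)
}

#' Observed flame-height interval
#'
#' The field convention bounds flame height below by the height of combustion
#' (loss of leaves and fine twigs) and above by the lowest of the scorch
#' height or the base of the next unconsumed stratum.
#'
#' @param site_id Site identifier.
#' @param lower,median,upper Interval bounds and central estimate (m), with
#'   `0 <= lower <= median <= upper`.
#' @return A one-row `data.frame`.
#' @export
ffm_observation <- function(site_id, lower, median, upper) {
  if (lower < 0 || median < lower || upper < median)
    stop_invalid("observation '%s': need 0 <= lower <= median <= upper",
                 site_id)
  data.frame(site_id = as.character(site_id), lower = as.numeric(lower),
             median = as.numeric(median), upper = as.numeric(upper),
             stringsAsFactors = FALSE)
}

#' @export
print.ffm_site <- function(x, ...) {
  cat(sprintf("Site '%s': surface fuel %.1f t/ha, %d strata\n",
              x$site_id, x$surface_fuel_load, length(x$strata)))
  for (s in site_strata(x)) {
    cat(sprintf("  %-12s %d species, crown %.1f-%.1f m, plants every %.1f m\n",
                s$stratum, nrow(s$species), s$crown_base_centre_height,
                s$crown_height, s$plant_separation))
  }
  invisible(x)
}
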