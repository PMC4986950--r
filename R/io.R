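# Tabular I/O: delimited-text schemas for species traits, site structure,
# weather and observations, with validation on read (row numbers in error
# messages) and a JSON export of validated site bundles. Leaf thickness is
# carried in millimetres in files (signalled by the column name) and
# converted to metres internally; all other lengths are metres.

SPECIES_COLS <- c("site_id", "stratum", "name", "composition", "leaf_form",
                  "leaf_thickness_mm", "leaf_width_m", "leaf_length_m",
                  "live_moisture", "percent_dead", "ignition_temperature",
                  "leaf_packing", "clump_diameter_m", "clump_separation_m",
                  "taxon_group")
STRUCTURE_COLS <- c("site_id", "stratum", "plant_separation",
                    "crown_base_centre_height", "crown_base_edge_height",
                    "crown_height", "crown_top_edge_height", "crown_width",
                    "surface_fuel_load")
WEATHER_COLS <- c("site_id", "slope", "wind_velocity_kmh", "air_temperature",
                  "relative_humidity", "dfmc")

check_schema <- function(df, cols, what, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_invalid("%s file '%s': missing columns %s", what, path,
                 paste(missing, collapse = ", "))
  df
}

check_numeric <- function(df, cols, what, path) {
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop_invalid("%s file '%s': non-numeric value in column '%s', line %d",
                   what, path, col, bad[1] + 1L)  # +1 for the header row
    if (anyNA(v))
      stop_invalid("%s file '%s': missing value in column '%s', line %d",
                   what, path, col, which(is.na(v))[1] + 1L)
    df[[col]] <- v
  }
  df
}

#' Read site tables from delimited text files
#'
#' Reads and validates the species, structure and weather CSVs (UTF-8,
#' header row) and assembles them into validated site bundles. Leaf
#' thickness is read in millimetres (`leaf_thickness_mm`) and converted to
#' metres; wind is carried in km/h in the weather file. Schema mismatches,
#' non-numeric cells and violated invariants are reported with file and
#' line context.
#'
#' @param species_path,structure_path,weather_path CSV paths.
#' @param observations_path Optional observations CSV
#'   (`site_id, lower, median, upper`).
#' @return A list with `sites`, `weather` and (optionally) `observations`.
#' @export
read_site_tables <- function(species_path, structure_path, weather_path,
                             observations_path = NULL) {
  sp <- check_schema(utils::read.csv(species_path, stringsAsFactors = FALSE),
                     SPECIES_COLS, "species", species_path)
  sp <- check_numeric(sp, c("composition", "leaf_thickness_mm",
                            "leaf_width_m", "leaf_length_m",
                            "live_moisture", "percent_dead",
                            "ignition_temperature", "leaf_packing",
                            "clump_diameter_m", "clump_separation_m"),
                      "species", species_path)
  st <- check_schema(utils::read.csv(structure_path,
                                     stringsAsFactors = FALSE),
                     STRUCTURE_COLS, "structure", structure_path)
  st <- check_numeric(st, setdiff(STRUCTURE_COLS, c("site_id", "stratum")),
                      "structure", structure_path)
  we <- check_schema(utils::read.csv(weather_path, stringsAsFactors = FALSE),
                     WEATHER_COLS, "weather", weather_path)
  we <- check_numeric(we, setdiff(WEATHER_COLS, "site_id"),
                      "weather", weather_path)

  sites <- list()
  for (sid in unique(st$site_id)) {
    srows <- st[st$site_id == sid, ]
    strata <- list()
    for (k in seq_len(nrow(srows))) {
      r <- srows[k, ]
      spr <- sp[sp$site_id == sid & sp$stratum == r$stratum, ]
      if (!nrow(spr))
        stop_invalid("site '%s': no species rows for stratum '%s'",
                     sid, r$stratum)
      species <- data.frame(
        name = spr$name, stratum = spr$stratum, leaf_form = spr$leaf_form,
        leaf_thickness = spr$leaf_thickness_mm / 1000,
        leaf_width = spr$leaf_width_m, leaf_length = spr$leaf_length_m,
        live_moisture = spr$live_moisture, percent_dead = spr$percent_dead,
        ignition_temperature = spr$ignition_temperature,
        leaf_packing = spr$leaf_packing,
        clump_diameter = spr$clump_diameter_m,
        clump_separation = spr$clump_separation_m,
        taxon_group = spr$taxon_group,
        composition = spr$composition / sum(spr$composition),
        stringsAsFactors = FALSE)
      strata[[r$stratum]] <- ffm_stratum(
        r$stratum, species, r$plant_separation, r$crown_base_centre_height,
        r$crown_base_edge_height, r$crown_height, r$crown_top_edge_height,
        r$crown_width)
    }
    sites[[sid]] <- ffm_site(sid, strata, srows$surface_fuel_load[1])
  }

  weather <- list()
  for (k in seq_len(nrow(we))) {
    r <- we[k, ]
    weather[[r$site_id]] <- ffm_weather(r$slope, r$wind_velocity_kmh,
                                        r$air_temperature,
                                        r$relative_humidity, r$dfmc)
  }

  out <- list(sites = unname(sites[unique(st$site_id)]),
              weather = unname(weather[unique(st$site_id)]))
  if (!is.null(observations_path)) {
    ob <- utils::read.csv(observations_path, stringsAsFactors = FALSE)
    check_schema(ob, c("site_id", "lower", "median", "upper"),
                 "observations", observations_path)
    out$observations <- ob
  }
  out
}

num_fmt <- function(x) formatC(x, format = "g", digits = 10)

#' Write site tables to delimited text files
#'
#' Writes the CSV schemas that [read_site_tables()] reads; a
#' write-read-write round trip is byte-identical.
#'
#' @param sites List of [ffm_site()] objects.
#' @param weather List of [ffm_weather()] records matching `sites`.
#' @param dir Output directory (created if needed).
#' @param observations Optional observations data frame.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_site_tables <- function(sites, weather, dir, observations = NULL) {
  stopifnot(length(sites) == length(weather))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp_rows <- list(); st_rows <- list(); we_rows <- list()
  for (i in seq_along(sites)) {
    site <- sites[[i]]
    for (s in site_strata(site)) {
      spd <- s$species
      sp_rows[[length(sp_rows) + 1L]] <- data.frame(
        site_id = site$site_id, stratum = s$stratum, name = spd$name,
        composition = num_fmt(spd$composition), leaf_form = spd$leaf_form,
        leaf_thickness_mm = num_fmt(spd$leaf_thickness * 1000),
        leaf_width_m = num_fmt(spd$leaf_width),
        leaf_length_m = num_fmt(spd$leaf_length),
        live_moisture = num_fmt(spd$live_moisture),
        percent_dead = num_fmt(spd$percent_dead),
        ignition_temperature = num_fmt(spd$ignition_temperature),
        leaf_packing = num_fmt(spd$leaf_packing),
        clump_diameter_m = num_fmt(spd$clump_diameter),
        clump_separation_m = num_fmt(spd$clump_separation),
        taxon_group = spd$taxon_group, stringsAsFactors = FALSE)
      st_rows[[length(st_rows) + 1L]] <- data.frame(
        site_id = site$site_id, stratum = s$stratum,
        plant_separation = num_fmt(s$plant_separation),
        crown_base_centre_height = num_fmt(s$crown_base_centre_height),
        crown_base_edge_height = num_fmt(s$crown_base_edge_height),
        crown_height = num_fmt(s$crown_height),
        crown_top_edge_height = num_fmt(s$crown_top_edge_height),
        crown_width = num_fmt(s$crown_width),
        surface_fuel_load = num_fmt(site$surface_fuel_load),
        stringsAsFactors = FALSE)
    }
    w <- weather[[i]]
    we_rows[[length(we_rows) + 1L]] <- data.frame(
      site_id = site$site_id, slope = num_fmt(w$slope),
      wind_velocity_kmh = num_fmt(w$wind_velocity),
      air_temperature = num_fmt(w$air_temperature),
      relative_humidity = num_fmt(w$relative_humidity),
      dfmc = num_fmt(w$dfmc), stringsAsFactors = FALSE)
  }
  paths <- c(species = file.path(dir, "species.csv"),
             structure = file.path(dir, "structure.csv"),
             weather = file.path(dir, "weather.csv"))
  utils::write.csv(do.call(rbind, sp_rows), paths["species"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, st_rows), paths["structure"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, we_rows), paths["weather"],
                   row.names = FALSE, quote = FALSE)
  if (!is.null(observations)) {
    paths["observations"] <- file.path(dir, "observations.csv")
    ob <- observations
    for (col in c("lower", "median", "upper")) ob[[col]] <- num_fmt(ob[[col]])
    utils::write.csv(ob, paths["observations"], row.names = FALSE,
                     quote = FALSE)
  }
  invisible(paths)
}

#' Export a validated site bundle as JSON
#'
#' @param bundle A list with `sites` and `weather` (as returned by
#'   [read_site_tables()] or [ffm_synthetic_sites()]).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
ffm_export_json <- function(bundle, path) {
  out <- list(
    sites = lapply(bundle$sites, function(site) {
      list(site_id = site$site_id,
           surface_fuel_load = site$surface_fuel_load,
           strata = lapply(unname(site_strata(site)), function(s) {
             list(stratum = s$stratum,
                  plant_separation = s$plant_separation,
                  crown_base_centre_height = s$crown_base_centre_height,
                  crown_base_edge_height = s$crown_base_edge_height,
                  crown_height = s$crown_height,
                  crown_top_edge_height = s$crown_top_edge_height,
                  crown_width = s$crown_width,
                  species = s$species)
           }))
    }),
    weather = lapply(bundle$weather, unclass)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
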