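# The three comparative treatments. F uses the surface litter model alone
# (under the vegetation-sheltered wind); FS adds stand structure but
# averages leaf traits into monocotyledon/dicotyledon groups and collapses
# internal crown structure; FSL is the full model with species-specific
# traits and clump structure.

treatment_record <- function(site_id, treatment, fire) {
  list(site_id = site_id, treatment = treatment,
       predicted_flame_height = fire$max_flame_height,
       donor_flame_heights = fire$donor_flame_heights,
       sum_lai = sum(fire$lai),
       canopy_lai = if ("canopy" %in% names(fire$lai))
         fire$lai[["canopy"]] else 0,
       mean_ic = fire$mean_ic,
       wrf = fire$wrf,
       strata_burnt = fire$strata_burnt)
}

#' Group-mean species table for the structure-only treatment
#'
#' Averages every leaf trait into the two taxon groups (monocotyledon,
#' dicotyledon): each species' numeric traits are replaced by its group's
#' unweighted mean (a config switch selects composition weighting), and the
#' modal leaf form in the group is used. Internal crown structure is
#' collapsed to a single uniform clump filling the crown depth with zero
#' separation.
#'
#' @param site An [ffm_site()].
#' @param config An [ffm_config()] list.
#' @return An `ffm_site` with group-mean traits and degenerate clump
#'   structure.
#' @export
fs_site <- function(site, config = ffm_config()) {
  all_sp <- do.call(rbind, lapply(site_strata(site), function(s) s$species))
  if (is.null(all_sp) || !nrow(all_sp)) return(site)
  weighting <- cfg_block(config, "treatments",
                         "group_mean_weighting")$group_mean_weighting
  num <- c("leaf_thickness", "leaf_width", "leaf_length", "live_moisture",
           "percent_dead", "ignition_temperature", "leaf_packing")
  groups <- split(all_sp, all_sp$taxon_group)
  gmean <- lapply(groups, function(g) {
    w <- if (identical(weighting, "composition")) {
      g$composition / sum(g$composition)
    } else rep(1 / nrow(g), nrow(g))
    means <- vapply(num, function(f) sum(w * g[[f]]), numeric(1))
    forms <- tapply(w, g$leaf_form, sum)
    list(means = means, form = names(forms)[which.max(forms)])
  })
  strata <- lapply(site$strata, function(st) {
    sp <- st$species
    for (i in seq_len(nrow(sp))) {
      gm <- gmean[[sp$taxon_group[i]]]
      if (is.null(gm)) stop_invalid("missing group mean for taxon group '%s'",
                                    sp$taxon_group[i])
      sp[i, num] <- as.list(gm$means)
      sp$leaf_form[i] <- gm$form
    }
    # internal structure not characterised: one clump filling the crown
    depth <- st$crown_height - st$crown_base_centre_height
    sp$clump_diameter <- max(depth, 1e-3)
    sp$clump_separation <- 0
    st$species <- sp
    st
  })
  ffm_site(site$site_id, strata, site$surface_fuel_load)
}

#' Run one model treatment for a site
#'
#' * `"F"` — surface fuel only: the litter pilot flame under the
#'   vegetation-sheltered wind; standing plants affect the prediction only
#'   through their wind sheltering, and no stratum ignition is attempted.
#' * `"FS"` — surface fuel and stand structure: the full engine, but leaf
#'   traits averaged into monocotyledon/dicotyledon groups and internal
#'   crown structure collapsed (see [fs_site()]).
#' * `"FSL"` — surface fuel, structure and leaf traits: the full engine with
#'   species-specific traits and clump structure.
#'
#' @param site An [ffm_site()].
#' @param weather An [ffm_weather()].
#' @param treatment `"F"`, `"FS"` or `"FSL"`.
#' @param config An [ffm_config()] list.
#' @return A prediction record: list with `site_id`, `treatment`,
#'   `predicted_flame_height`, `donor_flame_heights`, `sum_lai`,
#'   `canopy_lai`, `mean_ic`, `wrf`, `strata_burnt`.
#' @export
run_treatment <- function(site, weather, treatment = c("FSL", "FS", "F"),
                          config = ffm_config()) {
  treatment <- match.arg(treatment)
  validate_site(site)
  site_run <- switch(treatment,
                     F = site,
                     FS = fs_site(site, config),
                     FSL = site)
  if (treatment == "F") {
    co_surf <- cfg_block(config, "surface_fire", "reference_height")
    strata <- site_strata(site)
    profile <- wind_profile(kmh_to_ms(weather$wind_velocity), strata,
                            config = config)
    surf <- surface_flame(site$surface_fuel_load, weather$dfmc,
                          profile$speed_at(co_surf$reference_height),
                          weather$slope, config)
    lai <- setNames(vapply(strata, stratum_lai, numeric(1), config = config),
                    names(strata))
    fire <- list(max_flame_height = surf$flame_height,
                 donor_flame_heights = c(surface = surf$flame_height),
                 lai = lai, mean_ic = NA_real_, wrf = profile$wrf,
                 strata_burnt = character(0))
    return(treatment_record(site$site_id, "F", fire))
  }
  fire <- ffm_run(site_run, weather, config)
  treatment_record(site$site_id, treatment, fire)
}

#' Run all three treatments over a set of sites
#'
#' @param sites List of [ffm_site()] objects.
#' @param weather List of [ffm_weather()] records, one per site.
#' @param treatments Character vector of treatments to run.
#' @param config An [ffm_config()] list.
#' @return A `data.frame` of class `ffm_predictions`, one row per site x
#'   treatment, with the prediction and the covariates used by the
#'   sensitivity analysis (`donor_fh`: the maximum donor flame height below
#'   the highest receiver stratum).
#' @export
ffm_treatments <- function(sites, weather, treatments = c("F", "FS", "FSL"),
                           config = ffm_config()) {
  stopifnot(length(sites) == length(weather))
  rows <- list()
  for (i in seq_along(sites)) {
    for (tr in treatments) {
      rec <- run_treatment(sites[[i]], weather[[i]], tr, config)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = rec$site_id, treatment = rec$treatment,
        predicted_flame_height = rec$predicted_flame_height,
        donor_fh = donor_below_top(rec$donor_flame_heights),
        sum_lai = rec$sum_lai, canopy_lai = rec$canopy_lai,
        mean_ic = rec$mean_ic, wrf = rec$wrf,
        n_strata_burnt = length(rec$strata_burnt),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("ffm_predictions", "data.frame"))
}

# maximum donor flame height below the highest receiver stratum: drop the
# top-most stratum entry and take the max of what remains (surface included)
donor_below_top <- function(donor_fh) {
  labs <- intersect(FFM_STRATA, names(donor_fh))
  if (length(labs)) donor_fh <- donor_fh[setdiff(names(donor_fh),
                                                 labs[length(labs)])]
  max(donor_fh)
}
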