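# Seeded synthetic-stand generator: sites, species tables, weather records
# and observed flame-height intervals drawn within the structural, trait and
# weather ranges the model is parameterised for, so the whole pipeline can
# be exercised without field data. Species traits are jittered around
# synthetic archetypes (a eucalypt canopy, wattle/tea-tree midstorey,
# sclerophyll and mesic shrubs, tussock grass and forbs); these archetypes
# are illustrative, not measurements of real taxa. Observed intervals are
# manufactured by running the full simulator (the species-trait treatment)
# on each generated site and widening its prediction with configurable
# noise, so ground truth is recoverable by construction.

# printed parameter ranges the generator draws from, per stratum
default_ranges <- function() {
  list(
    surface_fuel_load = c(9.6, 24.3),
    plant_separation = list(near_surface = c(0.1, 3.6),
                            elevated = c(0.7, 8.9),
                            midstorey = c(3.2, 26.4),
                            canopy = c(0.5, 14.1)),
    crown_height = list(near_surface = c(0.1, 1.0),
                        elevated = c(0.2, 6.0),
                        midstorey = c(2.0, 15.0),
                        canopy = c(8.0, 35.0)),
    crown_width = list(near_surface = c(0.1, 1.9),
                       elevated = c(0.4, 4.2),
                       midstorey = c(1.5, 10.2),
                       canopy = c(2.8, 6.8)),
    base_centre_frac = c(0.0, 0.55),
    weather = list(slope = c(-28, 21), wind_velocity = c(-21, 30),
                   air_temperature = c(12.5, 37.6),
                   relative_humidity = c(13.0, 63.5),
                   dfmc = c(0.036, 0.137)),
    presence = c(near_surface = 1.0, elevated = 0.9, midstorey = 0.8,
                 canopy = 0.95),
    species_per_stratum = c(1, 3),
    trait_jitter = 0.2
  )
}

read_archetypes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_species_archetypes.csv",
                        package = "ffmr")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

runif1 <- function(r) runif(1, r[1], r[2])

# one stratum: geometry within printed ranges, invariants by construction
gen_stratum <- function(stratum, ranges, arch, min_height) {
  H <- max(runif1(ranges$crown_height[[stratum]]), min_height)
  bc <- runif1(ranges$base_centre_frac) * H
  be <- min(H, bc + runif(1, 0, 0.15) * H)
  te <- max(be, runif(1, 0.75, 1.0) * H)
  w <- runif1(ranges$crown_width[[stratum]])
  pool <- arch[arch$stratum == stratum, ]
  n_sp <- sample(seq(ranges$species_per_stratum[1],
                     ranges$species_per_stratum[2]), 1)
  rows <- pool[sample(nrow(pool), n_sp, replace = TRUE), ]
  j <- ranges$trait_jitter
  jit <- function(x) x * runif(length(x), 1 - j, 1 + j)
  sp <- data.frame(
    name = paste0(rows$name, "_", seq_len(n_sp)),
    stratum = stratum,
    leaf_form = rows$leaf_form,
    leaf_thickness = jit(rows$leaf_thickness_mm) / 1000,
    leaf_width = jit(rows$leaf_width_m),
    leaf_length = jit(rows$leaf_length_m),
    live_moisture = jit(rows$live_moisture),
    percent_dead = pmin(1, jit(rows$percent_dead)),
    ignition_temperature = rows$ignition_temperature,
    leaf_packing = round(jit(rows$leaf_packing)),
    clump_diameter = jit(rows$clump_diameter_m),
    clump_separation = jit(rows$clump_separation_m),
    taxon_group = rows$taxon_group,
    composition = 1 / n_sp,
    stringsAsFactors = FALSE
  )
  sp$leaf_width <- pmax(sp$leaf_width, sp$leaf_thickness)  # flat-leaf invariant
  ffm_stratum(stratum, sp, runif1(ranges$plant_separation[[stratum]]),
              bc, be, H, te, w)
}

gen_weather <- function(ranges) {
  wr <- ranges$weather
  ffm_weather(slope = runif1(wr$slope),
              wind_velocity = runif1(wr$wind_velocity),
              air_temperature = runif1(wr$air_temperature),
              relative_humidity = runif1(wr$relative_humidity),
              dfmc = runif1(wr$dfmc))
}

#' Generate a synthetic study: sites, weather and observed intervals
#'
#' Draws `n_sites` forest sites with up to four vegetation strata, species
#' trait tables jittered around synthetic archetypes, per-site weather, and
#' observed flame-height intervals. Every generated structure passes the
#' domain validators; strata geometry respects the vertical ordering
#' invariants by construction. Observed intervals are produced by running
#' the full simulator on each site and widening the prediction into an
#' interval: `half-width = hw_frac x prediction + hw_abs`, with the median
#' jittered inside the interval when `median_jitter` is on, and a fraction
#' of sites having their upper bound capped near the base of the lowest
#' unburnt stratum. With all noise parameters zero the interval collapses
#' to the prediction, so the full treatment recovers the truth exactly.
#' Output is deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param n_sites Number of sites, >= 1.
#' @param ranges Named overrides of the default parameter ranges.
#' @param noise List with `hw_frac`, `hw_abs`, `median_jitter`,
#'   `cap_fraction` controlling the observation noise model.
#' @param archetypes Optional path to an archetype CSV.
#' @param observations If `FALSE`, skip the truth-generating simulator runs
#'   and return only sites and weather (fast bulk generation).
#' @param config An [ffm_config()] list used for the truth-generating runs.
#' @return A list with `sites` (list of [ffm_site()]), `weather` (list of
#'   [ffm_weather()]), `observations` (data frame: site_id, lower, median,
#'   upper), `truth` (the generating predictions) and `seed`.
#' @examples
#' syn <- ffm_synthetic_sites(seed = 42, n_sites = 2)
#' names(syn$sites[[1]]$strata)
#' @export
ffm_synthetic_sites <- function(seed = 1, n_sites = 10, ranges = list(),
                                noise = list(), archetypes = NULL,
                                observations = TRUE,
                                config = ffm_config()) {
  stopifnot(n_sites >= 1)
  rg <- modifyList(default_ranges(), ranges)
  nz <- modifyList(list(hw_frac = 0.3, hw_abs = 0.2, median_jitter = TRUE,
                        cap_fraction = 0.2), noise)
  arch <- read_archetypes(archetypes)
  for (s in FFM_STRATA) {
    if (diff(rg$crown_height[[s]]) < 0)
      stop_invalid("infeasible crown_height range for stratum '%s'", s)
  }

  with_seed(seed, {
    sites <- vector("list", n_sites)
    weather <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      strata <- list()
      min_h <- 0
      for (s in FFM_STRATA) {
        if (runif(1) <= rg$presence[[s]]) {
          st <- gen_stratum(s, rg, arch, min_h)
          min_h <- st$crown_height
          strata[[s]] <- st
        }
      }
      sites[[i]] <- ffm_site(sprintf("site_%03d", i), strata,
                             runif1(rg$surface_fuel_load))
      weather[[i]] <- gen_weather(rg)
    }

    truth <- numeric(n_sites)
    obs <- vector("list", n_sites)
    if (observations) for (i in seq_len(n_sites)) {
      fire <- ffm_run(sites[[i]], weather[[i]], config)
      pred <- fire$max_flame_height
      truth[i] <- pred
      h <- nz$hw_frac * pred + nz$hw_abs
      med <- if (isTRUE(nz$median_jitter) && h > 0) {
        pred + runif(1, -0.5, 0.5) * h
      } else pred
      med <- max(med, 0)
      lower <- max(0, med - h)
      upper <- med + h
      if (h > 0 && runif(1) < nz$cap_fraction) {
        unburnt <- setdiff(names(sites[[i]]$strata), fire$strata_burnt)
        bases <- vapply(sites[[i]]$strata[unburnt],
                        function(s) s$crown_base_centre_height, numeric(1))
        bases <- bases[bases >= max(med, pred)]
        if (length(bases)) upper <- min(upper, min(bases))
      }
      upper <- max(upper, med, pred)   # truth stays recoverable
      lower <- min(lower, pred)
      obs[[i]] <- ffm_observation(sites[[i]]$site_id, lower, med, upper)
    }

    out <- list(sites = sites, weather = weather, seed = seed)
    if (observations) {
      out$observations <- do.call(rbind, obs)
      out$truth <- data.frame(
        site_id = vapply(sites, `[[`, character(1), "site_id"),
        predicted_flame_height = truth, stringsAsFactors = FALSE)
    }
    out
  })
}
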