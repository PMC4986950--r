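# The flame propagation engine: one-second time-stepped ignition and
# extinction bookkeeping from leaf to clump, plant and stratum. A surface
# litter flame pilots the run; each burning stratum's merged flame can
# ignite foliage in its own crown and in strata above, with convective heat
# dissipating over distance along the wind-tilted plume axis.

#' Depth of ignition along a plume
#'
#' The largest distance from the flame origin, along the plume axis, at
#' which receiver leaves can still be ignited: the heating time the donor
#' can supply (its remaining duration) must meet or exceed the receiver's
#' time to ignition at the local plume temperature, and the plume must be at
#' or above the receiver's endotherm. Found by bisection on the monotone
#' ignition condition.
#'
#' @param donor An [ffm_flame()] (its `duration_remaining` is the heating
#'   time available).
#' @param receiver A leaf flammability summary with fields `ic` and
#'   `ignition_temperature` (see [stratum_leaf_flammability()]).
#' @param ambient Ambient air temperature (deg C).
#' @param config An [ffm_config()] list.
#' @return Distance (m) from the flame origin; 0 when no distance qualifies.
#' @export
depth_of_ignition <- function(donor, receiver, ambient,
                              config = ffm_config()) {
  dur <- donor$duration_remaining
  if (dur <= 0 || donor$flame_length <= 0) return(0)
  ignites_at <- function(d) {
    temp <- plume_temperature(d, donor, ambient, config)
    t_ig <- time_to_ignition(temp, receiver$ic,
                             receiver$ignition_temperature, config)
    is.finite(t_ig) & t_ig <= dur
  }
  if (!ignites_at(0)) return(0)
  lo <- donor$flame_length   # everything inside the flame shares its temp
  hi <- max(2 * lo, 1)
  it <- 0
  while (ignites_at(hi) && it < 60) {
    lo <- hi
    hi <- hi * 2
    it <- it + 1
  }
  if (it >= 60) return(hi)  # effectively unbounded reach
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (ignites_at(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Number of leaves ignited along a pathway
#'
#' Counts the leaves inside the first `min(depth, path_length)` metres of a
#' plume pathway, given the periodic clump pattern (clump diameter +
#' separation) and the number of leaves per clump. Partial coverage of a
#' clump contributes proportionally; the count is floored to whole leaves.
#'
#' @param depth Depth of ignition measured into the pathway (m), >= 0.
#' @param path_length Length of the plume pathway through the crown (m).
#' @param traits A list with `leaf_packing`, `clump_diameter`,
#'   `clump_separation` (species-weighted means for a stratum).
#' @return Integer count of leaves, 0 when depth or path length is 0.
#' @export
leaves_ignited <- function(depth, path_length, traits) {
  stopifnot(depth >= 0, path_length >= 0)
  x <- min(depth, path_length)
  if (x <= 0) return(0L)
  period <- traits$clump_diameter + traits$clump_separation
  full <- floor(x / period)
  rem <- x - full * period
  partial <- min(rem, traits$clump_diameter) / traits$clump_diameter
  as.integer(floor(traits$leaf_packing * (full + partial)))
}

# per-stratum pre-computed quantities and mutable burning state
init_stratum_state <- function(stratum, dfmc, config) {
  flam <- stratum_leaf_flammability(stratum, dfmc, config)
  centre_depth <- stratum$crown_height - stratum$crown_base_centre_height
  capacity <- leaves_ignited(centre_depth, centre_depth, flam)
  list(stratum = stratum, flam = flam, capacity = capacity,
       cohorts = list(),       # each: list(expire, count)
       cum_ignited = 0L, leaves_burning = 0L,
       origin = stratum$crown_base_centre_height,
       max_flame_height = 0)
}

leaves_in_cohorts <- function(cohorts) {
  if (!length(cohorts)) return(0L)
  sum(vapply(cohorts, function(co) co$count, integer(1)))
}

stratum_flame <- function(st, wind_at_origin, slope, flame_temp, config) {
  if (st$leaves_burning <= 0) return(NULL)
  L <- merged_flame_length(st$leaves_burning, st$flam$flame_length, config)
  ang <- flame_angle(L, wind_at_origin, slope, config)
  ffm_flame(st$origin, L, ang, flame_temp, st$flam$flame_duration)
}

#' Advance the fire by one time step
#'
#' One tick of the engine: (1) cohorts whose flame duration has elapsed
#' extinguish; (2) strata are processed from the ground up — each stratum's
#' merged flame is recomputed from the leaves now burning, with its angle
#' set by the sheltered wind at its origin, and every active flame at or
#' below a stratum (surface pilot included) attempts to ignite leaves in
#' that stratum's crown through its plume pathway; (3) newly ignited leaves
#' join the burning pool, capped by the leaves available on the crown
#' centreline. Leaf-count conservation
#' (`burning = previous + newly - extinguished`) is asserted every step.
#'
#' @param state Engine state as produced by [ffm_run()] internals.
#' @param site An [ffm_site()].
#' @param weather An [ffm_weather()].
#' @param profile An `ffm_wind_profile` for the current step (burning strata
#'   excluded from sheltering).
#' @param config An [ffm_config()] list.
#' @return The updated state, with per-step bookkeeping in `state$record`.
#' @keywords internal
#' @export
ffm_step <- function(state, site, weather, profile, config) {
  t <- state$t + 1L
  flame_temp <- cfg_block(config, "flame", "temperature_c")$temperature_c
  ambient <- weather$air_temperature
  slope <- weather$slope
  strata_states <- state$strata
  n_strata <- length(strata_states)

  prev_burning <- unname(vapply(strata_states, function(s) s$leaves_burning,
                                integer(1)))

  # 1. extinction: retire cohorts whose duration has elapsed
  extinguished <- integer(n_strata)
  for (i in seq_len(n_strata)) {
    st <- strata_states[[i]]
    keep <- vapply(st$cohorts, function(co) co$expire > t, logical(1))
    extinguished[i] <- leaves_in_cohorts(st$cohorts[!keep])
    st$cohorts <- st$cohorts[keep]
    st$leaves_burning <- leaves_in_cohorts(st$cohorts)
    strata_states[[i]] <- st
  }

  # surface pilot flame, active for its configured duration
  surface_active <- t <= state$surface$flame_duration
  surf_flame <- NULL
  if (surface_active) {
    ang <- flame_angle(state$surface$flame_length,
                       profile$speed_at(0), slope, config)
    surf_flame <- ffm_flame(0, state$surface$flame_length, ang, flame_temp,
                            state$surface$flame_duration - (t - 1))
  }

  # 2.-3. ignition, escalating from the ground up; a stratum ignited this
  # step can immediately act as a donor for the strata above it
  flames <- vector("list", n_strata)
  for (i in seq_len(n_strata)) {
    st <- strata_states[[i]]
    flames[i] <- list(stratum_flame(st, profile$speed_at(st$origin), slope,
                                    flame_temp, config))
  }
  newly <- integer(n_strata)
  for (i in seq_len(n_strata)) {
    st <- strata_states[[i]]
    if (st$cum_ignited < st$capacity) {
      donors <- c(if (!is.null(surf_flame)) list(surf_flame),
                  Filter(Negate(is.null), flames[seq_len(i)]))
      best <- 0L
      for (donor in donors) {
        pw <- plume_pathway(donor, st$stratum, plant_offset = 0)
        if (pw$path_length <= 0) next
        d_ig <- depth_of_ignition(donor, st$flam, ambient, config)
        depth_in <- max(0, min(d_ig, pw$exit) - pw$entry)
        if (depth_in <= 0) next
        best <- max(best, leaves_ignited(depth_in, pw$path_length, st$flam))
      }
      newly[i] <- max(0L, min(best, st$capacity - st$cum_ignited))
      if (newly[i] > 0L) {
        expire <- t + max(1L, as.integer(round(st$flam$flame_duration)))
        st$cohorts <- c(st$cohorts, list(list(expire = expire,
                                              count = newly[i])))
        st$cum_ignited <- st$cum_ignited + newly[i]
        st$leaves_burning <- leaves_in_cohorts(st$cohorts)
        strata_states[[i]] <- st
        flames[i] <- list(stratum_flame(st, profile$speed_at(st$origin),
                                        slope, flame_temp, config))
      }
    }
  }

  # conservation of the leaf count ledger
  now_burning <- unname(vapply(strata_states, function(s) s$leaves_burning,
                               integer(1)))
  stopifnot(all(now_burning == prev_burning + newly - extinguished))

  heights <- c(if (surface_active) flame_height(surf_flame),
               vapply(Filter(Negate(is.null), flames), flame_height,
                      numeric(1)))
  overall <- if (length(heights)) max(heights) else 0
  for (i in seq_len(n_strata)) {
    if (!is.null(flames[[i]])) {
      strata_states[[i]]$max_flame_height <-
        max(strata_states[[i]]$max_flame_height, flame_height(flames[[i]]))
    }
  }

  state$t <- t
  state$strata <- strata_states
  state$record <- data.frame(
    t = t,
    surface_active = surface_active,
    overall_flame_height = overall,
    leaves_burning = I(list(now_burning)),
    newly_ignited = I(list(newly)),
    extinguished = I(list(extinguished))
  )
  state$active <- surface_active || any(now_burning > 0)
  state
}

#' Run the flame propagation simulator for one site
#'
#' Initialises the surface litter pilot flame under the sheltered wind
#' profile, then iterates one-second steps in which flames ignite foliage in
#' their own stratum and in strata above, until no flames remain or the step
#' cap is reached. The engine is fully deterministic.
#'
#' @param site An [ffm_site()].
#' @param weather An [ffm_weather()].
#' @param config An [ffm_config()] list.
#' @param max_steps Step cap; defaults to the configured value.
#' @return An object of class `ffm_fire`: a list with `site_id`,
#'   `trajectory` (one row per step), `max_flame_height` (m), `strata_burnt`
#'   (labels), `donor_flame_heights` (named, per stratum plus `surface`),
#'   `surface` (the pilot flame), `wrf`, `lai` (named per stratum) and
#'   `mean_ic`.
#' @examples
#' syn <- ffm_synthetic_sites(seed = 1, n_sites = 1)
#' fire <- ffm_run(syn$sites[[1]], syn$weather[[1]])
#' fire$max_flame_height
#' @export
ffm_run <- function(site, weather, config = ffm_config(),
                    max_steps = NULL) {
  validate_site(site)
  validate_weather(weather)
  prop <- cfg_block(config, "propagation", "max_steps")
  if (is.null(max_steps)) max_steps <- prop$max_steps
  co_surf <- cfg_block(config, "surface_fire", "reference_height")

  u_open <- kmh_to_ms(weather$wind_velocity)
  strata <- site_strata(site)
  lai <- vapply(strata, stratum_lai, numeric(1), config = config)

  profile0 <- wind_profile(u_open, strata, config = config)
  surf <- surface_flame(site$surface_fuel_load, weather$dfmc,
                        profile0$speed_at(co_surf$reference_height),
                        weather$slope, config)

  state <- list(
    t = 0L,
    strata = lapply(strata, init_stratum_state, dfmc = weather$dfmc,
                    config = config),
    surface = surf,
    active = TRUE
  )

  rows <- vector("list", max_steps)
  n_done <- 0L
  while (state$active && state$t < max_steps) {
    burning <- vapply(state$strata, function(s) s$leaves_burning > 0,
                      logical(1))
    profile <- wind_profile(u_open, strata[!burning], config = config)
    state <- ffm_step(state, site, weather, profile, config)
    n_done <- n_done + 1L
    rows[[n_done]] <- state$record
  }
  if (state$active) {
    warning("simulation truncated at ", max_steps, " steps for site '",
            site$site_id, "'")
  }
  traj <- do.call(rbind, rows[seq_len(n_done)])

  labs <- names(strata)
  donor_fh <- c(surface = surf$flame_height,
                setNames(vapply(state$strata,
                                function(s) s$max_flame_height, numeric(1)),
                         labs))
  burnt <- labs[vapply(state$strata, function(s) s$cum_ignited > 0,
                       logical(1))]
  max_h <- if (n_done) max(traj$overall_flame_height) else 0

  site_sp <- do.call(rbind, lapply(strata, function(s) s$species))
  mean_ic <- if (!is.null(site_sp) && nrow(site_sp)) {
    moist <- mean_leaf_moisture(site_sp$live_moisture, weather$dfmc * 100,
                                site_sp$percent_dead)
    mean(ignitability_coefficient(moist, site_sp$leaf_thickness * 1000,
                                  site_sp$leaf_form))
  } else NA_real_

  structure(list(
    site_id = site$site_id,
    trajectory = traj,
    n_steps = n_done,
    max_flame_height = max_h,
    strata_burnt = burnt,
    donor_flame_heights = donor_fh,
    surface = surf,
    wrf = profile0$wrf,
    lai = setNames(lai, labs),
    mean_ic = mean_ic
  ), class = "ffm_fire")
}

#' @export
print.ffm_fire <- function(x, ...) {
  cat(sprintf("Fire simulation, site '%s' (%d steps)\n", x$site_id,
              x$n_steps))
  cat(sprintf("  max flame height : %.2f m\n", x$max_flame_height))
  cat(sprintf("  strata burnt     : %s\n",
              if (length(x$strata_burnt)) paste(x$strata_burnt,
                                                collapse = ", ")
              else "none (surface only)"))
  cat(sprintf("  surface pilot    : %.2f m flame, WRF %.2f\n",
              x$surface$flame_height, x$wrf))
  invisible(x)
}

#' @export
summary.ffm_fire <- function(object, ...) {
  cat(sprintf("Fire simulation summary, site '%s'\n", object$site_id))
  print(object)
  cat("  donor flame heights (m):\n")
  for (nm in names(object$donor_flame_heights)) {
    cat(sprintf("    %-12s %.2f\n", nm, object$donor_flame_heights[[nm]]))
  }
  cat("  stratum LAI:\n")
  for (nm in names(object$lai)) {
    cat(sprintf("    %-12s %.3f\n", nm, object$lai[[nm]]))
  }
  invisible(object)
}

#' Plot the flame-height trajectory of a simulated fire
#' @param x An `ffm_fire`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ffm_fire <- function(x, ...) {
  if (is.null(x$trajectory) || !nrow(x$trajectory)) {
    stop("nothing to plot: empty trajectory")
  }
  graphics::plot(x$trajectory$t, x$trajectory$overall_flame_height,
                 type = "s", xlab = "time (s)", ylab = "flame height (m)",
                 main = sprintf("Site %s", x$site_id), ...)
  graphics::abline(h = x$surface$flame_height, lty = 3)
  invisible(x)
}
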