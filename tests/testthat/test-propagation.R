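cfg <- ffm_config()

test_that("depth of ignition agrees with an exhaustive 1 mm scan", {
  receiver <- list(ic = 20, ignition_temperature = 260)
  scan_depth <- function(donor, ambient) {
    d <- seq(0, 60, by = 0.001)
    temps <- plume_temperature(d, donor, ambient, cfg)
    ok <- is.finite(time_to_ignition(temps, receiver$ic,
                                     receiver$ignition_temperature, cfg)) &
      time_to_ignition(temps, receiver$ic,
                       receiver$ignition_temperature, cfg) <=
      donor$duration_remaining
    if (!any(ok)) 0 else max(d[ok])
  }
  for (L in c(0.3, 1, 3)) {
    for (dur in c(2, 8, 25)) {
      donor <- ffm_flame(0, L, pi / 2, 950, dur)
      expect_lt(abs(depth_of_ignition(donor, receiver, 30, cfg) -
                      scan_depth(donor, 30)), 2e-3)
    }
  }
  # no heating time: nothing ignites
  expect_equal(depth_of_ignition(ffm_flame(0, 1, pi / 2, 950, 0),
                                 receiver, 30, cfg), 0)
  # plume everywhere below the receiver endotherm
  cold <- list(ic = 20, ignition_temperature = 1000)
  expect_equal(depth_of_ignition(ffm_flame(0, 1, pi / 2, 950, 10),
                                 cold, 30, cfg), 0)
})

test_that("ignition reach grows with donor flame length", {
  receiver <- list(ic = 15, ignition_temperature = 220)
  reach <- vapply(c(0.2, 0.5, 1, 2, 4, 8), function(L) {
    depth_of_ignition(ffm_flame(0, L, pi / 2, 950, 10), receiver, 25, cfg)
  }, numeric(1))
  expect_true(all(diff(reach) >= 0))
})

test_that("leaves ignited along a pathway match a fine-grid enumeration", {
  traits <- list(leaf_packing = 40, clump_diameter = 0.3,
                 clump_separation = 0.2)
  expect_equal(leaves_ignited(0, 5, traits), 0L)
  expect_equal(leaves_ignited(5, 0, traits), 0L)
  # saturation: depth beyond the pathway counts every leaf on it
  expect_equal(leaves_ignited(100, 2.5, traits),
               leaves_ignited(2.5, 2.5, traits))

  enum <- function(x, traits) {
    if (x <= 0) return(0L)
    dt <- 1e-4
    pos <- seq(dt / 2, x, by = dt)
    period <- traits$clump_diameter + traits$clump_separation
    covered <- sum(pos %% period < traits$clump_diameter) * dt
    as.integer(floor(traits$leaf_packing * covered /
                       traits$clump_diameter))
  }
  set.seed(99)
  for (i in 1:20) {
    tr <- list(leaf_packing = sample(10:500, 1),
               clump_diameter = runif(1, 0.05, 1.2),
               clump_separation = runif(1, 0, 1))
    x <- runif(1, 0, 8)
    expect_lte(abs(leaves_ignited(x, 10, tr) - enum(x, tr)), 1L)
  }
})

test_that("step bookkeeping follows the ignition/extinction ledger", {
  # a single stratum whose fuel is exhausted: cohorts only expire
  site <- fixture_site()
  weather <- fixture_weather(wind = 0)
  st <- ffmr:::init_stratum_state(site$strata$elevated, weather$dfmc, cfg)
  st$cohorts <- list(list(expire = 3L, count = 4L),
                     list(expire = 5L, count = 6L))
  st$leaves_burning <- 10L
  st$cum_ignited <- st$capacity   # nothing left to ignite
  surf <- surface_flame(site$surface_fuel_load, weather$dfmc, 0, 0, cfg)
  surf$flame_duration <- 0        # pilot already out
  state <- list(t = 0L, strata = list(elevated = st), surface = surf,
                active = TRUE)
  profile <- wind_profile(0, list(), config = cfg)

  seen <- integer(0)
  for (k in 1:5) {
    state <- ffm_step(state, site, weather, profile, cfg)
    seen <- c(seen, state$record$leaves_burning[[1]])
  }
  # hand-traced: 10, 10 (no change), 6 (first cohort out), 6, 0 (all out)
  expect_identical(seen, c(10L, 10L, 6L, 6L, 0L))
  expect_false(state$active)
})

test_that("the engine conserves the leaf ledger and is deterministic", {
  site <- fixture_site()
  weather <- fixture_weather()
  f1 <- ffm_run(site, weather, cfg)
  f2 <- ffm_run(site, weather, cfg)
  expect_identical(f1$trajectory, f2$trajectory)
  expect_identical(f1$max_flame_height, f2$max_flame_height)

  # re-derive the ledger from the recorded per-step counts
  burn <- do.call(rbind, f1$trajectory$leaves_burning)
  new <- do.call(rbind, f1$trajectory$newly_ignited)
  ext <- do.call(rbind, f1$trajectory$extinguished)
  prev <- rbind(0L, burn[-nrow(burn), , drop = FALSE])
  expect_true(all(burn == prev + new - ext))
  expect_true(all(burn >= 0))
  # overall height is the running max over strata and surface flames
  expect_equal(f1$max_flame_height, max(f1$trajectory$overall_flame_height))
})

test_that("a site with no strata reduces to the surface flame", {
  site <- ffm_site("bare", list(), 15)
  weather <- fixture_weather()
  fire <- ffm_run(site, weather, cfg)
  expect_equal(fire$max_flame_height, fire$surface$flame_height)
  expect_length(fire$strata_burnt, 0)
})

test_that("heat dissipation over a huge inter-strata gap prevents ignition", {
  site <- fixture_site()
  lofty <- site$strata$canopy
  shift <- 100 - lofty$crown_base_centre_height
  lofty$crown_base_centre_height <- 100
  lofty$crown_base_edge_height <- lofty$crown_base_edge_height + shift
  lofty$crown_height <- lofty$crown_height + shift
  lofty$crown_top_edge_height <- lofty$crown_top_edge_height + shift
  site$strata$canopy <- lofty
  fire <- ffm_run(site, fixture_weather(), cfg)
  expect_false("canopy" %in% fire$strata_burnt)
})

test_that("more surface fuel never reduces the maximum flame height", {
  weather <- fixture_weather()
  heights <- vapply(c(10, 14, 18, 22), function(load) {
    ffm_run(fixture_site(surface_fuel = load), weather, cfg)$max_flame_height
  }, numeric(1))
  expect_true(all(diff(heights) >= 0))
})

test_that("removing a stratum never adds burnt strata above it", {
  weather <- fixture_weather()
  full <- ffm_run(fixture_site(), weather, cfg)
  pruned_site <- fixture_site()
  pruned_site$strata$elevated <- NULL
  pruned <- ffm_run(pruned_site, weather, cfg)
  above <- c("midstorey", "canopy")
  expect_true(all(intersect(pruned$strata_burnt, above) %in%
                    intersect(full$strata_burnt, above)))
})

test_that("wider tree spacing reduces sheltering and tilts low flames more", {
  weather <- fixture_weather(wind = 20)
  tilt_at <- function(sep) {
    site <- fixture_site()
    site$strata$canopy$plant_separation <- sep
    strata <- ffmr:::site_strata(site)
    prof <- wind_profile(ffmr:::kmh_to_ms(weather$wind_velocity), strata,
                         config = cfg)
    surf <- surface_flame(site$surface_fuel_load, weather$dfmc,
                          prof$speed_at(1.5), weather$slope, cfg)
    pi / 2 - flame_angle(surf$flame_length, prof$speed_at(0.2),
                         weather$slope, cfg)
  }
  tilts <- vapply(c(4, 8, 16), tilt_at, numeric(1))
  expect_true(all(diff(tilts) >= 0))
})
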