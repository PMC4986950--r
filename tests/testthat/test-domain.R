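test_that("validators enforce the structural invariants", {
  expect_silent(validate_site(fixture_site()))

  expect_error(ffm_species("x", "elevated", "flat", -1e-4, 0.01, 0.05,
                           100, 0, 260, 60, 0.3, 0.2),
               "leaf_thickness")
  expect_error(ffm_species("x", "elevated", "flat", 3e-4, 1e-4, 0.05,
                           100, 0, 260, 60, 0.3, 0.2),
               "leaf_width >= leaf_thickness")
  expect_error(ffm_species("x", "elevated", "flat", 3e-4, 0.01, 0.05,
                           100, 1.5, 260, 60, 0.3, 0.2),
               "percent_dead")
  # ignition temperature must exceed the ambient range the model sees
  expect_error(ffm_species("x", "elevated", "flat", 3e-4, 0.01, 0.05,
                           100, 0, 35, 60, 0.3, 0.2),
               "ignition_temperature")

  # crown base above the crown top is rejected
  expect_error(fixture_stratum(base_c = 3, base_e = 3, top = 2),
               "crown_height")
  # vertical ordering of strata within a site
  tall_ns <- fixture_stratum("near_surface",
                             fixture_species("near_surface"),
                             top = 5, base_c = 0, base_e = 0, top_e = 4.5)
  expect_error(ffm_site("bad", list(tall_ns, fixture_stratum()), 10),
               "ordered")
  expect_error(ffm_weather(10, 10, 25, 50, -0.01), "dfmc")
  expect_error(ffm_weather(50, 10, 25, 50, 0.07), "slope")
  expect_error(ffm_observation("s", 1, 0.5, 2), "lower <= median")
})

test_that("default-trait rules fill missing values by functional group", {
  sp <- fixture_species()
  sp$live_moisture <- NA
  sp$ignition_temperature <- NA
  sp$percent_dead <- NA
  out <- apply_default_traits(sp)
  expect_equal(out$live_moisture, 100)     # standard woody value
  expect_equal(out$ignition_temperature, 260)  # non-aromatic default
  expect_equal(out$percent_dead, 0)

  # C4 grass: half the foliage is standing dead
  g <- fixture_species("near_surface", "c4grass", group = "monocotyledon")
  g$percent_dead <- NA
  g$c4_grass <- TRUE
  expect_equal(apply_default_traits(g)$percent_dead, 0.5)

  # moisture classes
  m <- fixture_species(); m$live_moisture <- NA; m$moisture_class <- "mesic_herb"
  expect_equal(apply_default_traits(m)$live_moisture, 150)
  m$moisture_class <- "very_green"
  expect_equal(apply_default_traits(m)$live_moisture, 200)

  # aromatic foliage ignites at the lower standard endotherm
  a <- fixture_species(); a$ignition_temperature <- NA; a$aromatic <- TRUE
  expect_equal(apply_default_traits(a)$ignition_temperature, 220)

  # measured silica-free ash overrides the aromaticity rule
  f <- fixture_species(); f$ignition_temperature <- NA
  f$silica_free_ash <- 10
  expect_equal(apply_default_traits(f)$ignition_temperature, 220 + 2 * 10)

  # complete records pass through unchanged
  expect_identical(apply_default_traits(fixture_species()),
                   fixture_species())

  # mandatory morphological fields cannot be defaulted
  bad <- fixture_species(); bad$leaf_width <- NA
  expect_error(apply_default_traits(bad), "leaf_width")
})

test_that("site tables round-trip through CSV byte-identically", {
  syn <- ffm_synthetic_sites(seed = 11, n_sites = 3, observations = FALSE)
  d1 <- file.path(tempdir(), "ffm_io_1")
  d2 <- file.path(tempdir(), "ffm_io_2")
  p1 <- write_site_tables(syn$sites, syn$weather, d1)
  back <- read_site_tables(p1["species"], p1["structure"], p1["weather"])
  p2 <- write_site_tables(back$sites, back$weather, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p2[[f]]), readLines(p1[[f]]))
  }
  # weather spanning the full signed wind range is accepted
  expect_silent(validate_weather(ffm_weather(0, -21, 25, 50, 0.07)))
  expect_silent(validate_weather(ffm_weather(0, 30, 25, 50, 0.07)))
})

test_that("malformed input files are rejected with located messages", {
  syn <- ffm_synthetic_sites(seed = 12, n_sites = 1, observations = FALSE)
  d <- file.path(tempdir(), "ffm_io_bad")
  p <- write_site_tables(syn$sites, syn$weather, d)

  st <- read.csv(p[["structure"]], stringsAsFactors = FALSE)
  st$crown_base_centre_height[1] <- st$crown_height[1] + 1
  bad_path <- file.path(d, "structure_bad.csv")
  write.csv(st, bad_path, row.names = FALSE, quote = FALSE)
  expect_error(read_site_tables(p["species"], bad_path, p["weather"]),
               "crown")

  we <- readLines(p[["weather"]])
  we[2] <- sub("^([^,]*),[^,]*", "\\1,steep", we[2])
  bad_w <- file.path(d, "weather_bad.csv")
  writeLines(we, bad_w)
  expect_error(read_site_tables(p["species"], p["structure"], bad_w),
               "non-numeric.*line 2")

  sp <- read.csv(p[["species"]], stringsAsFactors = FALSE)
  sp$leaf_form <- NULL
  bad_sp <- file.path(d, "species_bad.csv")
  write.csv(sp, bad_sp, row.names = FALSE, quote = FALSE)
  expect_error(read_site_tables(bad_sp, p["structure"], p["weather"]),
               "missing columns leaf_form")
})

test_that("JSON export writes a complete validated bundle", {
  syn <- ffm_synthetic_sites(seed = 13, n_sites = 2, observations = FALSE)
  path <- file.path(tempdir(), "bundle.json")
  ffm_export_json(syn, path)
  j <- jsonlite::read_json(path)
  expect_length(j$sites, 2)
  expect_equal(j$sites[[1]]$site_id, "site_001")
  expect_true(all(c("slope", "dfmc") %in% names(j$weather[[1]])))
})
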