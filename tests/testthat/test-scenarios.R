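test_that("solar-flux regime classification uses the strictly-positive rule", {
  expect_equal(classify_boundary_layer(c(0, 350, -0.001, 1e-9)),
               c("SBL", "CBL", "SBL", "CBL"))
  expect_error(classify_boundary_layer(NaN), "finite")
})

test_that("convective velocity scale matches the closed form and its cube-root scaling", {
  # frozen: (9.8 * 100 * 1000 / (1.293 * 1004 * 293.15))^(1/3)
  expect_equal(convective_velocity_scale(100, 1000, 293.15), 1.370675,
               tolerance = 1e-6)
  expect_equal(convective_velocity_scale(1e-12, 1000, 293.15), 0,
               tolerance = 1e-3)
  expect_equal(convective_velocity_scale(-50, 1000, 293.15), -9)
  expect_equal(convective_velocity_scale(0, 1000, 293.15), -9)
  # homogeneity: w*(8H) = 2 w*(H)
  h <- c(5, 80, 300)
  expect_equal(convective_velocity_scale(8 * h, 500, 280),
               2 * convective_velocity_scale(h, 500, 280))
  expect_error(convective_velocity_scale(Inf, 1000, 293.15), "finite")
})

test_that("Monin-Obukhov length matches the closed form, as printed without a leading minus", {
  # frozen: 1.293 * 1004 * 293.15 * 0.027 / (0.4 * 9.8 * 100)
  expect_equal(monin_obukhov_length(100, 0.3, 293.15), 26.21198,
               tolerance = 1e-6)
  expect_equal(monin_obukhov_length(50, 0, 293.15), 0)
  # sign(L) = sign(H): positive for daytime upward flux
  expect_gt(monin_obukhov_length(100, 0.3, 293.15), 0)
  expect_lt(monin_obukhov_length(-20, 0.3, 293.15), 0)
  # near-neutral sentinel
  expect_equal(monin_obukhov_length(1e-9, 0.3, 293.15), 8888)
  expect_error(monin_obukhov_length(100, -0.1, 293.15), "non-negative")
})

test_that("wind direction follows the meteorological from-direction convention", {
  expect_equal(wind_direction(0, 1), 180)   # southerly
  expect_equal(wind_direction(1, 0), 270)   # westerly
  expect_equal(wind_direction(1, 1), 225)
  expect_equal(wind_direction(0, -1), 0)    # northerly wraps to 0
  expect_message(calm <- wind_direction(0, 0), "calm")
  expect_equal(calm, 0)
  set.seed(1)
  wd <- wind_direction(rnorm(500), rnorm(500))
  expect_true(all(wd >= 0 & wd < 360))
})

test_that("albedo is 1 at night and the clamped reflected fraction in daytime", {
  expect_equal(albedo(500, 100, "SBL"), 1)
  expect_equal(albedo(500, 100, "CBL"), 0.8)
  expect_equal(albedo(100, 100, "CBL"), 0)
  expect_equal(albedo(100, 150, "CBL"), 0)    # noise: up > down
  expect_warning(r <- albedo(0, 0, "CBL"), "non-positive")
  expect_equal(r, 1)
  set.seed(2)
  r <- albedo(runif(200, 0, 900), runif(200, 0, 900),
              sample(c("CBL", "SBL"), 200, replace = TRUE))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("Bowen ratio is |H/latent| with the series-median fallback at zero latent flux", {
  expect_equal(bowen_ratio(50, 100, 0.7), 0.5)
  expect_equal(bowen_ratio(-50, 100, 0.7), 0.5)
  expect_equal(bowen_ratio(50, 0, 0.7), 0.7)
  expect_equal(bowen_median(c(10, 50, 30), c(20, 0, 10)), 1.75) # median(0.5, 3)
})

test_that("cloud cover deciles floor the percentage", {
  expect_identical(cloud_cover_decile(57), 5L)
  expect_identical(cloud_cover_decile(0), 0L)
  expect_identical(cloud_cover_decile(100), 10L)
  expect_identical(cloud_cover_decile(9.99), 0L)
  expect_warning(d <- cloud_cover_decile(105), "clamped")
  expect_identical(d, 10L)
})

test_that("energy-balance sensible heat is the net-radiation residual and linear", {
  expect_equal(sensible_heat_cbl(600, 120, 350, 400, 80, 150), 200)
  expect_equal(sensible_heat_cbl(0, 0, 0, 0, 0, 0), 0)
  expect_equal(sensible_heat_cbl(1200, 240, 700, 800, 160, 300),
               2 * sensible_heat_cbl(600, 120, 350, 400, 80, 150))
})

test_that("Scenario 1 populates every surface field per the derivation summary", {
  s <- make_hours(24)
  rec <- build_scenario1(s, tz_offset = 0L)
  expect_equal(nrow(rec), 24L)
  expect_equal(rec$temperature, rep(293.15, 24))       # 20 C -> K
  expect_equal(rec$station_pressure, rep(10132.5, 24)) # Pa / 10
  expect_equal(rec$wind_height, rep(10, 24))
  expect_equal(rec$temperature_height, rep(2, 24))
  expect_equal(rec$precip_code, rep(11L, 24))
  expect_equal(rec$vptg_500m, rep(-9, 24))
  expect_equal(rec$adj_flag, rep("NAD", 24))
  expect_equal(rec$sub_flag, rep("NoSubs", 24))
  expect_equal(rec$hour, 1:24)
  expect_equal(rec$julian_day, rep(152L, 24))          # 2019-06-01
  expect_equal(rec$year, rep(19L, 24))
  expect_equal(rec$z_ic, s$pbl_height)
  expect_equal(rec$z_im, s$equilibrium_geopotential_height)
  expect_equal(rec$cloud_cover, rep(5L, 24))
  # albedo 1 on every SBL hour
  expect_true(all(rec$albedo[rec$regime == "SBL"] == 1))
  # daytime stability quantities from the closed forms
  cbl <- rec$regime == "CBL"
  expect_equal(rec$w_star[cbl],
               convective_velocity_scale(s$sensible_heat[cbl],
                                         s$pbl_height[cbl], 293.15))
  expect_equal(rec$obukhov_length[cbl],
               monin_obukhov_length(s$sensible_heat[cbl], 0.3, 293.15))
})

test_that("local-standard-time hour labeling shifts by the UTC offset", {
  s <- make_hours(24)
  rec <- build_scenario1(s, tz_offset = -6L)
  # first UTC hour 00 -> local 18 previous day -> hour 19, julian 151
  expect_equal(rec$hour[1], 19L)
  expect_equal(rec$julian_day[1], 151L)
  expect_equal(rec$hour[7], 1L)
  expect_equal(rec$julian_day[7], 152L)
})

test_that("Scenario 2 clamps raw inputs, recomputes w*/L from clamped values, then clamps derived ones", {
  s <- make_hours(24,
                  sensible_heat = rep(1000, 24),
                  pbl_height = rep(5200, 24),
                  friction_velocity = rep(2.5, 24),
                  surface_roughness = rep(3, 24))
  rec <- build_scenario2(s)
  expect_equal(rec$sensible_heat, rep(800, 24))
  expect_equal(rec$z_ic, rep(4000, 24))
  expect_equal(rec$friction_velocity, rep(2, 24))
  expect_equal(rec$surface_roughness, rep(2, 24))
  # w* and L recomputed from the clamped H = 800, Z_ic = 4000, u* = 2
  expect_equal(rec$w_star,
               rep(min(convective_velocity_scale(800, 4000, 293.15), 2), 24))
  expect_equal(rec$obukhov_length,
               rep(min(monin_obukhov_length(800, 2, 293.15), 8888), 24))
})

test_that("Scenario 2 equals Scenario 1 when raw and derived values stay inside the bounds", {
  s <- make_inbounds_series(n_days = 5, seed = 11)
  expect_identical(build_scenario2(s), build_scenario1(s))
})

test_that("Scenario-2 clamping is idempotent on fuzzed inputs", {
  gen <- generate_hourly_series(synth_config(seed = 12, n_days = 20,
                                             oob_rate = 0.1))
  s <- gen$series[[1]]
  r1 <- build_scenario2(s)
  # re-clamping the already-bounded record fields is a no-op
  b <- scenario_bounds()
  r2 <- r1
  r2$sensible_heat <- pmin(pmax(r2$sensible_heat, -64), 800)
  r2$friction_velocity <- pmin(pmax(r2$friction_velocity, 0), 2)
  r2$w_star <- ifelse(r2$w_star == -9, -9, pmin(pmax(r2$w_star, 0), 2))
  r2$obukhov_length <- pmin(pmax(r2$obukhov_length, -8888), 8888)
  r2$bowen_ratio <- pmin(pmax(r2$bowen_ratio, -10), 10)
  expect_identical(r1, r2)
})

test_that("Scenario 3 retains Scenario-2 values on stable hours and recomputes H, w*, L on convective hours", {
  s <- make_hours(48)
  r2 <- build_scenario2(s)
  r3 <- build_scenario3(s)
  sbl <- r3$regime == "SBL"
  expect_identical(r3[sbl, ], r2[sbl, ])
  cbl <- !sbl
  # daytime H from the energy balance regardless of the raw field:
  # (500 + 330 - 100 - 360) - 40 - 120 = 210
  expect_equal(unique(r3$sensible_heat[cbl]), 210)
  expect_equal(r3$w_star[cbl],
               convective_velocity_scale(rep(210, sum(cbl)),
                                         s$pbl_height[cbl], 293.15))
  expect_equal(r3$obukhov_length[cbl],
               rep(monin_obukhov_length(210, 0.3, 293.15), sum(cbl)))
  # only H, w*, L may differ from Scenario 2 on convective hours
  same_cols <- setdiff(names(r3), c("sensible_heat", "w_star",
                                    "obukhov_length"))
  expect_identical(r3[cbl, same_cols], r2[cbl, same_cols])
})

test_that("Scenario 3 equals Scenario 2 on an all-night series and re-applies the bounds in daytime", {
  night <- make_hours(48, visible_beam_downward_flux = 0)
  expect_identical(build_scenario3(night), build_scenario2(night))

  # energy-balance H above the cap: (1500+330-100-360) - 40 - 120 = 1210
  hot <- make_hours(24, downward_shortwave = rep(1500, 24))
  r3 <- build_scenario3(hot)
  expect_equal(unique(r3$sensible_heat[r3$regime == "CBL"]), 800)
})

test_that("surface-record invariants hold on fuzzed synthetic input", {
  gen <- generate_hourly_series(synth_config(seed = 13, n_days = 30,
                                             oob_rate = 0.05))
  for (scn in 1:3) {
    rec <- build_surface_records(gen$series[[1]], scenario = scn)
    expect_true(all(rec$wind_direction >= 0 & rec$wind_direction < 360))
    expect_true(all(rec$cloud_cover %in% 0:10))
    expect_true(all(rec$hour %in% 1:24))
    expect_true(all(rec$albedo >= 0 & rec$albedo <= 1))
    expect_true(all(rec$albedo[rec$regime == "SBL"] == 1))
    expect_true(all(rec$precip_code == 11L))
    expect_true(all(rec$vptg_500m == -9))
  }
})

test_that("constants and bounds constructors validate their inputs", {
  expect_error(met_constants(g = -1), "positive")
  expect_error(scenario_bounds(bowen = c(5, 1)), "lower < upper")
  expect_silent(scenario_bounds(sensible_heat = c(-100, 900)))
})

test_that("a key/value config file overrides constants and bounds", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "g = 9.81", "sensible_heat = -50, 700",
               "tz_offset = -6"), f)
  cfg <- read_met_config(f)
  expect_equal(do.call(met_constants, cfg$constants)$g, 9.81)
  expect_equal(do.call(scenario_bounds, cfg$bounds)$sensible_heat,
               c(-50, 700))
  expect_equal(cfg$options$tz_offset, -6)
})
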