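test_that("sector summer/winter ratios follow their definition", {
  ex <- dplyr::bind_rows(
    one_sector_exposure(c(winter = 12, spring = 9, summer = 6, autumn = 9)),
    one_sector_exposure(c(winter = 10, spring = 10, summer = 10,
                          autumn = 10)) |>
      dplyr::mutate(sector_id = 2L))
  sr <- sector_ratio(ex)
  expect_equal(sr$ratio[sr$sector_id == 1], 0.5)
  expect_equal(sr$ratio[sr$sector_id == 2], 1.0)
  bad <- one_sector_exposure(c(winter = 0, spring = 1, summer = 1,
                               autumn = 1))
  expect_error(sector_ratio(bad), "winter")
})

test_that("noise-free road sectors recover the planted road ratio", {
  spec <- region_spec(grid_shape = c(12, 12), n_sectors = 4, noise_sd = 0,
                      road_cells = data.frame(row = 1:12, col = 1), seed = 2)
  reg <- simulate_region(spec)
  f <- reg$fields |> dplyr::filter(pollutant == "NO2")
  road_cells <- spec$road_cells |> dplyr::mutate(stratum = "road")
  rr <- stratified_ratio(f, road_cells, B = 0)
  expect_equal(rr$ratio, spec$planted_ratio_road[["NO2"]],
               tolerance = 1e-12)
})

test_that("stratified ratios recover planted strata and partition area", {
  spec <- farfield_spec()
  f <- generate_fields(spec) |> dplyr::filter(pollutant == "NO2")
  strata <- tidyr::expand_grid(row = 1:30, col = 1:120) |>
    dplyr::mutate(stratum = dplyr::case_when(
      col == 2 ~ "road",
      col >= 110 ~ "background",
      TRUE ~ "mixed"))
  rr <- stratified_ratio(f, strata, B = 0)
  expect_equal(rr$ratio[rr$stratum == "road"], 0.78, tolerance = 1e-9)
  expect_equal(rr$ratio[rr$stratum == "background"], 0.46,
               tolerance = 1e-9)
  expect_equal(sum(rr$area_share), 1, tolerance = 1e-12)
  expect_true(all(rr$winter_sd >= 0))
  # a single stratum covering everything equals the overall ratio
  all_one <- strata |> dplyr::mutate(stratum = "all")
  r1 <- stratified_ratio(f, all_one, kind = "overall", B = 0)
  wide <- tidyr::pivot_wider(f, names_from = season, values_from = conc)
  expect_equal(r1$ratio, mean(wide$summer) / mean(wide$winter),
               tolerance = 1e-12)
})

test_that("ratios are scale invariant and empty strata are dropped with a warning", {
  spec <- tiny_spec()
  f <- generate_fields(spec) |> dplyr::filter(pollutant == "PM25")
  strata <- tidyr::expand_grid(row = 1:20, col = 1:24) |>
    dplyr::mutate(stratum = ifelse(col <= 12, "west", "east"))
  r <- stratified_ratio(f, strata, B = 0)
  f2 <- f |> dplyr::mutate(conc = conc * 11.3)
  r2 <- stratified_ratio(f2, strata, B = 0)
  expect_equal(r$ratio, r2$ratio, tolerance = 1e-12)
  ghost <- dplyr::bind_rows(strata,
                            tibble::tibble(row = 999, col = 999,
                                           stratum = "nowhere"))
  expect_warning(stratified_ratio(f, ghost, B = 0), "nowhere")
})

test_that("bootstrap CIs bracket the stratum ratio and are seed-stable", {
  spec <- region_spec(grid_shape = c(15, 20), n_sectors = 4, noise_sd = 1,
                      seed = 6)
  f <- generate_fields(spec) |> dplyr::filter(pollutant == "NO2")
  strata <- tidyr::expand_grid(row = 1:15, col = 1:20) |>
    dplyr::mutate(stratum = "all")
  r <- stratified_ratio(f, strata, B = 400, seed = 1)
  expect_true(r$ci_low <= r$ratio && r$ratio <= r$ci_high)
  expect_identical(r, stratified_ratio(f, strata, B = 400, seed = 1))
})

test_that("the distance transform matches brute-force nearest-road search", {
  withr::with_seed(12, {
    for (rep in 1:3) {
      rows <- sample(8:20, 1); cols <- sample(8:20, 1)
      road <- tibble::tibble(
        row = sample(rows, 4, replace = TRUE),
        col = sample(cols, 4, replace = TRUE))
      meta <- grid_meta(rows, cols, cell_size = 10)
      d <- distance_transform(road, meta)
      oracle <- brute_force_distance(rows, cols, road)
      expect_equal(d$dist_cells,
                   oracle[cbind(d$row, d$col)], tolerance = 1e-12)
      expect_equal(max(d$dist), 1)
      expect_equal(min(d$dist), 0)
    }
  })
})

test_that("a single road column yields distances proportional to offset", {
  meta <- grid_meta(1, 11, cell_size = 10)
  d <- distance_transform(tibble::tibble(row = 1, col = 1), meta)
  expect_equal(d$dist[order(d$col)], (0:10) / 10)
  expect_error(distance_transform(tibble::tibble(row = integer(0),
                                                 col = integer(0)), meta),
               "empty")
})

test_that("distance profiles recover linear and exponential structure", {
  meta <- grid_meta(10, 30, cell_size = 10)
  road <- tibble::tibble(row = 1:10, col = 1)
  d <- distance_transform(road, meta)
  # exactly linear concentration in distance -> LOESS equals the line
  lin_field <- d |>
    dplyr::mutate(pollutant = "NO2", season = "winter",
                  conc = 30 - 12 * dist)
  pr <- distance_profile(lin_field, d, span = 0.4)
  expect_equal(pr$fit, 30 - 12 * pr$distance, tolerance = 1e-9)
  expect_lt(coef(attr(pr, "linear"))[2], 0)
  # noise-free exponential decay: fitted origin within 2% of bg + increment
  spec <- region_spec(grid_shape = c(10, 30), n_sectors = 4, noise_sd = 0,
                      road_cells = road, seed = 3)
  f <- generate_fields(spec) |>
    dplyr::filter(pollutant == "NO2", season == "winter")
  pr2 <- distance_profile(f, d, span = 0.15)
  origin <- spec$background_winter[["NO2"]] +
    spec$road_increment_winter[["NO2"]]
  expect_lt(abs(pr2$fit[1] - origin) / origin, 0.02)
  expect_error(distance_profile(f, d |> dplyr::mutate(dist = 0.5)),
               "constant")
})

test_that("percent decline matches direct arithmetic", {
  expect_equal(percent_decline(12, 6), 50)
  expect_equal(percent_decline(12, 9.9), 17.5)
  expect_equal(percent_decline(7, 7), 0)
  expect_equal(percent_decline(7.5, 5.5, digits = 0), 27)
  expect_error(percent_decline(0, 1), "positive")
})
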