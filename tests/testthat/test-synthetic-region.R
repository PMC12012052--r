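test_that("noise-free fields carry the planted summer/winter ratios", {
  spec <- farfield_spec()
  fields <- generate_fields(spec)
  wide <- tidyr::pivot_wider(fields, names_from = season,
                             values_from = conc)
  for (p in spec$pollutants) {
    w <- wide[wide$pollutant == p, ]
    on_road <- w$col == 2
    expect_equal(w$summer[on_road] / w$winter[on_road],
                 rep(spec$planted_ratio_road[[p]], sum(on_road)),
                 tolerance = 1e-12)
    far <- w$col >= 110 # > 50 decay lengths from the road
    r_far <- w$summer[far] / w$winter[far]
    expect_true(all(abs(r_far - spec$planted_ratio_background[[p]]) <
                      0.01 * spec$planted_ratio_background[[p]]))
  }
})

test_that("field generation is deterministic under the master seed", {
  spec <- region_spec(grid_shape = c(12, 15), n_sectors = 6, noise_sd = 0.8,
                      seed = 42)
  expect_identical(generate_fields(spec), generate_fields(spec))
  expect_identical(simulate_region(spec)$sectors,
                   simulate_region(spec)$sectors)
  spec2 <- region_spec(grid_shape = c(12, 15), n_sectors = 6, noise_sd = 0.8,
                       seed = 43)
  expect_false(identical(generate_fields(spec), generate_fields(spec2)))
})

test_that("sectors partition the grid and attributes respect their contracts", {
  spec <- region_spec(grid_shape = c(25, 30), n_sectors = 40, seed = 9)
  sg <- generate_sectors(spec)
  # every cell in exactly one sector
  expect_equal(nrow(sg$cells), 25 * 30)
  expect_equal(nrow(dplyr::distinct(sg$cells, row, col)), 25 * 30)
  expect_setequal(unique(sg$cells$sector_id), sg$sectors$sector_id)
  expect_equal(nrow(sg$sectors), 40)
  # contiguity: each sector's cells form one rook-connected component
  for (sid in sg$sectors$sector_id) {
    m <- sg$cells[sg$cells$sector_id == sid, c("row", "col")]
    seen <- 1L
    frontier <- 1L
    repeat {
      nb <- integer(0)
      for (i in frontier) {
        adj <- which(abs(m$row - m$row[i]) + abs(m$col - m$col[i]) == 1)
        nb <- union(nb, setdiff(adj, seen))
      }
      if (length(nb) == 0) break
      seen <- union(seen, nb)
      frontier <- nb
    }
    expect_equal(length(seen), nrow(m))
  }
  expect_true(all(sg$sectors$population > 0))
  expect_true(all(sg$sectors$degurba %in% 1:3))
  expect_setequal(sort(unique(sg$sectors$bimd_decile)), 1:10)
  expect_true(all(sg$sectors$mobiscore >= 0 & sg$sectors$mobiscore <= 10))
})

test_that("car ownership follows the piecewise-linear accessibility rule exactly", {
  spec <- tiny_spec()
  s <- generate_sectors(spec)$sectors
  expected <- spec$cars_plateau +
    spec$cars_post_slope * pmax(s$mobiscore - spec$mobiscore_changepoint, 0)
  expect_equal(s$cars_per_household, expected, tolerance = 1e-12)
  # direct evaluation: score 8.5 with changepoint 8, plateau 1.1, slope -0.4
  expect_equal(1.1 - 0.4 * (8.5 - 8.0), 0.9, tolerance = 1e-12)
})

test_that("urban deprivation deciles track winter NO2", {
  spec <- region_spec(grid_shape = c(40, 50), n_sectors = 150, seed = 21,
                      noise_sd = 0)
  reg <- simulate_region(spec)
  urb <- dplyr::inner_join(
    reg$sectors[reg$sectors$degurba == 1, c("sector_id", "bimd_decile")],
    dplyr::filter(reg$truth$true_sector_means,
                  pollutant == "NO2", season == "winter"),
    by = "sector_id")
  # decile 1 = most deprived = highest NO2: negative rank correlation
  expect_lt(cor(urb$bimd_decile, urb$true_mean, method = "spearman"), -0.5)
})

test_that("generator rejects invalid region parameters", {
  expect_error(region_spec(decay_scale = 0), "decay_scale")
  expect_error(region_spec(road_cells = data.frame(row = 99, col = 1),
                           grid_shape = c(10, 10)), "outside")
  expect_error(region_spec(road_cells = data.frame(row = integer(0),
                                                   col = integer(0))),
               "at least one")
  expect_error(region_spec(grid_shape = c(3, 3), n_sectors = 10), "exceeds")
  expect_error(region_spec(planted_ratio_road = c(NO2 = 0.4, PM25 = 0.4)),
               "must exceed")
})

test_that("noise-free sector means match the recorded truth exactly", {
  reg <- simulate_region(tiny_spec())
  ex <- zonal_mean(reg$fields, reg$cells)
  cmp <- dplyr::inner_join(ex, reg$truth$true_sector_means,
                           by = c("sector_id", "pollutant", "season"))
  expect_equal(cmp$mean_conc, cmp$true_mean, tolerance = 1e-12)
})

test_that("with noise, recovered stratum ratios stay within 3 SE of planted over seeds", {
  ratios <- vapply(1:20, function(s) {
    spec <- region_spec(grid_shape = c(20, 30), n_sectors = 8,
                        noise_sd = 0.5, seed = s)
    f <- generate_fields(spec)
    road <- spec$road_cells |> dplyr::mutate(stratum = "road")
    rr <- stratified_ratio(f |> dplyr::filter(pollutant == "NO2"), road,
                           kind = "landcover", B = 0)
    rr$ratio
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.78), 3 * se)
})
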