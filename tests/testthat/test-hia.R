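test_that("excess concentration clips at the guideline", {
  expect_equal(excess_concentration(12, 10), 2)
  expect_equal(excess_concentration(8, 10), 0)
  expect_equal(excess_concentration(5, 5), 0)
  expect_error(excess_concentration(-1, 10), ">= 0")
})

test_that("relative-risk rescaling honours its fixed points", {
  expect_equal(rescale_rr(1.045, 10), 1.045, tolerance = 1e-15)
  expect_equal(rescale_rr(1.7, 0), 1, tolerance = 1e-15)
  expect_equal(rescale_rr(1.118, 20), 1.118^2, tolerance = 1e-12)
  expect_equal(rescale_rr(1.118, 20), 1.249924, tolerance = 1e-6)
  expect_error(rescale_rr(1.05, -3), ">= 0")
  expect_error(rescale_rr(0, 5), "positive")
})

test_that("preventable fraction follows 1 - 1/RR and clips protective RRs", {
  expect_equal(preventable_fraction(1), 0)
  expect_equal(preventable_fraction(2), 0.5)
  expect_equal(preventable_fraction(1.045), 1 - 1 / 1.045,
               tolerance = 1e-15)
  expect_equal(preventable_fraction(1.045), 0.0430622009569378,
               tolerance = 1e-13)
  expect_warning(pf <- preventable_fraction(0.9), "clipped")
  expect_equal(pf, 0)
})

test_that("triangular draws respect support, mean and CDF at the mode", {
  er <- default_erf()$NO2
  draws <- sample_rr_triangular(er, 1e5, seed = 31)
  a <- 1.026; b <- 1.065; c0 <- 1.045
  expect_true(all(draws >= a & draws <= b))
  tri_mean <- (a + b + c0) / 3
  tri_var <- (a^2 + b^2 + c0^2 - a * b - a * c0 - b * c0) / 18
  se <- sqrt(tri_var / 1e5)
  expect_lt(abs(mean(draws) - tri_mean), 3 * se)
  # empirical CDF at the mode vs closed form (c-a)/(b-a)
  p_mode <- (c0 - a) / (b - a)
  se_p <- sqrt(p_mode * (1 - p_mode) / 1e5)
  expect_lt(abs(mean(draws <= c0) - p_mode), 4 * se_p)
  # degenerate support collapses to the constant
  degen <- exposure_response("NO2", 1.05, 1.05, 1.05, 10)
  expect_equal(sample_rr_triangular(degen, 10, seed = 1), rep(1.05, 10))
})

test_that("sectors at the guideline have zero preventable fraction", {
  ex <- one_sector_exposure(c(winter = 10, spring = 10, summer = 10,
                              autumn = 10))
  sec <- tibble::tibble(sector_id = 1L, population = 500)
  pf <- pf_with_uncertainty(ex, sec, default_erf()$NO2, n_iter = 500,
                            seed = 1)
  nat <- pf[pf$level == "national", ]
  expect_equal(nat$pf, 0)
  expect_equal(nat$pf_low, 0)
  expect_equal(nat$pf_high, 0)
})

test_that("a degenerate triangular reproduces the deterministic PF", {
  # single sector with CON = 10: PF = 1 - 1/1.045 exactly
  ex <- one_sector_exposure(c(winter = 20, spring = 20, summer = 20,
                              autumn = 20))
  sec <- tibble::tibble(sector_id = 1L, population = 500)
  er <- exposure_response("NO2", 1.045, 1.045, 1.045, guideline = 10)
  pf <- pf_with_uncertainty(ex, sec, er, n_iter = 200, seed = 1)
  nat <- pf[pf$level == "national", ]
  expect_equal(nat$pf, 1 - 1 / 1.045, tolerance = 1e-12)
  expect_equal(nat$pf_low, nat$pf, tolerance = 1e-12)
  expect_equal(nat$pf_high, nat$pf, tolerance = 1e-12)
})

test_that("counterfactual modes differ exactly by the guideline excess", {
  ex <- one_sector_exposure(c(winter = 22, spring = 18, summer = 12,
                              autumn = 16)) # annual mean 17
  sec <- tibble::tibble(sector_id = 1L, population = 500)
  er <- default_erf()$NO2
  pf_g <- pf_with_uncertainty(ex, sec, er, n_iter = 100, seed = 1,
                              counterfactual = "guideline")
  pf_z <- pf_with_uncertainty(ex, sec, er, n_iter = 100, seed = 1,
                              counterfactual = "zero")
  s_g <- pf_g[pf_g$level == "sector", ]
  s_z <- pf_z[pf_z$level == "sector", ]
  expect_equal(s_g$con, 7)
  expect_equal(s_z$con, 17)
  expect_equal(s_g$pf, 1 - 1 / rescale_rr(1.045, 7), tolerance = 1e-12)
  expect_equal(s_z$pf, 1 - 1 / rescale_rr(1.045, 17), tolerance = 1e-12)
})

test_that("national PF is a population-weighted mean bracketed by sector PFs", {
  reg <- simulate_region(region_spec(grid_shape = c(20, 25), n_sectors = 30,
                                     seed = 14))
  ex <- zonal_mean(reg$fields, reg$cells)
  pf <- pf_with_uncertainty(ex, reg$sectors, default_erf()$NO2,
                            n_iter = 1000, seed = 2)
  sec <- pf[pf$level == "sector", ]
  nat <- pf[pf$level == "national", ]
  expect_gte(nat$pf, min(sec$pf))
  expect_lte(nat$pf, max(sec$pf))
  w <- reg$sectors$population[match(sec$sector_id, reg$sectors$sector_id)]
  expect_equal(nat$pf, sum(sec$pf * w) / sum(w), tolerance = 1e-12)
  # CI brackets the point estimate; PF at the CI bounds of RR10 brackets
  # the Monte Carlo interval outward (monotone transform)
  expect_true(nat$pf_low <= nat$pf & nat$pf <= nat$pf_high)
  er <- default_erf()$NO2
  ann <- annual_means(ex |> dplyr::filter(pollutant == "NO2"))
  con <- excess_concentration(ann$annual_mean, er$guideline)
  pf_at <- function(rr10) {
    v <- 1 - 1 / rescale_rr(rr10, con)
    sum(v * w) / sum(w)
  }
  expect_lte(pf_at(er$rr10_low), nat$pf_low + 1e-12)
  expect_gte(pf_at(er$rr10_high), nat$pf_high - 1e-12)
})

test_that("PF is monotone in concentration and in RR10", {
  cons <- c(0, 2, 5, 10, 20, 40)
  pfs <- 1 - 1 / rescale_rr(1.045, cons)
  expect_true(all(diff(pfs) > 0))
  rrs <- c(1.01, 1.05, 1.1, 1.2)
  pfs2 <- vapply(rrs, function(r) 1 - 1 / rescale_rr(r, 15), numeric(1))
  expect_true(all(diff(pfs2) > 0))
})

test_that("the PF point estimate is seed-free and its CI is seed-stable", {
  reg <- simulate_region(region_spec(grid_shape = c(15, 20), n_sectors = 20,
                                     seed = 5))
  ex <- zonal_mean(reg$fields, reg$cells)
  runs <- lapply(c(1, 99, 1234), function(s) {
    g <- glance(pf_with_uncertainty(ex, reg$sectors, default_erf()$PM25,
                                    n_iter = 10000, seed = s))
  })
  pts <- vapply(runs, function(g) g$pf, numeric(1))
  expect_equal(pts, rep(pts[1], 3), tolerance = 1e-15)
  los <- vapply(runs, function(g) g$pf_low, numeric(1))
  his <- vapply(runs, function(g) g$pf_high, numeric(1))
  expect_lt(diff(range(los)) / mean(los), 0.05)
  expect_lt(diff(range(his)) / mean(his), 0.05)
})

test_that("exposure-response configuration is validated", {
  expect_error(exposure_response("NO2", 1.0, 1.1, 1.2, 10), "rr10_low")
  expect_error(exposure_response("NO2", 1.05, 1.0, 1.1, -2), "guideline")
  er <- default_erf()
  expect_equal(er$NO2$rr10, 1.045)
  expect_equal(er$NO2$guideline, 10)
  expect_equal(er$PM25$rr10, 1.118)
  expect_equal(er$PM25$guideline, 5)
})
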