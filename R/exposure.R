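#' Zonal mean: aggregate a gridded field to sector exposures
#'
#' Arithmetic mean of the member-cell concentrations of every sector, the
#' raster-to-sector aggregation step ("zonal statistics"). NODATA cells
#' (`NA` concentrations) are excluded; a sector whose cells are all
#' NODATA is an error.
#'
#' @param fields long field tibble (`pollutant`, `season`, `row`, `col`,
#'   `conc`); may hold several pollutant/season layers at once.
#' @param cells membership tibble (`sector_id`, `row`, `col`).
#' @return An exposure tibble: `sector_id`, `pollutant`, `season`,
#'   `mean_conc` (ug/m3), `n_cells`.
#' @examples
#' reg <- simulate_region(region_spec(grid_shape = c(10, 10), n_sectors = 4))
#' zonal_mean(reg$fields, reg$cells)
#' @export
zonal_mean <- function(fields, cells) {
  joined <- fields |>
    inner_join(cells |> select("sector_id", "row", "col"),
               by = c("row", "col"))
  out <- joined |>
    group_by(.data$sector_id, .data$pollutant, .data$season) |>
    summarise(mean_conc = mean(.data$conc, na.rm = TRUE),
              n_cells = sum(!is.na(.data$conc)), .groups = "drop")
  empty <- out |> filter(.data$n_cells == 0)
  if (nrow(empty) > 0) {
    abort(sprintf("sectors with only NODATA cells: %s.",
                  paste(unique(empty$sector_id), collapse = ", ")))
  }
  out
}

#' Annual sector means from seasonal exposures
#'
#' The annual mean is the unweighted mean of the four seasonal sector
#' means (seasons carry equal weight in the annual aggregate).
#'
#' @param exposure exposure tibble from [zonal_mean()].
#' @return Tibble `sector_id`, `pollutant`, `annual_mean`.
#' @export
annual_means <- function(exposure) {
  chk <- exposure |>
    distinct(.data$pollutant, .data$season) |>
    count(.data$pollutant)
  if (any(chk$n != length(SEASONS))) {
    bad <- chk$pollutant[chk$n != length(SEASONS)]
    abort(sprintf("pollutant %s does not have all four seasons.",
                  paste(bad, collapse = ", ")))
  }
  exposure |>
    group_by(.data$sector_id, .data$pollutant) |>
    summarise(annual_mean = mean(.data$mean_conc), .groups = "drop")
}

#' Population-weighted mean of a per-sector quantity
#'
#' Computes `sum(pop * value) / sum(pop)`. Zero-population sectors drop
#' out through their zero weight; negative or all-zero populations are
#' errors.
#'
#' @param data data frame holding the value and weight columns.
#' @param value,weight unquoted column names.
#' @return A single number.
#' @examples
#' population_weighted_mean(data.frame(v = c(2, 4), p = c(1, 3)), v, p)
#' @export
population_weighted_mean <- function(data, value, weight) {
  v <- eval_tidy(enquo(value), data)
  w <- eval_tidy(enquo(weight), data)
  if (any(w < 0, na.rm = TRUE)) abort("negative population weights.")
  if (!any(w > 0, na.rm = TRUE)) abort("all population weights are zero.")
  keep <- !is.na(v) & !is.na(w)
  sum(v[keep] * w[keep]) / sum(w[keep])
}

#' Seasonal contributions to annual residential exposure
#'
#' Share of each season in the annual exposure of one pollutant:
#' `share(s) = M(s) / sum over seasons of M(s')`, where `M(s)` is by
#' default the population-weighted mean over sectors of the sector
#' seasonal means ("residential" exposure), or the unweighted sector mean
#' when `weighted = FALSE`.
#'
#' @param exposure exposure tibble from [zonal_mean()].
#' @param sectors sector attribute tibble with `population`.
#' @param pollutant pollutant label to summarise.
#' @param weighted population-weight the sector means (default) or not.
#' @return Tibble `pollutant`, `season`, `share` (four rows summing to 1).
#' @export
seasonal_shares <- function(exposure, sectors, pollutant, weighted = TRUE) {
  ex <- exposure |> filter(.data$pollutant == !!pollutant)
  have <- unique(ex$season)
  miss <- setdiff(SEASONS, have)
  if (length(miss) > 0) {
    abort(sprintf("missing season(s) for %s: %s.", pollutant,
                  paste(miss, collapse = ", ")))
  }
  seasonal <- purrr::map_dbl(SEASONS, function(s) {
    d <- ex |> filter(.data$season == s) |>
      inner_join(sectors |> select("sector_id", "population"),
                 by = "sector_id")
    if (weighted) {
      population_weighted_mean(d, .data$mean_conc, .data$population)
    } else {
      mean(d$mean_conc)
    }
  })
  tibble(pollutant = pollutant,
         season = factor(SEASONS, levels = SEASONS),
         share = seasonal / sum(seasonal))
}
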