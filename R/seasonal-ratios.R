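#' Summer/winter concentration ratio per sector
#'
#' Divides each sector's mean summer concentration by its mean winter
#' concentration. Values near 1 indicate weak seasonal dilution (traffic
#' hotspots); low values indicate a strong winter excess.
#'
#' @param exposure exposure tibble from [zonal_mean()] holding at least
#'   the summer and winter rows.
#' @return Tibble `sector_id`, `pollutant`, `summer_mean`, `winter_mean`,
#'   `ratio`.
#' @export
sector_ratio <- function(exposure) {
  wide <- exposure |>
    filter(.data$season %in% c("summer", "winter")) |>
    select("sector_id", "pollutant", "season", "mean_conc") |>
    tidyr::pivot_wider(names_from = "season", values_from = "mean_conc")
  if (!all(c("summer", "winter") %in% names(wide)) ||
      anyNA(wide$summer) || anyNA(wide$winter)) {
    abort("summer and winter means must be present for every sector.")
  }
  if (any(wide$winter <= 0)) {
    abort(sprintf("non-positive winter mean in sector(s): %s.",
                  paste(wide$sector_id[wide$winter <= 0], collapse = ", ")))
  }
  wide |>
    mutate(ratio = .data$summer / .data$winter) |>
    rename(summer_mean = "summer", winter_mean = "winter")
}

#' Summer/winter ratio stratified by a cell classification
#'
#' For each stratum k (land-cover class, degree of urbanisation, or any
#' cell partition), the ratio of the mean summer concentration over the
#' stratum's cells to the mean winter concentration over the same cells
#' — a single fraction of aggregate concentrations, not a mean of
#' cellwise ratios (the cellwise-mean alternative is available via
#' `cellwise = TRUE`). Also reports the stratum winter mean and standard
#' deviation across cells, the stratum's area share, and a nonparametric
#' bootstrap percentile confidence interval over cells.
#'
#' @param fields long field tibble with summer and winter layers of one
#'   pollutant.
#' @param strata tibble mapping cells to strata: `row`, `col`, `stratum`.
#' @param kind label for the stratification (`"landcover"`, `"degurba"`,
#'   `"overall"`, ...).
#' @param cellwise if `TRUE`, use the mean of cellwise ratios instead of
#'   the ratio of means.
#' @param B bootstrap replicates for the CI (0 disables the CI).
#' @param conf_level CI level.
#' @param seed seed for the bootstrap resampling.
#' @return A ratio tibble: `stratum_kind`, `stratum`, `winter_mean`,
#'   `winter_sd`, `ratio`, `ci_low`, `ci_high`, `area_share`, `n_cells`.
#' @export
stratified_ratio <- function(fields, strata, kind = "landcover",
                             cellwise = FALSE, B = 1000,
                             conf_level = 0.95, seed = 1L) {
  pols <- unique(fields$pollutant)
  if (length(pols) > 1) {
    return(purrr::map_dfr(pols, function(p) {
      stratified_ratio(fields |> filter(.data$pollutant == p), strata,
                       kind = kind, cellwise = cellwise, B = B,
                       conf_level = conf_level, seed = seed) |>
        mutate(pollutant = p, .before = 1)
    }))
  }
  wide <- fields |>
    filter(.data$season %in% c("summer", "winter")) |>
    select("season", "row", "col", "conc") |>
    tidyr::pivot_wider(names_from = "season", values_from = "conc") |>
    inner_join(strata |> select("row", "col", "stratum"),
               by = c("row", "col")) |>
    filter(!is.na(.data$summer) & !is.na(.data$winter))
  total_cells <- nrow(wide)
  declared <- unique(strata$stratum)
  present <- unique(wide$stratum)
  missing_strata <- setdiff(declared, present)
  if (length(missing_strata) > 0) {
    warn(sprintf("empty stratum(s) omitted: %s.",
                 paste(missing_strata, collapse = ", ")))
  }
  alpha <- (1 - conf_level) / 2
  ratio_of <- function(s, w) {
    if (cellwise) mean(s / w) else mean(s) / mean(w)
  }
  out <- purrr::map_dfr(split(wide, wide$stratum), function(d) {
    r <- ratio_of(d$summer, d$winter)
    ci <- c(NA_real_, NA_real_)
    if (B > 0 && nrow(d) > 1) {
      boot <- withr::with_seed(seed, {
        vapply(seq_len(B), function(b) {
          i <- sample.int(nrow(d), replace = TRUE)
          ratio_of(d$summer[i], d$winter[i])
        }, numeric(1))
      })
      ci <- unname(quantile(boot, c(alpha, 1 - alpha)))
    }
    tibble(stratum = d$stratum[1],
           winter_mean = mean(d$winter),
           winter_sd = sd(d$winter),
           ratio = r, ci_low = ci[1], ci_high = ci[2],
           area_share = nrow(d) / total_cells, n_cells = nrow(d))
  })
  out |> mutate(stratum_kind = kind, .before = 1) |> arrange(.data$stratum)
}

#' Normalised Euclidean distance to the nearest road cell
#'
#' Distance from each cell center to the nearest road cell center,
#' divided by the maximum such distance on the grid, so values live in
#' [0, 1] with 0 on road cells. A uniform cost surface is assumed.
#'
#' @param road_cells tibble of road cell positions (`row`, `col`).
#' @param meta a [grid_meta()] (or anything with `rows`/`cols`).
#' @return Tibble `row`, `col`, `dist` (normalised), `dist_cells`
#'   (distance in cell units).
#' @export
distance_transform <- function(road_cells, meta) {
  road_cells <- as_tibble(as.data.frame(road_cells))
  if (nrow(road_cells) == 0) abort("road mask is empty.")
  d <- min_road_distance(meta$rows, meta$cols, road_cells)
  dmax <- max(d)
  grid_cells_tbl(meta$rows, meta$cols) |>
    mutate(dist_cells = d[cbind(.data$row, .data$col)],
           dist = if (dmax > 0) .data$dist_cells / dmax else .data$dist_cells)
}

#' Concentration profile against distance to roads
#'
#' LOESS fit of cell concentrations against normalised road distance,
#' evaluated on a uniform distance grid with a pointwise confidence
#' band, together with an ordinary linear fit of the same relation.
#'
#' @param field field tibble holding one pollutant/season layer (or pass
#'   `pollutant`/`season` to select one).
#' @param dist distance tibble from [distance_transform()].
#' @param pollutant,season optional layer selectors.
#' @param span,degree LOESS settings.
#' @param n_eval evaluation grid size.
#' @param conf_level confidence level of the band.
#' @return A tibble of class `distance_profile` (`distance`, `fit`, `se`,
#'   `ci_low`, `ci_high`) with attributes `linear` (the `lm` fit) and
#'   `loess` (the [loess_fit()] object).
#' @export
distance_profile <- function(field, dist, pollutant = NULL, season = NULL,
                             span = 0.75, degree = 1, n_eval = 50,
                             conf_level = 0.95) {
  f <- field
  if (!is.null(pollutant)) f <- f |> filter(.data$pollutant == !!pollutant)
  if (!is.null(season)) f <- f |> filter(.data$season == !!season)
  d <- f |> select(dplyr::any_of(c("row", "col", "conc"))) |>
    inner_join(dist |> select("row", "col", "dist"),
               by = c("row", "col")) |>
    filter(!is.na(.data$conc))
  if (nrow(d) < 20) abort("need at least 20 cells for a distance profile.")
  if (length(unique(d$dist)) < 2) abort("distance values are constant.")
  lf <- loess_fit(d, .data$dist, .data$conc, span = span, degree = degree,
                  n_eval = n_eval)
  lin <- lm(conc ~ dist, data = d)
  td <- tidy(lf, conf_level = conf_level)
  out <- tibble(distance = td$x, fit = td$.fitted, se = td$.se,
                ci_low = td$.lower, ci_high = td$.upper)
  class(out) <- c("distance_profile", class(out))
  attr(out, "linear") <- lin
  attr(out, "loess") <- lf
  out
}

#' @export
autoplot.distance_profile <- function(object, ...) {
  lin <- attr(object, "linear")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(intercept = coef(lin)[1], slope = coef(lin)[2],
                         linetype = "dashed") +
    ggplot2::labs(x = "normalised distance to road",
                  y = expression(concentration ~ (mu * g / m^3)))
}

#' Percent decline of a concentration between two points
#'
#' `100 * (c_origin - c_at_d) / c_origin`: the percentage by which a
#' concentration has declined from its value at the origin (e.g. at a
#' road) to its value at some distance.
#'
#' @param c_origin concentration at the origin (ug/m3, > 0).
#' @param c_at_d concentration at the comparison point (ug/m3).
#' @param digits optional rounding of the reported percentage.
#' @return Percent decline (positive = decrease). Vectorised.
#' @examples
#' percent_decline(12, 6) # 50
#' @export
percent_decline <- function(c_origin, c_at_d, digits = NULL) {
  if (any(c_origin <= 0)) abort("`c_origin` must be positive.")
  p <- 100 * (c_origin - c_at_d) / c_origin
  if (!is.null(digits)) p <- round(p, digits)
  p
}
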