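#' Exposure and seasonal-ratio curves across deprivation deciles
#'
#' For each pollutant metric (annual mean concentration and summer/winter
#' ratio) and each degree-of-urbanisation class, a LOESS curve of the
#' sector metric against the deprivation decile (treated as numeric
#' 1..10, decile 1 = most deprived), evaluated on the deciles present in
#' that class. Classes with fewer than `min_sectors` sectors are skipped
#' with a warning.
#'
#' @param exposure exposure tibble from [zonal_mean()] (all seasons).
#' @param sectors sector attribute tibble with `bimd_decile`, `degurba`.
#' @param span,degree LOESS settings.
#' @param min_sectors minimum sectors per stratum.
#' @param conf_level confidence level of the pointwise band.
#' @return A tibble of class `disparity_curves`: `metric`, `pollutant`,
#'   `degurba`, `decile`, `fit`, `se`, `ci_low`, `ci_high`.
#' @export
deprivation_curves <- function(exposure, sectors, span = 0.75, degree = 1,
                               min_sectors = 5, conf_level = 0.95) {
  if (!all(c("bimd_decile", "degurba") %in% names(sectors))) {
    abort("sectors must carry `bimd_decile` and `degurba`.")
  }
  ann <- annual_means(exposure) |>
    mutate(metric = "annual", value = .data$annual_mean) |>
    select("sector_id", "pollutant", "metric", "value")
  rat <- sector_ratio(exposure) |>
    mutate(metric = "summer_winter_ratio", value = .data$ratio) |>
    select("sector_id", "pollutant", "metric", "value")
  metrics <- bind_rows(ann, rat) |>
    inner_join(sectors |> select("sector_id", "bimd_decile", "degurba"),
               by = "sector_id") |>
    filter(!is.na(.data$bimd_decile) & !is.na(.data$value))
  groups <- metrics |> distinct(.data$metric, .data$pollutant, .data$degurba)
  out <- purrr::pmap_dfr(groups, function(metric, pollutant, degurba) {
    d <- metrics |>
      filter(.data$metric == !!metric, .data$pollutant == !!pollutant,
             .data$degurba == !!degurba)
    if (nrow(d) < min_sectors || length(unique(d$bimd_decile)) < 3) {
      warn(sprintf("stratum skipped (too small): %s %s DEGURBA %s.",
                   pollutant, metric, degurba))
      return(NULL)
    }
    deciles <- sort(unique(d$bimd_decile))
    lf <- loess_fit(d, .data$bimd_decile, .data$value, span = span,
                    degree = degree, eval_x = deciles)
    td <- tidy(lf, conf_level = conf_level)
    tibble(metric = metric, pollutant = pollutant, degurba = degurba,
           decile = td$x, fit = td$.fitted, se = td$.se,
           ci_low = td$.lower, ci_high = td$.upper)
  })
  class(out) <- c("disparity_curves", class(out))
  out
}

#' @export
autoplot.disparity_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$decile, y = .data$fit,
                               colour = factor(.data$degurba),
                               fill = factor(.data$degurba))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$pollutant + .data$metric, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "deprivation decile (1 = most deprived)",
                  colour = "DEGURBA", fill = "DEGURBA")
}

#' Detect the accessibility turning point of car ownership
#'
#' Operationalises the "turning point" of a smoothed car-ownership curve:
#' fit a LOESS of cars per household against the accessibility score,
#' differentiate the fitted curve numerically on a fine grid, and report
#' the smallest score at which the derivative falls below
#' `-threshold_frac * max(|derivative|)` and stays below it for the rest
#' of the range. A sustained crossing that starts at the very first grid
#' point means the curve declines from the outset — no plateau-then-drop
#' regime change — and is reported as not detected, as is a numerically
#' constant curve. Straight-line fits on either side of the turning point
#' give the pre- and post-slopes.
#'
#' @param data data frame of sector records.
#' @param score,cars unquoted column names of the accessibility score
#'   (e.g. Mobiscore) and cars per household.
#' @param span,degree LOESS settings (a smaller span than usual is needed
#'   to resolve the kink; default 0.15).
#' @param n_grid size of the derivative evaluation grid.
#' @param threshold_frac fraction of the maximum absolute derivative used
#'   as the sustained-decline threshold.
#' @param trim fraction of the evaluation range dropped at each end
#'   before applying the rule; local-regression derivatives are unstable
#'   in the boundary windows and would otherwise distort the reference
#'   maximum.
#' @return An object of class `turning_point` with fields `x_star`,
#'   `detected`, `pre_slope`, `post_slope`, `threshold`, `method` and the
#'   underlying `loess_fit`. `tidy()` returns the smoothed curve,
#'   `glance()` the detection summary.
#' @examples
#' set.seed(1)
#' d <- data.frame(m = runif(200, 0, 10))
#' d$cars <- 1.1 - 0.4 * pmax(d$m - 8, 0) + rnorm(200, 0, 0.05)
#' glance(turning_point(d, m, cars))
#' @export
turning_point <- function(data, score, cars, span = 0.15, degree = 1,
                          n_grid = 200, threshold_frac = 0.5, trim = 0.05) {
  x <- eval_tidy(enquo(score), data)
  y <- eval_tidy(enquo(cars), data)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 30) abort("need at least 30 sectors with score and car ownership.")
  d <- tibble(x = x, y = y)
  lf <- loess_fit(d, x, y, span = span, degree = degree,
                  eval_x = seq(min(x), max(x), length.out = n_grid))
  g <- lf$eval_x
  fit <- lf$fitted
  h <- diff(g)[1]
  deriv <- c(diff(fit) / h, NA)
  deriv[n_grid] <- deriv[n_grid - 1]
  # detection operates on the interior of the grid
  k <- max(1L, ceiling(trim * n_grid))
  interior <- seq.int(k, n_grid - k + 1L)
  mx <- max(abs(deriv[interior]))
  res <- list(x_star = NA_real_, detected = FALSE,
              pre_slope = NA_real_, post_slope = NA_real_,
              threshold = NA_real_,
              method = sprintf("loess span %.2f deg %d; sustained derivative < -%.2f * max|d|",
                               span, degree, threshold_frac),
              fit = lf)
  if (mx > 1e-10 && diff(range(y)) > 1e-12) {
    thr <- -threshold_frac * mx
    below <- deriv[interior] < thr
    # rev(cumprod(rev(below))): TRUE where below from here to the end
    sustained <- rev(cumprod(rev(below))) > 0
    idx <- interior[sustained]
    if (length(idx) > 0 && idx[1] > interior[1]) {
      x_star <- g[idx[1]]
      res$x_star <- x_star
      res$detected <- TRUE
      res$threshold <- thr
      pre <- d |> filter(.data$x < x_star)
      post <- d |> filter(.data$x >= x_star)
      if (nrow(pre) >= 2) res$pre_slope <- unname(coef(lm(y ~ x, pre))[2])
      if (nrow(post) >= 2) res$post_slope <- unname(coef(lm(y ~ x, post))[2])
    }
  }
  structure(res, class = "turning_point")
}

#' @export
print.turning_point <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("<turning_point> x* = %.2f (pre slope %.3f, post slope %.3f)\n",
                x$x_star, x$pre_slope, x$post_slope))
  } else {
    cat("<turning_point> no sustained regime change detected\n")
  }
  invisible(x)
}

#' @export
tidy.turning_point <- function(x, ...) tidy(x$fit, ...)

#' @export
glance.turning_point <- function(x, ...) {
  tibble(detected = x$detected, x_star = x$x_star,
         pre_slope = x$pre_slope, post_slope = x$post_slope,
         threshold = x$threshold, method = x$method)
}

#' @export
autoplot.turning_point <- function(object, ...) {
  td <- tidy(object)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$.fitted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$.lower, ymax = .data$.upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "accessibility score", y = "cars per household")
  if (object$detected) {
    p <- p + ggplot2::geom_vline(xintercept = object$x_star,
                                 linetype = "dashed")
  }
  p
}
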