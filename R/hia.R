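#' Exposure-response configuration for one pollutant
#'
#' Bundles a literature relative risk per 10 ug/m3 of long-term exposure
#' (point estimate and 95% CI) with the WHO long-term guideline value
#' used as the counterfactual.
#'
#' @param pollutant pollutant label.
#' @param rr10 relative risk per 10 ug/m3 increase.
#' @param rr10_low,rr10_high 95% CI bounds of `rr10`.
#' @param guideline WHO long-term guideline (ug/m3).
#' @return A list of class `exposure_response`.
#' @seealso [default_erf()] for the ELAPSE all-cause mortality values.
#' @export
exposure_response <- function(pollutant, rr10, rr10_low, rr10_high,
                              guideline) {
  if (!(rr10_low <= rr10 && rr10 <= rr10_high)) {
    abort("require rr10_low <= rr10 <= rr10_high.")
  }
  if (any(c(rr10, rr10_low, rr10_high) <= 0)) abort("relative risks must be positive.")
  if (guideline < 0) abort("`guideline` must be >= 0.")
  structure(list(pollutant = pollutant, rr10 = rr10, rr10_low = rr10_low,
                 rr10_high = rr10_high, guideline = guideline),
            class = "exposure_response")
}

#' Default exposure-response functions (ELAPSE meta-analysis, all-cause
#' mortality) and 2021 WHO long-term guidelines
#'
#' NO2: RR 1.045 (95% CI 1.026-1.065) per 10 ug/m3, guideline 10 ug/m3.
#' PM2.5: RR 1.118 (95% CI 1.06-1.179) per 10 ug/m3, guideline 5 ug/m3.
#'
#' @return Named list of [exposure_response()] objects for `NO2` and
#'   `PM25`.
#' @export
default_erf <- function() {
  list(
    NO2 = exposure_response("NO2", 1.045, 1.026, 1.065, guideline = 10),
    PM25 = exposure_response("PM25", 1.118, 1.060, 1.179, guideline = 5)
  )
}

#' Excess concentration above a guideline
#'
#' The exposure increment that would disappear under the counterfactual
#' of meeting the guideline: `max(conc - guideline, 0)`.
#'
#' @param conc concentration (ug/m3, >= 0). Vectorised.
#' @param guideline guideline value (ug/m3).
#' @return Excess concentration (ug/m3).
#' @export
excess_concentration <- function(conc, guideline) {
  if (any(conc < 0, na.rm = TRUE)) abort("`conc` must be >= 0.")
  pmax(conc - guideline, 0)
}

#' Rescale a relative risk from its 10 ug/m3 increment to an exposure
#'
#' Log-linear rescaling: `RR_exposure = exp(log(rr10) / 10 * con)`.
#' Equals `rr10` at `con = 10` and 1 at `con = 0`.
#'
#' @param rr10 relative risk per 10 ug/m3 (> 0). Vectorised.
#' @param con concentration increment (ug/m3, >= 0). Vectorised.
#' @return The rescaled relative risk.
#' @examples
#' rescale_rr(1.045, 10) # 1.045
#' rescale_rr(1.118, 20) # 1.118^2
#' @export
rescale_rr <- function(rr10, con) {
  if (any(rr10 <= 0)) abort("`rr10` must be positive.")
  if (any(con < 0, na.rm = TRUE)) abort("`con` must be >= 0.")
  exp(log(rr10) / 10 * con)
}

#' Preventable fraction of an outcome for a given relative risk
#'
#' `PF = 1 - 1/RR`: the proportion of the outcome that would not occur
#' under the counterfactual exposure. Relative risks below 1 (protective)
#' are outside the scope of a preventable fraction and are clipped to
#' PF = 0 with a warning.
#'
#' @param rr relative risk (>= 1 expected). Vectorised.
#' @return Preventable fraction in [0, 1).
#' @examples
#' preventable_fraction(2) # 0.5
#' @export
preventable_fraction <- function(rr) {
  if (any(rr < 1)) {
    warn("relative risk(s) below 1 clipped to preventable fraction 0.")
    rr <- pmax(rr, 1)
  }
  1 - 1 / rr
}

#' Sample relative risks from a triangular distribution
#'
#' Draws RR10 values from Triangular(a = `rr10_low`, c = `rr10`,
#' b = `rr10_high`) by inverse-CDF transform of seeded uniforms, the
#' standard way of propagating a point-estimate-plus-CI through a Monte
#' Carlo analysis. Degenerate a = b returns the constant.
#'
#' @param er an [exposure_response()].
#' @param n number of draws.
#' @param seed optional seed for the uniform stream.
#' @return Numeric vector of `n` draws, all within `[a, b]`.
#' @export
sample_rr_triangular <- function(er, n, seed = NULL) {
  stopifnot(inherits(er, "exposure_response"), n >= 1)
  a <- er$rr10_low; b <- er$rr10_high; c0 <- er$rr10
  if (a == b) return(rep(a, n))
  u <- if (is.null(seed)) runif(n) else withr::with_seed(seed, runif(n))
  fc <- (c0 - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c0 - a)),
         b - sqrt((1 - u) * (b - a) * (b - c0)))
}

#' Preventable fraction with Monte Carlo uncertainty
#'
#' Sector-level and nationally aggregated preventable fractions against
#' the WHO-guideline counterfactual. For each sector the annual mean
#' concentration is converted to the exposure increment CON (by default
#' the excess over the guideline, clipped at 0; set
#' `counterfactual = "zero"` to use the raw concentration), the
#' literature RR10 is rescaled to that increment and PF = 1 - 1/RR is
#' computed. The national figure is the population-weighted mean of the
#' sector PFs. Uncertainty: `n_iter` Monte Carlo iterations drawing RR10
#' from a triangular distribution ([sample_rr_triangular()]); CI =
#' 2.5/97.5 percentiles over iterations, point estimate at the mode.
#'
#' @param exposure exposure tibble from [zonal_mean()] (all four seasons).
#' @param sectors sector attribute tibble with `population`.
#' @param er an [exposure_response()].
#' @param n_iter Monte Carlo iterations (default 10000).
#' @param seed seed of the Monte Carlo stream.
#' @param counterfactual `"guideline"` (default) or `"zero"`.
#' @param conf_level CI level.
#' @return A tibble of class `pf_result`: rows for each sector plus one
#'   national row (`level`, `sector_id`, `pollutant`, `con`,
#'   `rr_exposure`, `pf`, `pf_low`, `pf_high`), with attributes
#'   `n_iterations`, `seed` and `counterfactual`.
#' @export
pf_with_uncertainty <- function(exposure, sectors, er, n_iter = 10000,
                                seed = 1L, counterfactual = c("guideline", "zero"),
                                conf_level = 0.95) {
  counterfactual <- match.arg(counterfactual)
  stopifnot(inherits(er, "exposure_response"))
  ann <- annual_means(exposure |> filter(.data$pollutant == er$pollutant))
  if (nrow(ann) == 0) abort(sprintf("no annual means available for %s.", er$pollutant))
  ann <- ann |> inner_join(sectors |> select("sector_id", "population"),
                           by = "sector_id")
  con <- if (counterfactual == "guideline") {
    excess_concentration(ann$annual_mean, er$guideline)
  } else {
    ann$annual_mean
  }
  rr_point <- rescale_rr(er$rr10, con)
  pf_point <- 1 - 1 / rr_point # rr_point >= 1 since con >= 0, rr10 > 1 assumed
  pf_point[rr_point < 1] <- 0
  nat_point <- sum(pf_point * ann$population) / sum(ann$population)
  draws <- sample_rr_triangular(er, n_iter, seed = seed)
  # sectors x iterations PF matrix via the log-linear rescaling
  logd <- log(draws) / 10
  pf_mat <- 1 - exp(-outer(con, logd))
  pf_mat[pf_mat < 0] <- 0
  w <- ann$population / sum(ann$population)
  nat_draws <- as.vector(crossprod(pf_mat, w))
  alpha <- (1 - conf_level) / 2
  qs <- unname(t(apply(pf_mat, 1, quantile, probs = c(alpha, 1 - alpha))))
  nat_q <- unname(quantile(nat_draws, c(alpha, 1 - alpha)))
  out <- bind_rows(
    tibble(level = "sector", sector_id = ann$sector_id,
           pollutant = er$pollutant, con = con, rr_exposure = rr_point,
           pf = pf_point, pf_low = qs[, 1], pf_high = qs[, 2]),
    tibble(level = "national", sector_id = NA,
           pollutant = er$pollutant, con = NA_real_,
           rr_exposure = NA_real_, pf = nat_point,
           pf_low = nat_q[[1]], pf_high = nat_q[[2]])
  )
  class(out) <- c("pf_result", class(out))
  attr(out, "n_iterations") <- n_iter
  attr(out, "seed") <- seed
  attr(out, "counterfactual") <- counterfactual
  out
}

#' @export
glance.pf_result <- function(x, ...) {
  nat <- x |> filter(.data$level == "national")
  tibble(pollutant = nat$pollutant, pf = nat$pf, pf_low = nat$pf_low,
         pf_high = nat$pf_high,
         n_iterations = attr(x, "n_iterations"),
         seed = attr(x, "seed"),
         counterfactual = attr(x, "counterfactual"))
}

#' @export
autoplot.pf_result <- function(object, ...) {
  d <- object |> filter(.data$level == "sector") |>
    arrange(.data$pf) |> mutate(rank = dplyr::row_number())
  nat <- object |> filter(.data$level == "national")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = 100 * .data$pf)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * .data$pf_low,
                                      ymax = 100 * .data$pf_high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 100 * nat$pf, linetype = "dashed") +
    ggplot2::labs(x = "sectors (ranked)", y = "preventable fraction (%)",
                  title = sprintf("%s: national PF %.1f%% [%.1f-%.1f]",
                                  nat$pollutant, 100 * nat$pf,
                                  100 * nat$pf_low, 100 * nat$pf_high))
}
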