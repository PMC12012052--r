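# Local weighted polynomial regression with tricube weights.
#
# The engine works on bare vectors; loess_fit() is the data-frame-first
# user surface. At each evaluation point x0 the q = ceiling(span * n)
# nearest observations (ties broken by lower index) are weighted by
# w = (1 - (d/dmax)^3)^3 and a degree-1 or degree-2 polynomial centered
# at x0 is fit by weighted least squares; the fitted value is the
# intercept and its hat vector l gives se = sigma * sqrt(sum(l^2)) with a
# single global residual variance sigma^2 = RSS / (n - tr(L)) estimated
# from the fit at the data points themselves.

loess_weights <- function(x, x0, q) {
  d <- abs(x - x0)
  ord <- order(d, seq_along(d)) # deterministic tie-break: lower index first
  idx <- ord[seq_len(q)]
  dmax <- d[idx[q]]
  w <- numeric(length(x))
  if (dmax == 0) {
    w[idx] <- 1
  } else {
    u <- pmin(d[idx] / dmax, 1)
    w[idx] <- (1 - u^3)^3
    # the furthest neighbour gets weight 0 by construction; keep a tiny
    # positive weight when too few points remain for the local polynomial
    if (sum(w > 0) < 3) w[idx] <- pmax(w[idx], 1e-9)
  }
  w
}

# hat (equivalent-kernel) vector of the local fit at x0
loess_hat <- function(x, x0, q, degree) {
  w <- loess_weights(x, x0, q)
  use <- which(w > 0)
  X <- outer(x[use] - x0, 0:degree, `^`)
  W <- w[use]
  XtWX <- crossprod(X, X * W)
  # l' y = e1' (X'WX)^-1 X'W y; tiny ridge if the local design is singular
  # (all in-window x coincide)
  l1 <- tryCatch(
    solve(XtWX, t(X * W))[1, ],
    error = function(e) {
      solve(XtWX + diag(1e-10, ncol(X)), t(X * W))[1, ]
    }
  )
  l <- numeric(length(x))
  l[use] <- l1
  l
}

loess_engine <- function(x, y, span, degree, eval_x) {
  n <- length(x)
  q <- ceiling(span * n)
  if (q < degree + 2) {
    abort(sprintf("span %.2f keeps only %d neighbours; need at least degree + 2 = %d.",
                  span, q, degree + 2))
  }
  L_data <- t(vapply(x, loess_hat, numeric(n), x = x, q = q, degree = degree))
  fitted_data <- as.vector(L_data %*% y)
  resid <- y - fitted_data
  df_model <- sum(diag(L_data))
  df_resid <- max(n - df_model, 1e-8)
  sigma2 <- sum(resid^2) / df_resid
  ev <- vapply(eval_x, function(x0) {
    l <- loess_hat(x, x0, q, degree)
    c(sum(l * y), sqrt(sigma2 * sum(l^2)))
  }, numeric(2))
  list(eval_x = eval_x, fitted = ev[1, ], se = ev[2, ],
       fitted_data = fitted_data, sigma = sqrt(sigma2),
       df_model = df_model, n = n, q = q)
}

#' Locally weighted regression (LOESS) with tricube weights
#'
#' A self-contained LOESS smoother: at each evaluation point the
#' `ceiling(span * n)` nearest observations are tricube-weighted and a
#' local polynomial of the given degree is fit by weighted least squares.
#' Pointwise standard errors come from the local hat vector and a global
#' residual variance estimate; the 95% band is `fitted +/- 1.96 * se`.
#' Evaluation outside the observed x range is an error (no
#' extrapolation). With `degree = 1` and data that are exactly linear in
#' x, the fit reproduces the line at every evaluation point.
#'
#' @param data data frame with the predictor and response.
#' @param x,y unquoted column names of predictor and response.
#' @param span fraction of observations in each local neighbourhood,
#'   in (0, 1]. Default 0.75.
#' @param degree local polynomial degree, 1 (default) or 2.
#' @param eval_x evaluation grid; default a length-`n_eval` uniform grid
#'   over the observed x range.
#' @param n_eval size of the default evaluation grid.
#' @return An object of class `loess_fit`; use [tidy()] for the fitted
#'   curve, [glance()] for fit summaries, [autoplot()] to plot, and
#'   [predict()] for new evaluation points.
#' @examples
#' d <- data.frame(x = 1:20, y = (1:20) * 2 + 1)
#' fit <- loess_fit(d, x, y, span = 0.5)
#' head(tidy(fit))
#' @export
loess_fit <- function(data, x, y, span = 0.75, degree = 1,
                      eval_x = NULL, n_eval = 50) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (!degree %in% c(1, 2)) abort("`degree` must be 1 or 2.")
  if (span <= 0 || span > 1) abort("`span` must be in (0, 1].")
  if (length(unique(xv)) < degree + 2) {
    abort(sprintf("need at least %d distinct x values for degree %d.",
                  degree + 2, degree))
  }
  rng <- range(xv)
  if (is.null(eval_x)) eval_x <- seq(rng[1], rng[2], length.out = n_eval)
  if (any(eval_x < rng[1] - 1e-12 | eval_x > rng[2] + 1e-12)) {
    abort("evaluation points outside the observed x range (no extrapolation).")
  }
  eng <- loess_engine(xv, yv, span, degree, eval_x)
  structure(
    list(x = xv, y = yv, span = span, degree = degree,
         eval_x = eng$eval_x, fitted = eng$fitted, se = eng$se,
         fitted_data = eng$fitted_data, sigma = eng$sigma,
         df_model = eng$df_model, n = eng$n),
    class = "loess_fit"
  )
}

#' @export
print.loess_fit <- function(x, ...) {
  cat(sprintf("<loess_fit> n = %d, span = %.2f, degree = %d, sigma = %.4g\n",
              x$n, x$span, x$degree, x$sigma))
  invisible(x)
}

#' @rdname loess_fit
#' @param object,x_new a `loess_fit` and new evaluation points.
#' @export
predict.loess_fit <- function(object, x_new, ...) {
  rng <- range(object$x)
  if (any(x_new < rng[1] - 1e-12 | x_new > rng[2] + 1e-12)) {
    abort("evaluation points outside the observed x range (no extrapolation).")
  }
  eng <- loess_engine(object$x, object$y, object$span, object$degree, x_new)
  tibble(x = x_new, .fitted = eng$fitted, .se = eng$se)
}

#' Tidy a LOESS fit into its evaluated curve
#'
#' @param x a `loess_fit`.
#' @param conf_level confidence level for the pointwise band.
#' @param ... unused.
#' @return Tibble `x`, `.fitted`, `.se`, `.lower`, `.upper`.
#' @export
tidy.loess_fit <- function(x, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ex <- x$eval_x; ft <- x$fitted; se <- x$se
  tibble(x = ex, .fitted = ft, .se = se,
         .lower = ft - z * se, .upper = ft + z * se)
}

#' @export
glance.loess_fit <- function(x, ...) {
  tibble(n = x$n, span = x$span, degree = x$degree,
         sigma = x$sigma, df_model = x$df_model,
         df_residual = x$n - x$df_model)
}

#' @export
autoplot.loess_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$.fitted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$.lower, ymax = .data$.upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "fitted", title = sprintf(
      "LOESS (span %.2f, degree %d)", object$span, object$degree))
}
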