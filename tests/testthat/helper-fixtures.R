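# Shared fixtures, built in code.

# small quiet region for structural tests
tiny_spec <- function(..., seed = 11) {
  region_spec(grid_shape = c(20, 24), n_sectors = 12, noise_sd = 0,
              cars_noise_sd = 0, seed = seed, ...)
}

# geometry with a long reach so the background stratum is effectively at
# infinite road distance (exp(-50/2) ~ 1e-11 relative increment)
farfield_spec <- function(..., seed = 5) {
  region_spec(grid_shape = c(30, 120), n_sectors = 18, decay_scale = 2,
              road_cells = data.frame(row = 1:30, col = 2),
              noise_sd = 0, cars_noise_sd = 0, seed = seed, ...)
}

# hand-rolled exposure table: one sector, four seasonal means
one_sector_exposure <- function(means = c(winter = 20, spring = 10,
                                          summer = 5, autumn = 15),
                                pollutant = "NO2") {
  tibble::tibble(sector_id = 1L, pollutant = pollutant,
                 season = names(means), mean_conc = unname(means),
                 n_cells = 1L)
}

# independent oracle: brute-force zonal mean by explicit looping
zonal_mean_loop <- function(fields, cells) {
  out <- list()
  for (p in unique(fields$pollutant)) {
    for (s in unique(fields$season)) {
      f <- fields[fields$pollutant == p & fields$season == s, ]
      for (sid in sort(unique(cells$sector_id))) {
        cc <- cells[cells$sector_id == sid, ]
        vals <- numeric(0)
        for (i in seq_len(nrow(cc))) {
          v <- f$conc[f$row == cc$row[i] & f$col == cc$col[i]]
          if (length(v) == 1 && !is.na(v)) vals <- c(vals, v)
        }
        out[[length(out) + 1]] <- data.frame(
          sector_id = sid, pollutant = p, season = s,
          mean_conc = mean(vals), n_cells = length(vals))
      }
    }
  }
  tibble::as_tibble(do.call(rbind, out))
}

# independent oracle: nearest-road distance by explicit double loop
brute_force_distance <- function(rows, cols, road) {
  d <- matrix(Inf, rows, cols)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    for (k in seq_len(nrow(road))) {
      d[r, c] <- min(d[r, c],
                     sqrt((r - road$row[k])^2 + (c - road$col[k])^2))
    }
  }
  d
}

# independent oracle: one local weighted fit via explicit normal equations
loess_probe_oracle <- function(x, y, span, degree, x0) {
  n <- length(x)
  q <- ceiling(span * n)
  d <- abs(x - x0)
  idx <- order(d, seq_along(d))[1:q]
  dmax <- max(d[idx])
  w <- (1 - pmin(d[idx] / dmax, 1)^3)^3
  X <- outer(x[idx] - x0, 0:degree, `^`)
  A <- t(X) %*% diag(w) %*% X
  b <- t(X) %*% diag(w) %*% y[idx]
  solve(A, b)[1, 1]
}
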