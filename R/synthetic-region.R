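# Euclidean distance (in cell units) from every cell center to the nearest
# road cell center. Accumulates a running minimum over road cells, which is
# O(cells x roads) but vectorised over cells.
min_road_distance <- function(rows, cols, road_cells) {
  if (nrow(road_cells) == 0) abort("road mask is empty: at least one road cell required.")
  cr <- rep(seq_len(rows), times = cols)
  cc <- rep(seq_len(cols), each = rows)
  d2 <- rep(Inf, rows * cols)
  for (k in seq_len(nrow(road_cells))) {
    d2 <- pmin(d2, (cr - road_cells$row[k])^2 + (cc - road_cells$col[k])^2)
  }
  matrix(sqrt(d2), nrow = rows, ncol = cols)
}

grid_cells_tbl <- function(rows, cols) {
  tibble(row = rep(seq_len(rows), times = cols),
         col = rep(seq_len(cols), each = rows))
}

# noise-free concentration surface for one pollutant x season
true_surface <- function(spec, pollutant, season, dist = NULL) {
  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  if (is.null(dist)) dist <- min_road_distance(rows, cols, spec$road_cells)
  bg_w <- spec$background_winter[[pollutant]]
  inc_w <- spec$road_increment_winter[[pollutant]]
  r_bg <- spec$planted_ratio_background[[pollutant]]
  r_rd <- spec$planted_ratio_road[[pollutant]]
  bg <- bg_w * season_factor(season, r_bg)
  road_total <- (bg_w + inc_w) * season_factor(season, r_rd)
  inc <- road_total - bg
  bg + inc * exp(-dist / spec$decay_scale)
}

#' Generate seasonal concentration fields for a synthetic region
#'
#' Builds one gridded concentration surface per pollutant and season:
#' a seasonal background plus a road increment decaying exponentially with
#' distance to the nearest road cell, plus independent Gaussian cell noise
#' (clipped at a 0.1 ug/m3 floor so ratios stay defined). Noise-free, the
#' cellwise summer/winter ratio equals `planted_ratio_road` on road cells
#' and approaches `planted_ratio_background` far from roads.
#'
#' Draws come from a stream seeded with `spec$seed`; pollutants are
#' processed in spec order and seasons winter, spring, summer, autumn, so
#' regeneration with the same spec is bit-identical.
#'
#' @param spec a [region_spec()].
#' @return A tibble with columns `pollutant`, `season`, `row`, `col`,
#'   `conc` (ug/m3), carrying a `grid_meta` attribute.
#' @examples
#' f <- generate_fields(region_spec(grid_shape = c(10, 12), n_sectors = 4, noise_sd = 0))
#' dplyr::count(f, pollutant, season)
#' @export
generate_fields <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  dist <- min_road_distance(rows, cols, spec$road_cells)
  base <- grid_cells_tbl(rows, cols)
  out <- withr::with_seed(spec$seed, {
    purrr::map_dfr(spec$pollutants, function(p) {
      purrr::map_dfr(spec$seasons, function(s) {
        tru <- true_surface(spec, p, s, dist)
        conc <- as.vector(tru)
        if (spec$noise_sd > 0) {
          conc <- conc + rnorm(length(conc), 0, spec$noise_sd)
        }
        conc <- pmax(conc, 0.1)
        tibble(pollutant = p, season = s, row = base$row, col = base$col,
               conc = conc)
      })
    })
  })
  attr(out, "grid_meta") <- grid_meta(rows, cols, cell_size = spec$cell_size)
  out
}

# contiguous partition of the grid into n_sectors regions: rectangular
# tiling with a few random merges of adjacent tiles
partition_sectors <- function(rows, cols, n_sectors) {
  nr_t <- max(1L, min(rows, as.integer(round(sqrt(n_sectors * rows / cols)))))
  nc_t <- as.integer(ceiling(n_sectors / nr_t))
  while (nc_t > cols) {
    nr_t <- nr_t + 1L
    nc_t <- as.integer(ceiling(n_sectors / nr_t))
  }
  row_band <- as.integer(cut(seq_len(rows), breaks = nr_t, labels = FALSE))
  col_band <- as.integer(cut(seq_len(cols), breaks = nc_t, labels = FALSE))
  tile <- outer(row_band, col_band, function(r, c) (r - 1L) * nc_t + c)
  # merge surplus tiles into a grid-adjacent neighbour; merging two
  # contiguous regions keeps the union contiguous
  n_tiles <- nr_t * nc_t
  alive <- seq_len(n_tiles)
  label <- seq_len(n_tiles) # current region id of each original tile
  tile_r <- (seq_len(n_tiles) - 1L) %/% nc_t + 1L
  tile_c <- (seq_len(n_tiles) - 1L) %% nc_t + 1L
  while (length(unique(label)) > n_sectors) {
    victims <- unique(label)
    v <- sample(victims, 1)
    members <- which(label == v)
    nbrs <- integer(0)
    for (m in members) {
      cand <- c(
        if (tile_r[m] > 1) m - nc_t,
        if (tile_r[m] < nr_t) m + nc_t,
        if (tile_c[m] > 1) m - 1L,
        if (tile_c[m] < nc_t) m + 1L
      )
      nbrs <- c(nbrs, cand)
    }
    nbr_labels <- setdiff(unique(label[nbrs]), v)
    if (length(nbr_labels) == 0) next
    target <- if (length(nbr_labels) == 1) nbr_labels else sample(nbr_labels, 1)
    label[label == v] <- target
  }
  sector_of_tile <- match(label, sort(unique(label)))
  matrix(sector_of_tile[tile], nrow = rows, ncol = cols)
}

#' Generate the sector attribute table of a synthetic region
#'
#' Partitions the grid into `n_sectors` contiguous sectors (rectangular
#' tiling perturbed by random merges) and assigns per-sector attributes:
#' population (rounded Gaussian around `population_mean`), land cover
#' (modal class of member cells, from a 6-class palette assigned by
#' distance to road), degree of urbanisation (DEGURBA 1/2/3 by tertiles of
#' mean road distance, 1 = closest), a deprivation decile (in urban
#' sectors negatively associated with distance to road, so deprived urban
#' sectors sit in high-NO2 locations), a Mobiscore accessibility score in
#' [0, 10] (higher near roads/centres), and cars per household following a
#' plateau-then-decline rule in the Mobiscore with changepoint
#' `mobiscore_changepoint`.
#'
#' @param spec a [region_spec()].
#' @return A list with `sectors` (one row per sector: `sector_id`,
#'   `population`, `landcover`, `degurba`, `bimd_decile`, `mobiscore`,
#'   `cars_per_household`, `n_cells`, `mean_road_dist`) and `cells`
#'   (cell membership: `row`, `col`, `sector_id`, `landcover`,
#'   `road_dist`).
#' @examples
#' s <- generate_sectors(region_spec(grid_shape = c(20, 20), n_sectors = 12))
#' head(s$sectors)
#' @export
generate_sectors <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  dist <- min_road_distance(rows, cols, spec$road_cells)
  dmax <- max(dist)
  dist_norm <- if (dmax > 0) dist / dmax else dist
  withr::with_seed(spec$seed + 1L, {
    sec <- partition_sectors(rows, cols, spec$n_sectors)
    cells <- grid_cells_tbl(rows, cols) |>
      mutate(
        sector_id = sec[cbind(.data$row, .data$col)],
        road_dist = dist[cbind(.data$row, .data$col)],
        dist_norm = dist_norm[cbind(.data$row, .data$col)]
      )
    on_road <- rep(FALSE, nrow(cells))
    on_road[cells$road_dist == 0] <- TRUE
    # 6-class land cover by jittered distance band
    band <- cells$dist_norm + rnorm(nrow(cells), 0, 0.03)
    lc <- dplyr::case_when(
      on_road ~ "road_rail",
      band < 0.10 ~ "urban_fabric",
      band < 0.18 ~ "industry",
      band < 0.45 ~ "arable",
      band < 0.70 ~ "pasture",
      TRUE ~ "forest"
    )
    cells$landcover <- lc
    n <- spec$n_sectors
    sectors <- cells |>
      group_by(.data$sector_id) |>
      summarise(
        n_cells = dplyr::n(),
        mean_road_dist = mean(.data$road_dist),
        mean_dist_norm = mean(.data$dist_norm),
        landcover = names(sort(table(.data$landcover), decreasing = TRUE))[1],
        .groups = "drop"
      )
    sectors$population <- pmax(25, round(rnorm(n, spec$population_mean,
                                               spec$population_sd)))
    sectors$degurba <- as.integer(cut(rank(sectors$mean_road_dist,
                                           ties.method = "first"),
                                      breaks = 3, labels = FALSE))
    # deprivation deciles: urban score tracks winter NO2 (standardised),
    # so after reversal decile 1 (most deprived) holds the highest NO2
    no2w_surface <- true_surface(spec, "NO2", "winter", dist)
    no2w_by_sector <- cells |>
      mutate(v = no2w_surface[cbind(.data$row, .data$col)]) |>
      group_by(.data$sector_id) |>
      summarise(no2w = mean(.data$v), .groups = "drop")
    no2w <- no2w_by_sector$no2w[match(sectors$sector_id,
                                      no2w_by_sector$sector_id)]
    z <- as.vector(scale(no2w))
    if (any(!is.finite(z))) z <- rep(0, n)
    score <- ifelse(sectors$degurba == 1, spec$deprivation_no2_slope * z, 0) +
      rnorm(n, 0, 1)
    sectors$bimd_decile <- 11L - dplyr::ntile(score, 10)
    sectors$mobiscore <- pmin(10, pmax(0, 10.5 - 9 * sectors$mean_dist_norm +
                                         rnorm(n, 0, 0.6)))
    # exact piecewise-linear rule (no clipping: the planted slope must be
    # recoverable over the whole score range)
    over <- pmax(sectors$mobiscore - spec$mobiscore_changepoint, 0)
    cars <- spec$cars_plateau + spec$cars_post_slope * over
    if (spec$cars_noise_sd > 0) cars <- cars + rnorm(n, 0, spec$cars_noise_sd)
    sectors$cars_per_household <- cars
    list(
      sectors = sectors |>
        select("sector_id", "population", "landcover", "degurba",
               "bimd_decile", "mobiscore", "cars_per_household",
               "n_cells", "mean_road_dist"),
      cells = cells |> select("row", "col", "sector_id", "landcover",
                              "road_dist")
    )
  })
}

#' Simulate a complete synthetic study region with recorded ground truth
#'
#' Runs [generate_fields()] and [generate_sectors()] and assembles the
#' ground truth needed to validate every downstream stage: noise-free
#' per-sector seasonal means, the planted road/background summer-winter
#' ratios, the planted car-ownership changepoint and the master seed.
#'
#' @param spec a [region_spec()].
#' @return A list of class `season_region` with elements `spec`, `fields`
#'   (long concentration tibble), `sectors`, `cells` and `truth`.
#' @examples
#' reg <- simulate_region(region_spec(grid_shape = c(15, 20), n_sectors = 8))
#' names(reg)
#' @export
simulate_region <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  fields <- generate_fields(spec)
  sg <- generate_sectors(spec)
  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  dist <- min_road_distance(rows, cols, spec$road_cells)
  true_sector_means <- purrr::map_dfr(spec$pollutants, function(p) {
    purrr::map_dfr(spec$seasons, function(s) {
      tru <- true_surface(spec, p, s, dist)
      sg$cells |>
        mutate(conc = tru[cbind(.data$row, .data$col)]) |>
        group_by(.data$sector_id) |>
        summarise(true_mean = mean(.data$conc), .groups = "drop") |>
        mutate(pollutant = p, season = s, .before = 1)
    })
  })
  truth <- list(
    seed = spec$seed,
    planted_ratio_road = as.list(spec$planted_ratio_road),
    planted_ratio_background = as.list(spec$planted_ratio_background),
    mobiscore_changepoint = spec$mobiscore_changepoint,
    cars_plateau = spec$cars_plateau,
    cars_post_slope = spec$cars_post_slope,
    decay_scale = spec$decay_scale,
    true_sector_means = true_sector_means
  )
  structure(
    list(spec = spec, fields = fields, sectors = sg$sectors,
         cells = sg$cells, truth = truth),
    class = "season_region"
  )
}

#' @export
print.season_region <- function(x, ...) {
  cat("<season_region>\n")
  print(x$spec)
  cat(sprintf("  fields: %d cells x %d pollutant-season layers\n",
              prod(x$spec$grid_shape),
              length(x$spec$pollutants) * length(x$spec$seasons)))
  invisible(x)
}

#' Write the ground truth of a synthetic region to JSON
#'
#' @param region a `season_region` from [simulate_region()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(region, path) {
  stopifnot(inherits(region, "season_region"))
  tr <- region$truth
  tr$true_sector_means <- as.data.frame(tr$true_sector_means)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
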