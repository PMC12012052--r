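#' Read and validate a sector attribute table with cell membership
#'
#' The attribute CSV must carry `sector_id`, `population`, `landcover`,
#' `degurba`; `bimd_decile`, `mobiscore` and `cars_per_household` are
#' optional and may be missing (empty cells). The membership CSV links
#' sectors to raster cells with columns `sector_id`, `row`, `col`.
#'
#' Validation: sector ids unique; populations non-negative (zero allowed
#' but flagged with a warning, since zero-population sectors drop out of
#' population-weighted summaries); `degurba` in {1,2,3}; deciles in 1..10
#' or missing; membership rows must reference known sectors.
#'
#' @param attr_path path to the attribute CSV.
#' @param membership_path path to the cell-membership CSV (optional).
#' @return A list with `sectors` and `cells` tibbles (`cells` is `NULL`
#'   when no membership file is given).
#' @export
read_sectors <- function(attr_path, membership_path = NULL) {
  sectors <- readr::read_csv(attr_path, show_col_types = FALSE)
  need <- c("sector_id", "population", "landcover", "degurba")
  miss <- setdiff(need, names(sectors))
  if (length(miss) > 0) {
    abort(sprintf("sector table is missing required columns: %s.",
                  paste(miss, collapse = ", ")))
  }
  for (opt in c("bimd_decile", "mobiscore", "cars_per_household")) {
    if (!opt %in% names(sectors)) sectors[[opt]] <- NA_real_
  }
  if (anyDuplicated(sectors$sector_id)) {
    abort("duplicate sector ids in attribute table.")
  }
  if (any(sectors$population < 0, na.rm = TRUE)) {
    abort("negative population in sector table.")
  }
  if (any(sectors$population == 0, na.rm = TRUE)) {
    warn("sectors with population 0 present; they are excluded from population-weighted summaries.")
  }
  if (!all(sectors$degurba %in% c(1, 2, 3))) {
    abort("`degurba` must be 1 (city), 2 (towns/suburbs) or 3 (rural).")
  }
  dec <- sectors$bimd_decile
  if (any(!is.na(dec) & !(dec %in% 1:10))) {
    abort("`bimd_decile` must be in 1..10 or missing.")
  }
  cells <- NULL
  if (!is.null(membership_path)) {
    cells <- readr::read_csv(membership_path, show_col_types = FALSE)
    if (!all(c("sector_id", "row", "col") %in% names(cells))) {
      abort("membership table needs columns sector_id, row, col.")
    }
    unknown <- setdiff(unique(cells$sector_id), sectors$sector_id)
    if (length(unknown) > 0) {
      abort(sprintf("membership references unknown sector ids: %s.",
                    paste(utils::head(unknown, 5), collapse = ", ")))
    }
  }
  list(sectors = sectors, cells = cells)
}

# per-sector cell squares compacted to row-run rectangles, as GeoJSON
# MultiPolygon coordinates (map units, per the package grid convention)
sector_rectangles <- function(cells, meta) {
  cells |>
    arrange(.data$sector_id, .data$row, .data$col) |>
    group_by(.data$sector_id, .data$row) |>
    mutate(run = cumsum(c(1L, diff(.data$col) != 1L))) |>
    group_by(.data$sector_id, .data$row, .data$run) |>
    summarise(col0 = min(.data$col), col1 = max(.data$col), .groups = "drop") |>
    mutate(
      xmin = meta$x_origin + (.data$col0 - 1) * meta$cell_size,
      xmax = meta$x_origin + .data$col1 * meta$cell_size,
      ymax = meta$y_origin - (.data$row - 1) * meta$cell_size,
      ymin = meta$y_origin - .data$row * meta$cell_size
    )
}

#' Write a sector frame to CSV + GeoJSON + membership CSV
#'
#' @param sectors sector attribute tibble.
#' @param cells cell-membership tibble (`sector_id`, `row`, `col`).
#' @param dir output directory (created if needed).
#' @param meta a [grid_meta()] for polygon coordinates.
#' @return Named character vector of the three written paths, invisibly.
#' @export
write_sectors <- function(sectors, cells, dir, meta) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  attr_path <- file.path(dir, "sectors.csv")
  mem_path <- file.path(dir, "sector_cells.csv")
  gj_path <- file.path(dir, "sectors.geojson")
  readr::write_csv(sectors, attr_path)
  readr::write_csv(cells |> select("sector_id", "row", "col"), mem_path)
  rects <- sector_rectangles(cells, meta)
  feats <- lapply(split(rects, rects$sector_id), function(rr) {
    polys <- lapply(seq_len(nrow(rr)), function(i) {
      with(rr[i, ], list(list(
        c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax),
        c(xmin, ymin)
      )))
    })
    list(
      type = "Feature",
      properties = list(sector_id = rr$sector_id[1]),
      geometry = list(type = "MultiPolygon", coordinates = polys)
    )
  })
  gj <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(gj, gj_path, auto_unbox = TRUE, digits = NA)
  invisible(c(attributes = attr_path, membership = mem_path,
              geojson = gj_path))
}

# even-odd ray casting: is point (px, py) inside the ring?
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Rasterise GeoJSON sector polygons to a cell-membership table
#'
#' Assigns each raster cell to the sector whose polygon contains the cell
#' center (even-odd rule; later features win ties). Intended for real
#' data delivered as polygons; synthetic regions carry an explicit
#' membership table already.
#'
#' @param geojson_path path to a GeoJSON FeatureCollection of (Multi)Polygons
#'   with a `sector_id` property.
#' @param meta a [grid_meta()] describing the target grid.
#' @return A membership tibble (`sector_id`, `row`, `col`); cells outside
#'   all polygons are dropped.
#' @export
rasterise_sectors <- function(geojson_path, meta) {
  gj <- jsonlite::read_json(geojson_path, simplifyVector = FALSE)
  if (is.null(gj$features)) abort("GeoJSON file has no features.")
  cells <- grid_cells_tbl(meta$rows, meta$cols)
  cx <- meta$x_origin + (cells$col - 0.5) * meta$cell_size
  cy <- meta$y_origin - (cells$row - 0.5) * meta$cell_size
  sid <- rep(NA, nrow(cells))
  for (ft in gj$features) {
    id <- ft$properties$sector_id
    geom <- ft$geometry
    polys <- if (geom$type == "Polygon") list(geom$coordinates) else geom$coordinates
    for (poly in polys) {
      for (ring in poly) {
        rg <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
        # cheap bbox prefilter, then exact test
        cand <- which(cx >= min(rg[, 1]) & cx <= max(rg[, 1]) &
                      cy >= min(rg[, 2]) & cy <= max(rg[, 2]))
        for (k in cand) {
          if (point_in_ring(cx[k], cy[k], rg)) sid[k] <- id
        }
      }
    }
  }
  cells |> mutate(sector_id = sid) |> filter(!is.na(.data$sector_id)) |>
    select("sector_id", "row", "col")
}
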