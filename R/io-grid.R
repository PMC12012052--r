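#' Grid georeferencing metadata
#'
#' Raster convention used everywhere in the package: row 1 is the north
#' edge; the center of cell (r, c) lies at
#' `(x_origin + (c - 0.5) * cell_size, y_origin - (r - 0.5) * cell_size)`.
#'
#' @param rows,cols grid dimensions in cells.
#' @param x_origin,y_origin map coordinates of the north-west grid corner.
#' @param cell_size cell edge length in map units; must be positive.
#' @param nodata sentinel for missing cells; a large negative value that
#'   can never be a concentration.
#' @return A list of class `grid_meta`.
#' @export
grid_meta <- function(rows, cols, x_origin = 0, y_origin = rows * cell_size,
                      cell_size = 10, nodata = -9999) {
  if (cell_size <= 0) abort("`cell_size` must be positive.")
  if (nodata >= 0) abort("`nodata` must be negative so it is never a plausible concentration.")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 x_origin = x_origin, y_origin = y_origin,
                 cell_size = cell_size, nodata = nodata),
            class = "grid_meta")
}

#' Convert between long field tibbles and grid matrices
#'
#' `field_to_matrix()` extracts one pollutant/season layer as a matrix in
#' grid layout (row 1 = north); `matrix_to_field()` wraps a matrix as a
#' long field tibble with a `grid_meta` attribute.
#'
#' @param field long field tibble.
#' @param pollutant,season layer selectors (optional when the tibble
#'   holds a single layer).
#' @return `field_to_matrix()`: a numeric matrix; `matrix_to_field()`: a
#'   field tibble.
#' @export
field_to_matrix <- function(field, pollutant = NULL, season = NULL) {
  f <- field
  if (!is.null(pollutant)) f <- f[f$pollutant == pollutant, ]
  if (!is.null(season)) f <- f[f$season == season, ]
  if (nrow(f) == 0) abort("no cells match the requested pollutant/season.")
  rows <- max(f$row); cols <- max(f$col)
  m <- matrix(NA_real_, rows, cols)
  m[cbind(f$row, f$col)] <- f$conc
  m
}

#' @rdname field_to_matrix
#' @param m a numeric matrix in grid layout.
#' @param meta a [grid_meta()].
#' @export
matrix_to_field <- function(m, pollutant, season, meta) {
  tibble(pollutant = pollutant, season = season,
         row = rep(seq_len(nrow(m)), times = ncol(m)),
         col = rep(seq_len(ncol(m)), each = nrow(m)),
         conc = as.vector(m)) |>
    (\(x) { attr(x, "grid_meta") <- meta; x })()
}

write_ascii_grid <- function(m, path, meta, digits = 6) {
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", meta$x_origin),
    sprintf("yllcorner %.10g", meta$y_origin - nrow(m) * meta$cell_size),
    sprintf("cellsize %.10g", meta$cell_size),
    sprintf("NODATA_value %.10g", meta$nodata)
  )
  vals <- m
  vals[is.na(vals)] <- meta$nodata
  body <- apply(signif(vals, digits), 1, function(r) {
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort(sprintf("malformed ESRI ASCII grid header in '%s' (missing %s).",
                  path, paste(setdiff(need, names(hdr)), collapse = ", ")))
  }
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  rows <- as.integer(hdr$nrows); cols <- as.integer(hdr$ncols)
  if (length(vals) != rows * cols) {
    abort(sprintf("ASCII grid '%s' has %d values, expected %d.",
                  path, length(vals), rows * cols))
  }
  m <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  meta <- grid_meta(rows, cols,
                    x_origin = hdr$xllcorner,
                    y_origin = hdr$yllcorner + rows * hdr$cellsize,
                    cell_size = hdr$cellsize, nodata = nodata)
  list(values = m, meta = meta)
}

tiff_sidecar <- function(path) paste0(path, ".json")

# the tiff writer stores float samples on a [0, 1] scale; concentrations
# are min-max scaled on write and restored on read, with the scale and
# the NODATA cell list carried in the JSON sidecar
write_float_tiff <- function(m, path, meta) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write TIFF rasters; use .asc instead.")
  }
  na_idx <- which(is.na(m))
  fin <- m[is.finite(m)]
  vmin <- if (length(fin)) min(fin) else 0
  vmax <- if (length(fin)) max(fin) else 1
  span <- max(vmax - vmin, 1e-300)
  scaled <- (m - vmin) / span
  scaled[na_idx] <- 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  sidecar <- c(unclass(meta),
               list(vmin = vmin, vmax = vmax, na_cells = na_idx))
  jsonlite::write_json(sidecar, tiff_sidecar(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_float_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to read TIFF rasters.")
  }
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  sc <- tiff_sidecar(path)
  if (!file.exists(sc)) {
    abort(sprintf("missing georeferencing sidecar '%s'.", sc))
  }
  j <- jsonlite::read_json(sc, simplifyVector = TRUE)
  meta <- grid_meta(nrow(m), ncol(m), j$x_origin, j$y_origin, j$cell_size,
                    j$nodata)
  m <- m * (j$vmax - j$vmin) + j$vmin
  if (length(j$na_cells)) m[j$na_cells] <- NA_real_
  list(values = m, meta = meta)
}

#' Read a seasonal concentration field from disk
#'
#' Auto-detects the raster format from the extension: `.asc`/`.txt` is an
#' ESRI ASCII grid; `.tif`/`.tiff` is a single-band float TIFF whose
#' georeferencing lives in a `<file>.json` sidecar. Cells equal to the
#' declared NODATA value come back as `NA` and are excluded from every
#' downstream mean. Any other non-finite value is a hard error naming the
#' offending cell.
#'
#' @param path raster file path.
#' @param pollutant,season labels attached to the returned rows.
#' @return A field tibble (`pollutant`, `season`, `row`, `col`, `conc`)
#'   with a `grid_meta` attribute.
#' @seealso [write_field()]
#' @export
read_field <- function(path, pollutant, season) {
  if (!file.exists(path)) abort(sprintf("raster '%s' does not exist.", path))
  ext <- tolower(tools::file_ext(path))
  g <- switch(ext,
    asc = , txt = read_ascii_grid(path),
    tif = , tiff = read_float_tiff(path),
    abort(sprintf("unrecognised raster extension '.%s' (use .asc or .tif).", ext))
  )
  bad <- which(!is.finite(g$values) & !is.na(g$values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-finite value at cell (row %d, col %d) in '%s'.",
                  bad[1, 1], bad[1, 2], path))
  }
  matrix_to_field(g$values, pollutant, season, g$meta)
}

#' Write a seasonal concentration field to disk
#'
#' Counterpart of [read_field()]; format chosen by extension. ASCII grids
#' are written with `digits` significant digits and round-trip exactly at
#' that precision.
#'
#' @param field field tibble (or a plain matrix).
#' @param path output path (`.asc` or `.tif`).
#' @param pollutant,season which layer of `field` to write (ignored for a
#'   matrix input).
#' @param meta a [grid_meta()]; defaults to the field's attribute.
#' @param digits significant digits for ASCII output.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, pollutant = NULL, season = NULL,
                        meta = NULL, digits = 6) {
  if (is.matrix(field)) {
    m <- field
  } else {
    m <- field_to_matrix(field, pollutant, season)
    meta <- meta %||% attr(field, "grid_meta")
  }
  meta <- meta %||% grid_meta(nrow(m), ncol(m), cell_size = 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    asc = , txt = write_ascii_grid(m, path, meta, digits),
    tif = , tiff = write_float_tiff(m, path, meta),
    abort(sprintf("unrecognised raster extension '.%s' (use .asc or .tif).", ext))
  )
  invisible(path)
}

#' Check that a set of fields share one grid shape
#'
#' @param fields long field tibble covering several pollutant/season layers.
#' @return `fields` invisibly; errors if layers disagree in shape.
#' @export
validate_field_grid <- function(fields) {
  shp <- fields |>
    group_by(.data$pollutant, .data$season) |>
    summarise(rows = max(.data$row), cols = max(.data$col),
              n = dplyr::n(), .groups = "drop")
  if (nrow(distinct(shp, .data$rows, .data$cols, .data$n)) > 1) {
    abort("seasonal fields have mismatched grid shapes.")
  }
  invisible(fields)
}
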