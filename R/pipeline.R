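#' Assemble a pipeline run configuration
#'
#' A run is configured either from a synthetic region (`synthetic` =
#' arguments to [region_spec()]) or from input files (`inputs` = paths to
#' seasonal rasters, the sector attribute/membership CSVs and a road-mask
#' raster); exactly one of the two must be given. All seeds live in the
#' config and are echoed in the run manifest, so the manifest alone
#' reproduces a run.
#'
#' @param synthetic named list of [region_spec()] arguments, or `NULL`.
#' @param inputs named list with `fields` (a data frame or list of
#'   `path`/`pollutant`/`season` entries), `sectors_attr`,
#'   `sectors_membership` and `road_mask` paths, or `NULL`.
#' @param erf named list of [exposure_response()] objects; defaults to
#'   [default_erf()].
#' @param loess list with `span` and `degree`.
#' @param bootstrap list with `B` and `seed` for ratio CIs.
#' @param mc list with `n_iter` and `seed` for the PF Monte Carlo.
#' @param counterfactual `"guideline"` or `"zero"` (see
#'   [pf_with_uncertainty()]).
#' @param shares_weighted population-weight the seasonal shares.
#' @param seed master seed (used for the synthetic region when its spec
#'   does not set one).
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = list(), inputs = NULL,
                       erf = default_erf(),
                       loess = list(span = 0.75, degree = 1),
                       bootstrap = list(B = 1000, seed = 1L),
                       mc = list(n_iter = 10000, seed = 1L),
                       counterfactual = "guideline",
                       shares_weighted = TRUE,
                       seed = 1L) {
  if (!is.null(synthetic) && !is.null(inputs)) {
    abort("set exactly one of `synthetic` or `inputs`, not both.")
  }
  if (is.null(synthetic) && is.null(inputs)) {
    abort("set one of `synthetic` or `inputs`.")
  }
  structure(
    list(synthetic = synthetic, inputs = inputs, erf = erf, loess = loess,
         bootstrap = bootstrap, mc = mc, counterfactual = counterfactual,
         shares_weighted = shares_weighted, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` or `.json`). Top-level keys
#'   mirror the arguments of [run_config()]; `erf` entries are plain
#'   lists with `rr10`, `rr10_low`, `rr10_high`, `guideline`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort("config must be .yaml or .json.")
  )
  erf <- default_erf()
  if (!is.null(raw$erf)) {
    erf <- purrr::imap(raw$erf, function(e, p) {
      exposure_response(p, e$rr10, e$rr10_low, e$rr10_high, e$guideline)
    })
  }
  run_config(
    synthetic = raw$synthetic,
    inputs = raw$inputs,
    erf = erf,
    loess = raw$loess %||% list(span = 0.75, degree = 1),
    bootstrap = raw$bootstrap %||% list(B = 1000, seed = 1L),
    mc = raw$mc %||% list(n_iter = 10000, seed = 1L),
    counterfactual = raw$counterfactual %||% "guideline",
    shares_weighted = raw$shares_weighted %||% TRUE,
    seed = raw$seed %||% 1L
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    if (is.null(args$seed)) args$seed <- config$seed
    spec <- do.call(region_spec, args)
    reg <- simulate_region(spec)
    meta <- attr(reg$fields, "grid_meta")
    list(fields = reg$fields, sectors = reg$sectors, cells = reg$cells,
         road_cells = spec$road_cells, meta = meta, region = reg)
  } else {
    inp <- config$inputs
    ftab <- as.data.frame(do.call(rbind, lapply(inp$fields, as.data.frame)))
    fields <- purrr::pmap_dfr(ftab, function(path, pollutant, season) {
      read_field(path, pollutant, season)
    })
    validate_field_grid(fields)
    sec <- read_sectors(inp$sectors_attr, inp$sectors_membership)
    if (is.null(sec$cells)) abort("a cell-membership table is required.")
    if (!"landcover" %in% names(sec$cells)) {
      # membership tables carry no per-cell land cover: cells inherit
      # their sector's class
      sec$cells <- sec$cells |>
        inner_join(sec$sectors |> select("sector_id", "landcover"),
                   by = "sector_id")
    }
    rm <- read_field(inp$road_mask, "road", "mask")
    road_cells <- rm |> filter(.data$conc > 0) |> select("row", "col")
    meta <- attr(rm, "grid_meta")
    list(fields = fields, sectors = sec$sectors, cells = sec$cells,
         road_cells = road_cells, meta = meta, region = NULL)
  }
}

#' Run the full spatio-seasonal analysis pipeline
#'
#' Orchestrates every stage on one set of inputs: sector exposure
#' aggregation, summer/winter ratios (per sector, overall, by land cover
#' and by DEGURBA), distance-to-road concentration profiles, seasonal
#' contribution shares, preventable fractions with Monte Carlo CIs,
#' deprivation disparity curves and the car-ownership turning point.
#' Results are returned and, when `out_dir` is given, written as CSV/JSON
#' together with a manifest (config echo, seeds, package version) that
#' suffices to reproduce the run. All stages are deterministic given the
#' config seeds. A failing stage aborts with the stage name.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress per-stage progress messages.
#' @return A list of class `pipeline_result` with elements `exposure`,
#'   `sector_ratios`, `ratio_overall`, `ratio_landcover`, `ratio_degurba`,
#'   `distance_profiles`, `seasonal_shares`, `pf`, `disparity_curves`,
#'   `turning_point`, `manifest` (plus `region` for synthetic runs).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  inp <- run_stage("load", load_pipeline_inputs(config))
  say("load: %d sectors, %d cells, %d field layers",
      nrow(inp$sectors), nrow(inp$cells),
      nrow(distinct(inp$fields, .data$pollutant, .data$season)))

  exposure <- run_stage("aggregate", zonal_mean(inp$fields, inp$cells))
  say("aggregate: %d exposure rows", nrow(exposure))

  sector_ratios <- run_stage("ratios", sector_ratio(exposure))
  all_cells <- inp$cells |> mutate(stratum = "all")
  lc_cells <- inp$cells |> mutate(stratum = .data$landcover)
  dg_cells <- inp$cells |>
    inner_join(inp$sectors |> select("sector_id", "degurba"),
               by = "sector_id") |>
    mutate(stratum = as.character(.data$degurba))
  B <- config$bootstrap$B; bseed <- config$bootstrap$seed
  ratio_overall <- run_stage("ratios",
    stratified_ratio(inp$fields, all_cells, kind = "overall", B = B, seed = bseed))
  ratio_landcover <- run_stage("ratios",
    stratified_ratio(inp$fields, lc_cells, kind = "landcover", B = B, seed = bseed))
  ratio_degurba <- run_stage("ratios",
    stratified_ratio(inp$fields, dg_cells, kind = "degurba", B = B, seed = bseed))
  say("ratios: overall %d, landcover %d, degurba %d rows",
      nrow(ratio_overall), nrow(ratio_landcover), nrow(ratio_degurba))

  dist <- run_stage("distance", distance_transform(inp$road_cells, inp$meta))
  profiles <- run_stage("distance", {
    combos <- inp$fields |> distinct(.data$pollutant, .data$season) |>
      filter(.data$season %in% c("summer", "winter"))
    purrr::pmap_dfr(combos, function(pollutant, season) {
      pr <- distance_profile(inp$fields, dist, pollutant = pollutant,
                             season = season, span = config$loess$span,
                             degree = config$loess$degree)
      as_tibble(pr) |> mutate(pollutant = pollutant, season = season,
                              .before = 1)
    })
  })
  say("distance: %d profile rows", nrow(profiles))

  shares <- run_stage("shares", purrr::map_dfr(
    intersect(POLLUTANTS, unique(exposure$pollutant)),
    function(p) seasonal_shares(exposure, inp$sectors, p,
                                weighted = config$shares_weighted)))
  say("shares: winter share %s",
      paste(sprintf("%s %.1f%%", shares$pollutant[shares$season == "winter"],
                    100 * shares$share[shares$season == "winter"]),
            collapse = ", "))

  pf <- run_stage("hia", purrr::map_dfr(config$erf, function(er) {
    if (!er$pollutant %in% exposure$pollutant) return(NULL)
    pf_with_uncertainty(exposure, inp$sectors, er,
                        n_iter = config$mc$n_iter, seed = config$mc$seed,
                        counterfactual = config$counterfactual)
  }))
  say("hia: %d PF rows (%s counterfactual)", nrow(pf), config$counterfactual)

  curves <- run_stage("disparities",
    deprivation_curves(exposure, inp$sectors, span = config$loess$span,
                       degree = config$loess$degree))
  tp <- run_stage("disparities", {
    ok <- inp$sectors |>
      filter(is.finite(.data$mobiscore) & is.finite(.data$cars_per_household))
    if (nrow(ok) >= 30) {
      turning_point(ok, .data$mobiscore, .data$cars_per_household)
    } else {
      NULL
    }
  })
  if (!is.null(tp)) say("disparities: turning point %s",
                        if (tp$detected) sprintf("%.2f", tp$x_star) else "not detected")

  manifest <- list(
    package = "seasonair",
    version = as.character(utils::packageVersion("seasonair")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seeds = list(master = config$seed, bootstrap = bseed,
                 monte_carlo = config$mc$seed),
    counterfactual = config$counterfactual,
    loess = config$loess,
    bootstrap = list(B = B),
    mc = list(n_iter = config$mc$n_iter),
    erf = purrr::map(config$erf, unclass),
    synthetic = config$synthetic,
    inputs = config$inputs
  )

  res <- structure(
    list(exposure = exposure, sector_ratios = sector_ratios,
         ratio_overall = ratio_overall, ratio_landcover = ratio_landcover,
         ratio_degurba = ratio_degurba, distance_profiles = profiles,
         seasonal_shares = shares, pf = pf, disparity_curves = curves,
         turning_point = tp, manifest = manifest, region = inp$region),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write a pipeline result bundle to a directory
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) readr::write_csv(x, file.path(out_dir, name))
  wcsv(result$exposure, "exposure.csv")
  wcsv(result$sector_ratios, "sector_ratios.csv")
  wcsv(result$ratio_overall, "ratios_overall.csv")
  wcsv(result$ratio_landcover, "ratios_landcover.csv")
  wcsv(result$ratio_degurba, "ratios_degurba.csv")
  wcsv(result$distance_profiles, "distance_profiles.csv")
  wcsv(result$seasonal_shares, "seasonal_shares.csv")
  wcsv(as_tibble(result$pf), "pf.csv")
  wcsv(as_tibble(result$disparity_curves), "disparity_curves.csv")
  if (!is.null(result$turning_point)) {
    jsonlite::write_json(as.list(glance(result$turning_point)),
                         file.path(out_dir, "turning_point.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  # timestamp excluded from the manifest file so identical runs are
  # byte-identical on disk
  man <- result$manifest
  man$timestamp <- NULL
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$region)) {
    write_truth(result$region, file.path(out_dir, "truth.json"))
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  nat <- x$pf |> filter(.data$level == "national")
  for (i in seq_len(nrow(nat))) {
    cat(sprintf("  %s national PF %.2f%% [%.2f-%.2f]\n", nat$pollutant[i],
                100 * nat$pf[i], 100 * nat$pf_low[i], 100 * nat$pf_high[i]))
  }
  ws <- x$seasonal_shares |> filter(.data$season == "winter")
  cat(sprintf("  winter exposure shares: %s\n",
              paste(sprintf("%s %.1f%%", ws$pollutant, 100 * ws$share),
                    collapse = ", ")))
  if (!is.null(x$turning_point) && x$turning_point$detected) {
    cat(sprintf("  car-ownership turning point at score %.2f\n",
                x$turning_point$x_star))
  }
  invisible(x)
}
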