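#' Write and read the standard CSV interchange formats
#'
#' The pipeline exchanges four streams as plain CSV: the monthly index
#' (`year`, `month`, `value`), the gridded climate in long format (pixel
#' metadata and monthly values in separate files), child-level microdata,
#' and derived tables (exposures, teleconnection flags, estimates). A
#' structured JSON sidecar records every planted parameter of a synthetic
#' world so test harnesses can recover the ground truth.
#'
#' @param x object to write.
#' @param path file path.
#' @return `write_*` return the path invisibly; `read_*` return
#'   `data.table`s (or a `climate_grid`).
#' @name ensoanthro-io
NULL

#' @rdname ensoanthro-io
#' @export
write_nino_csv <- function(x, path) {
  data.table::fwrite(check_nino_series(x), path)
  invisible(path)
}

#' @rdname ensoanthro-io
#' @export
read_nino_csv <- function(path) check_nino_series(data.table::fread(path))

#' @rdname ensoanthro-io
#' @param meta_path,monthly_path paths for the pixel metadata and the long
#'   monthly values of a climate grid.
#' @export
write_grid_csv <- function(x, meta_path, monthly_path) {
  stopifnot(inherits(x, "climate_grid"))
  data.table::fwrite(x$meta, meta_path)
  data.table::fwrite(x$monthly, monthly_path)
  invisible(c(meta_path, monthly_path))
}

#' @rdname ensoanthro-io
#' @export
read_grid_csv <- function(meta_path, monthly_path) {
  structure(list(meta = data.table::fread(meta_path),
                 monthly = data.table::fread(monthly_path)),
            class = "climate_grid")
}

#' @rdname ensoanthro-io
#' @export
write_children_csv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path)
  invisible(path)
}

#' @rdname ensoanthro-io
#' @export
read_children_csv <- function(path) data.table::fread(path)

#' Write the ground-truth sidecar of a synthetic world
#'
#' Records the full configuration and every planted coefficient draw as
#' JSON so downstream test harnesses can compare estimates to truth
#' without re-running the generators.
#'
#' @param config a [world_config()].
#' @param effects a [world_effects()] list.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_truth_sidecar <- function(config, effects, path) {
  named_to_list <- function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else if (is.list(x)) lapply(x, named_to_list)
    else x
  }
  truth <- list(
    config = named_to_list(unclass(config)),
    effects = lapply(effects, function(x)
      if (data.table::is.data.table(x)) as.data.frame(x) else as.list(x)))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate the four input streams of a synthetic study
#'
#' Runs the whole generator chain: index, geography, gridded climate,
#' estimated teleconnection map, and child surveys. Outcomes are planted
#' using the TRUE (generator) positive-precipitation flags; the estimated
#' map from the simulated grid is returned alongside so analyses can use
#' it, making teleconnection misclassification part of any end-to-end
#' recovery exercise. Set `tele = "truth"` to skip the grid and correlation
#' stage (fast path for estimator-focused simulations).
#'
#' @param config a [world_config()].
#' @param tele `"estimated"` (default) or `"truth"`.
#' @return list of class `synthetic_world`: `config`, `nino`, `geography`,
#'   `grid` (unless `tele = "truth"`), `tele` (the map available to the
#'   analyst), `tele_truth`, `children`, `effects`.
#' @export
simulate_world <- function(config = world_config(),
                           tele = c("estimated", "truth")) {
  tele <- match.arg(tele)
  nino <- simulate_nino(config)
  geography <- world_geography(config)
  effects <- world_effects(config, geography)
  tele_truth <- truth_teleconnection_map(geography)
  grid <- NULL; tele_map <- tele_truth
  if (tele == "estimated") {
    grid <- simulate_climate_grid(nino, config, geography)
    tele_map <- teleconnection_map(grid, nino)
  }
  children <- simulate_surveys(nino, tele_truth, config, geography, effects)
  structure(list(config = config, nino = nino, geography = geography,
                 grid = grid, tele = tele_map, tele_truth = tele_truth,
                 children = children, effects = effects),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d countries, %d years, %s children (seed %d)\n",
              x$config$n_countries, x$config$n_years,
              format(nrow(x$children), big.mark = ","), x$config$seed))
  invisible(x)
}
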