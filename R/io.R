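## File I/O: CSV schemas for designs, layouts and inventories; JSON for
## niche configs, run configs and manifests. CSV dialect: UTF-8, comma
## delimited, header row, "." decimal separator.

write_csv_ <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a plot design CSV
#'
#' Columns: `plot_id, block, row, col, richness, myco_level, composition`
#' (species semicolon-delimited; `block/row/col` empty for unplaced
#' designs; grid coordinates 0-based, row-major).
#'
#' @param design a `plot_design` data.frame.
#' @param path file path.
#' @return `write_design_csv`: the path, invisibly. `read_design_csv`: the
#'   design.
#' @export
write_design_csv <- function(design, path) {
  cols <- c("plot_id", "block", "row", "col", "richness", "myco_level", "composition")
  for (cl in setdiff(cols, names(design))) design[[cl]] <- NA_integer_
  write_csv_(design[cols], path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "richness", "myco_level", "composition")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("design CSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  if (all(is.na(x$block))) x$block <- x$row <- x$col <- NULL
  class(x) <- c("plot_design", "data.frame")
  x
}

#' Write planting layouts as CSV
#'
#' One row per tree position: `plot_id, row, col, species_id, is_core`
#' (`is_core` as 0/1).
#'
#' @param design a `plot_design`.
#' @param path file path.
#' @param seed seed from which per-plot layout seeds are derived (use the
#'   simulation seed for consistency with [simulate_inventory()]).
#' @export
write_layout_csv <- function(design, path, seed = 1L) {
  seeds <- split_seed(seed, nrow(design))
  comps <- design_species(design)
  lay <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    l <- planting_layout(comps[[i]], seed = seeds[i])
    cbind(plot_id = design$plot_id[i], l)
  }))
  lay$is_core <- as.integer(lay$is_core)
  write_csv_(lay, path)
}

#' Write / read a tree inventory CSV
#'
#' Columns: `plot_id, row, col, species_id, is_core, year, diameter_cm,
#' alive` (`is_core`/`alive` as 0/1).
#'
#' @param inventory a `tree_inventory` data.frame.
#' @param path file path.
#' @export
write_inventory_csv <- function(inventory, path) {
  inv <- inventory
  inv$alive <- as.integer(inv$alive)
  if ("is_core" %in% names(inv)) inv$is_core <- as.integer(inv$is_core)
  write_csv_(inv, path)
}

#' @rdname write_inventory_csv
#' @export
read_inventory_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "row", "col", "species_id", "year", "diameter_cm", "alive")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("inventory CSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  x$alive <- as.logical(x$alive)
  if ("is_core" %in% names(x)) x$is_core <- as.logical(x$is_core)
  class(x) <- c("tree_inventory", "data.frame")
  x
}

#' Serialize / restore a niche configuration as JSON
#'
#' The JSON carries the full replay metadata: per-species disks and rates,
#' scenario, scenario parameters and seed.
#'
#' @param config a `niche_config`.
#' @param path file path.
#' @export
write_niche_json <- function(config, path) {
  stopifnot(inherits(config, "niche_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_niche_json
#' @export
read_niche_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$species <- as.data.frame(x$species, stringsAsFactors = FALSE)
  structure(x, class = "niche_config")
}

#' Default run configuration
#'
#' All pipeline knobs with their defaults: the master `seed`, design
#' parameters (pool size, grid dimensions), simulation parameters
#' (scenario, years, growth noise, mortality, quadrature resolution) and
#' analysis parameters (bootstrap replicates, richness scale).
#'
#' @param ... overrides, e.g. `default_config(seed = 7, scenario = "selection")`.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L, pool_size = 5L,
    blocks = 2L, grid_rows = 5L, grid_cols = 8L,
    scenario = "complementarity", years = 2L, noise_sd = 0.1,
    mortality_rate = 0.02, init_diameter = 1.0, init_sd = 0.1,
    resolution = 200L,
    year_from = 1, year_to = 2, core_only = TRUE,
    n_boot = 1000L, richness_scale = "log2")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Read a run configuration from JSON or YAML
#'
#' Accepts `.json` or `.yaml`/`.yml` (the latter requires the \pkg{yaml}
#' package). Unknown fields are rejected; missing fields fall back to
#' [default_config()] values, so a config round-trips losslessly.
#'
#' @param path config file.
#' @return named list as from [default_config()].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml, got: ", path)
  do.call(default_config, raw)
}

#' @rdname read_run_config
#' @param config config list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_manifest <- function(outdir, config, files) {
  manifest <- list(
    package = "mycodiv",
    version = as.character(utils::packageVersion("mycodiv")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
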