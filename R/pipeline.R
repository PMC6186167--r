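#' Run the full experiment pipeline
#'
#' Chains every stage: trait-based pool selection, design assembly, spatial
#' randomization, niche sampling, inventory simulation, basal-area yields,
#' additive partitioning, and treatment-level analysis. The master seed
#' fans out to per-stage child seeds via [split_seed()] (order: pools,
#' design, layout, niche, simulation, analysis), so any stage can be
#' replayed in isolation.
#'
#' @param config named list from [default_config()] / [read_run_config()].
#' @param outdir output directory (created if missing); when `NULL`, nothing
#'   is written and the results are only returned.
#' @param traits optional [trait_table()] (or path to its CSV). When absent,
#'   the bundled synthetic example table is used.
#' @return (invisibly) list with `pools`, `design`, `niche`, `inventory`,
#'   `yields`, `yield_table`, `partition`, `summaries`, `models`, `files`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL, traits = NULL) {
  if (is.character(traits)) traits <- read_trait_table(traits)
  if (is.null(traits))
    traits <- read_trait_table(system.file("extdata", "example_traits_synthetic.csv",
                                           package = "mycodiv", mustWork = TRUE))
  seeds <- split_seed(config$seed, 6L)

  pools <- select_pools(traits, pool_size = config$pool_size, seed = seeds[1L])
  design <- assemble_design(pools, seed = seeds[2L])
  design <- randomize_layout(design, blocks = config$blocks,
                             grid_rows = config$grid_rows,
                             grid_cols = config$grid_cols, seed = seeds[3L])
  niche <- sample_niche_config(pools, scenario = config$scenario, seed = seeds[4L])
  inventory <- simulate_inventory(design, niche, years = config$years,
                                  noise_sd = config$noise_sd,
                                  mortality_rate = config$mortality_rate,
                                  init_diameter = config$init_diameter,
                                  init_sd = config$init_sd,
                                  resolution = config$resolution,
                                  seed = seeds[5L])
  yields <- basal_area_increment(inventory, config$year_from, config$year_to,
                                 core_only = config$core_only)
  yt <- build_yield_table(yields, design)
  part <- partition_effects(yt)
  part$composition <- design$composition[match(part$plot_id, design$plot_id)]

  prod <- stats::aggregate(list(productivity = yields$yield),
                           list(plot_id = yields$plot_id), sum)
  di <- match(prod$plot_id, design$plot_id)
  prod$richness <- design$richness[di]
  prod$myco_level <- design$myco_level[di]
  prod$composition <- design$composition[di]

  summaries <- list(
    productivity = group_summary(prod, "productivity", n_boot = config$n_boot,
                                 seed = seeds[6L]),
    NE = group_summary(part, "NE", n_boot = config$n_boot, seed = seeds[6L] + 1L),
    CE = group_summary(part, "CE", n_boot = config$n_boot, seed = seeds[6L] + 2L),
    SE = group_summary(part, "SE", n_boot = config$n_boot, seed = seeds[6L] + 3L))
  models <- list(
    productivity = fit_mixed_model(prod, "productivity",
                                   richness_scale = config$richness_scale),
    NE = fit_mixed_model(part, "NE", richness_scale = config$richness_scale),
    CE = fit_mixed_model(part, "CE", richness_scale = config$richness_scale),
    SE = fit_mixed_model(part, "SE", richness_scale = config$richness_scale))

  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(outdir, f)
    write_run_config(config, fp("config.json"))
    jsonlite::write_json(unclass(pools)[c("amf_pool", "emf_pool",
                                          "objective_value", "q_amf", "q_emf")],
                         fp("pools.json"), auto_unbox = TRUE, digits = NA)
    write_design_csv(design, fp("design.csv"))
    write_layout_csv(design, fp("layout.csv"), seed = seeds[5L])
    write_niche_json(niche, fp("niche.json"))
    write_inventory_csv(inventory, fp("inventory.csv"))
    write_csv_(yields, fp("yields.csv"))
    write_csv_(part[c("plot_id", "richness", "myco_level", "NE", "CE", "SE")],
               fp("partition.csv"))
    write_csv_(do.call(rbind, lapply(names(summaries), function(nm)
      cbind(response = nm, summaries[[nm]]))), fp("group_summaries.csv"))
    jsonlite::write_json(
      lapply(models, function(m)
        list(coefficients = m$coefficients, varcomp = m$varcomp,
             singular = m$singular)),
      fp("models.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files <- fp(c("config.json", "pools.json", "design.csv", "layout.csv",
                  "niche.json", "inventory.csv", "yields.csv", "partition.csv",
                  "group_summaries.csv", "models.json"))
    write_manifest(outdir, config, files)
  }
  invisible(list(pools = pools, design = design, niche = niche,
                 inventory = inventory, yields = yields, yield_table = yt,
                 partition = part, summaries = summaries, models = models,
                 files = files))
}
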