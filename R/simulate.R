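#' Simulate a tree-level diameter inventory
#'
#' The measurement layer of the synthetic-data generator. For every plot the
#' community's per-species resource capture is computed with
#' [community_capture()]; each species' capture is divided by its planted
#' density (`140 / richness` trees) to give a per-capita share, and each
#' living tree grows
#'
#' \deqn{\Delta d = \mathrm{rate}_i \cdot \mathrm{share}_i \cdot e^{\varepsilon},
#'       \quad \varepsilon \sim N(0, \mathrm{noise\_sd}^2)}
#'
#' centimetres of stem diameter per year (multiplicative lognormal noise,
#' i.i.d. per tree-year, so diameters stay positive and increments are
#' right-skewed). Initial diameters at planting (year 0) are lognormal with
#' median `init_diameter` cm. Every tree dies independently with probability
#' `mortality_rate` per year; a dead tree stops growing, keeps its last
#' diameter and is flagged `alive = FALSE` from that year on.
#'
#' @param design a placed or unplaced `plot_design`; planting layouts are
#'   generated per plot with [planting_layout()] under child seeds.
#' @param config a `niche_config` covering all design species.
#' @param years number of growth years (records cover years `0..years`).
#' @param noise_sd lognormal growth noise SD (default 0.1).
#' @param mortality_rate annual death probability in `[0, 1)` (default 0.02).
#' @param init_diameter median planting diameter, cm at 5 cm stem height.
#' @param init_sd lognormal SD of the planting diameter (default 0.1).
#' @param resolution capture quadrature resolution (default 200).
#' @param seed integer seed; everything downstream is deterministic given it.
#' @return data.frame of class `tree_inventory`: `plot_id`, `row`, `col`,
#'   `species_id`, `is_core`, `year`, `diameter_cm`, `alive`.
#' @export
simulate_inventory <- function(design, config, years = 2L, noise_sd = 0.1,
                               mortality_rate = 0.02, init_diameter = 1.0,
                               init_sd = 0.1, resolution = 200L, seed = 1L) {
  stopifnot(inherits(config, "niche_config"), years >= 1L, noise_sd >= 0,
            mortality_rate >= 0, mortality_rate < 1, init_diameter > 0,
            init_sd >= 0)
  years <- as.integer(years)
  comps <- design_species(design)
  rates <- stats::setNames(config$species$rate, config$species$species_id)
  unknown <- setdiff(unique(unlist(comps)), names(rates))
  if (length(unknown) > 0L)
    stop("design species missing from niche config: ",
         paste(unknown, collapse = ", "))

  # capture is a property of the composition only: cache per unique set
  cap_cache <- new.env(parent = emptyenv())
  capture_of <- function(sp) {
    key <- paste(sp, collapse = ";")
    if (is.null(cap_cache[[key]]))
      cap_cache[[key]] <- community_capture(config, sp, resolution)$capture
    cap_cache[[key]]
  }

  seeds <- split_seed(seed, nrow(design))
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    sp <- comps[[i]]
    n_per_species <- 140L / design$richness[i]
    share <- capture_of(sp) / n_per_species
    lay <- planting_layout(sp, seed = seeds[i])
    n <- nrow(lay)
    tree_rate <- rates[lay$species_id] * share[lay$species_id]

    sim <- with_seed(seeds[i] + 1L, {
      d0 <- init_diameter * exp(stats::rnorm(n, 0, init_sd))
      inc <- matrix(tree_rate, n, years) *
        exp(matrix(stats::rnorm(n * years, 0, noise_sd), n, years))
      dies <- matrix(stats::runif(n * years) < mortality_rate, n, years)
      list(d0 = d0, inc = inc, dies = dies)
    })
    # alive[, y] = alive at (the end of) year y; death in year y cancels
    # that year's growth and freezes the diameter
    alive <- t(apply(!sim$dies, 1L, cumprod)) == 1
    if (years == 1L) alive <- matrix(alive, ncol = 1L)
    diam <- sim$d0 + t(apply(sim$inc * alive, 1L, cumsum))
    if (years == 1L) diam <- matrix(diam, ncol = 1L)

    out[[i]] <- data.frame(
      plot_id = design$plot_id[i],
      row = rep(lay$row, years + 1L),
      col = rep(lay$col, years + 1L),
      species_id = rep(lay$species_id, years + 1L),
      is_core = rep(lay$is_core, years + 1L),
      year = rep(0:years, each = n),
      diameter_cm = c(sim$d0, diam),
      alive = c(rep(TRUE, n), alive),
      stringsAsFactors = FALSE)
  }
  inv <- do.call(rbind, out)
  rownames(inv) <- NULL
  class(inv) <- c("tree_inventory", "data.frame")
  inv
}
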