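## Resource-niche model: every species occupies a disk in a 2-D unit
## resource space (axes interpretable as, e.g., phosphorus and nitrogen
## supply). A community captures the union of its members' disks; resource
## cells covered by several species are split equally among them. Captured
## resource drives diameter growth in simulate_inventory().

rect <- function(x0, y0, x1, y1) c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)

#' Sample a per-species niche configuration
#'
#' Draws niche disks (center, radius) and intrinsic growth rates for all
#' pool species under one of three archetypal scenarios:
#'
#' * `"complementarity"` — disjoint between-type niches, equal rates: AMF
#'   centers are drawn uniformly in `amf_region` (the phosphorus-rich end of
#'   the space, reflecting the more efficient phosphorus supply by AMF) and
#'   EMF centers in `emf_region`; the default regions are separated by twice
#'   the default radius, so between-type disks never overlap.
#' * `"selection"` — nested niches, one dominant rate: all disks are
#'   concentric; one dominant species gets a larger disk
#'   (`dominant_radius`) and a rate advantage (`dominant_rate_advantage`),
#'   so mixtures are driven by that species' dominance.
#' * `"neutral"` — identical niches, equal rates: all species share one
#'   disk, so mixtures behave exactly like monocultures.
#'
#' @param pools a `species_pools` object.
#' @param scenario one of `"complementarity"`, `"selection"`, `"neutral"`.
#' @param seed integer seed (center draws are deterministic given it).
#' @param radius niche disk radius for ordinary species (resource-space
#'   units in `(0, 0.5]`, default 0.10).
#' @param base_rate intrinsic growth rate: cm diameter increment per unit
#'   per-capita captured resource per year (default 2500, which puts annual
#'   increments of a 140-tree monoculture near 0.5-1 cm).
#' @param amf_rate_advantage multiplier on AMF rates (default 1 = none).
#' @param dominant_species label of the dominant species for the selection
#'   scenario (default: lexicographically first pool species).
#' @param dominant_rate_advantage,dominant_radius dominance knobs for the
#'   selection scenario.
#' @param amf_region,emf_region axis-aligned rectangles `c(x0, y0, x1, y1)`
#'   inside the unit box from which centers are drawn.
#' @return object of class `niche_config`: list with `species` (data.frame:
#'   `species_id`, `mycorrhizal_type`, `cx`, `cy`, `radius`, `rate`),
#'   `scenario`, `seed`, and the scenario parameters.
#' @export
sample_niche_config <- function(pools, scenario = c("complementarity", "selection", "neutral"),
                                seed = 1L, radius = 0.10, base_rate = 2500,
                                amf_rate_advantage = 1,
                                dominant_species = NULL,
                                dominant_rate_advantage = 8,
                                dominant_radius = 0.35,
                                amf_region = rect(0.05, 0.05, 0.40, 0.95),
                                emf_region = rect(0.60, 0.05, 0.95, 0.95)) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(pools, "species_pools"), radius > 0, radius <= 0.5,
            base_rate > 0)
  chk_region <- function(rg) stopifnot(length(rg) == 4, all(rg >= 0), all(rg <= 1),
                                       rg[3] >= rg[1], rg[4] >= rg[2])
  chk_region(amf_region); chk_region(emf_region)
  sp <- sort(c(pools$amf_pool, pools$emf_pool))
  myco <- ifelse(sp %in% pools$amf_pool, "AMF", "EMF")
  n <- length(sp)
  runif_in <- function(k, rg) cbind(stats::runif(k, rg[1], rg[3]),
                                    stats::runif(k, rg[2], rg[4]))
  cfg <- with_seed(seed, {
    if (scenario == "complementarity") {
      centers <- matrix(NA_real_, n, 2L)
      centers[myco == "AMF", ] <- runif_in(sum(myco == "AMF"), amf_region)
      centers[myco == "EMF", ] <- runif_in(sum(myco == "EMF"), emf_region)
      data.frame(species_id = sp, mycorrhizal_type = myco,
                 cx = centers[, 1L], cy = centers[, 2L],
                 radius = radius,
                 rate = base_rate * ifelse(myco == "AMF", amf_rate_advantage, 1),
                 stringsAsFactors = FALSE)
    } else if (scenario == "selection") {
      dom <- dominant_species %||% sp[1L]
      if (!dom %in% sp) stop("dominant_species not in the pools")
      data.frame(species_id = sp, mycorrhizal_type = myco,
                 cx = 0.5, cy = 0.5,
                 radius = ifelse(sp == dom, dominant_radius, radius),
                 rate = base_rate * ifelse(sp == dom, dominant_rate_advantage, 1),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(species_id = sp, mycorrhizal_type = myco,
                 cx = 0.5, cy = 0.5, radius = radius, rate = base_rate,
                 stringsAsFactors = FALSE)
    }
  })
  structure(list(species = cfg, scenario = scenario, seed = as.integer(seed),
                 params = list(radius = radius, base_rate = base_rate,
                               amf_rate_advantage = amf_rate_advantage,
                               dominant_rate_advantage = dominant_rate_advantage,
                               dominant_radius = dominant_radius,
                               amf_region = as.numeric(amf_region),
                               emf_region = as.numeric(emf_region))),
            class = "niche_config")
}

#' Per-species resource capture of a community
#'
#' Discretizes the unit resource box into `resolution^2` cells. A cell
#' covered by `k >= 1` member disks contributes `1 / (resolution^2 * k)` to
#' each covering species — contested resource is split equally. The union
#' of covered cells is the community's total exploitation of the resource
#' space.
#'
#' @param config a `niche_config`.
#' @param species character vector of community members (non-empty, all in
#'   the config).
#' @param resolution grid cells per axis (>= 50; default 200).
#' @return list with `capture` (named per-species vector), `union_area`
#'   (total exploited fraction of the box) and `resolution`.
#' @export
community_capture <- function(config, species, resolution = 200L) {
  stopifnot(inherits(config, "niche_config"), resolution >= 50L)
  species <- unique(as.character(species))
  if (length(species) == 0L) stop("empty species set")
  cs <- config$species
  if (!all(species %in% cs$species_id))
    stop("unknown species: ", paste(setdiff(species, cs$species_id), collapse = ", "))
  idx <- match(species, cs$species_id)
  g <- (seq_len(resolution) - 0.5) / resolution
  px <- rep(g, times = resolution)
  py <- rep(g, each = resolution)
  inside <- vapply(idx, function(i)
    (px - cs$cx[i])^2 + (py - cs$cy[i])^2 <= cs$radius[i]^2,
    logical(length(px)))
  k <- rowSums(inside)
  cell <- 1 / resolution^2
  covered <- k > 0
  w <- numeric(length(k))
  w[covered] <- cell / k[covered]
  capture <- colSums(inside * w)
  names(capture) <- species
  list(capture = capture, union_area = sum(covered) * cell,
       resolution = as.integer(resolution))
}
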