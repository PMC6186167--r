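#' Basal-area increment per plot and species
#'
#' Tree productivity is the mean annual increment in stem basal area.
#' Per tree, `BA = pi * (diameter_cm / 200)^2` square metres; a plot x
#' species yield is the summed increment `BA(year_to) - BA(year_from)` over
#' trees alive at `year_to`, divided by the elapsed time
#' `year_to - year_from` (fractional years supported). Trees dead by
#' `year_to` contribute zero increment; a living tree with a negative
#' increment is kept with a warning.
#'
#' @param inventory a `tree_inventory` data.frame.
#' @param year_from,year_to measurement years (both present in the data).
#' @param core_only if `TRUE` (default) only core-area trees are used,
#'   mirroring the field protocol of measuring the central 64 trees.
#' @return data.frame with `plot_id`, `species_id`, `yield` (m^2 basal area
#'   per year).
#' @export
#' @examples
#' inv <- data.frame(plot_id = "p", row = 0, col = 0, species_id = "s",
#'                   is_core = TRUE, year = c(1, 2),
#'                   diameter_cm = c(2, 4), alive = TRUE)
#' basal_area_increment(inv, 1, 2)$yield  # pi * (0.02^2 - 0.01^2)
basal_area_increment <- function(inventory, year_from = 1, year_to = 2,
                                 core_only = TRUE) {
  stopifnot(year_to > year_from)
  if (!all(c(year_from, year_to) %in% inventory$year))
    stop("inventory lacks year ", setdiff(c(year_from, year_to), inventory$year)[1L])
  inv <- inventory[inventory$year %in% c(year_from, year_to), , drop = FALSE]
  if (core_only && "is_core" %in% names(inv)) inv <- inv[inv$is_core, , drop = FALSE]
  key <- paste(inv$plot_id, inv$row, inv$col, sep = "\r")
  a <- inv[inv$year == year_from, ]
  b <- inv[inv$year == year_to, ]
  m <- match(paste(a$plot_id, a$row, a$col, sep = "\r"),
             paste(b$plot_id, b$row, b$col, sep = "\r"))
  if (anyNA(m)) stop("trees present in year_from but missing in year_to")
  b <- b[m, ]
  ba <- function(d_cm) pi * (d_cm / 200)^2
  inc <- (ba(b$diameter_cm) - ba(a$diameter_cm)) / (year_to - year_from)
  inc[!b$alive] <- 0
  if (any(inc < 0 & b$alive))
    warning(sum(inc < 0 & b$alive), " living tree(s) with negative basal-area",
            " increment; kept")
  out <- stats::aggregate(list(yield = inc),
                          list(plot_id = a$plot_id, species_id = a$species_id),
                          sum)
  out[order(out$plot_id, out$species_id), , drop = FALSE] |>
    (\(x) { rownames(x) <- NULL; x })()
}

#' Build the yield table for additive partitioning
#'
#' Joins mixture yields with their monoculture references. For every species
#' the reference `M_i` is the mean plot-level yield over that species'
#' monoculture plots; the expected relative yield `RY_E,i = 1/N` reflects
#' equal planting proportions. Mixture plots containing a species without a
#' positive monoculture reference are excluded with a message.
#'
#' @param yields output of [basal_area_increment()].
#' @param design the `plot_design` the yields belong to.
#' @return data.frame of class `yield_table` with columns `plot_id`,
#'   `richness`, `myco_level`, `species_id`, `Y_O`, `M`, `RY_E`, `N`.
#' @export
build_yield_table <- function(yields, design) {
  di <- match(yields$plot_id, design$plot_id)
  if (anyNA(di)) stop("yields contain plots absent from the design")
  yields$richness <- design$richness[di]
  yields$myco_level <- design$myco_level[di]

  mono <- yields[yields$richness == 1L, , drop = FALSE]
  if (nrow(mono) == 0L) stop("no monoculture plots: cannot build references")
  M <- tapply(mono$yield, mono$species_id, mean)

  mix <- yields[yields$richness > 1L, , drop = FALSE]
  keep <- rep(TRUE, nrow(mix))
  for (p in unique(mix$plot_id)) {
    sp <- mix$species_id[mix$plot_id == p]
    bad <- !(sp %in% names(M)) | M[sp] <= 0
    if (any(bad)) {
      message("excluding plot ", p, ": no positive monoculture reference for ",
              paste(sp[bad], collapse = ", "))
      keep[mix$plot_id == p] <- FALSE
    }
  }
  mix <- mix[keep, , drop = FALSE]
  out <- data.frame(plot_id = mix$plot_id, richness = mix$richness,
                    myco_level = mix$myco_level, species_id = mix$species_id,
                    Y_O = mix$yield, M = as.numeric(M[mix$species_id]),
                    RY_E = 1 / mix$richness, N = mix$richness,
                    stringsAsFactors = FALSE)
  class(out) <- c("yield_table", "data.frame")
  out
}

#' Additive partition of the net biodiversity effect
#'
#' The two-way additive partition of mixture overyielding: with observed
#' relative yields `RY_O,i = Y_O,i / M_i` and deviations
#' `dRY_i = RY_O,i - RY_E,i`,
#'
#' \deqn{NE = \sum_i Y_{O,i} - \sum_i RY_{E,i} M_i,\quad
#'       CE = N\,\overline{dRY}\,\overline{M},\quad
#'       SE = N\,\mathrm{cov}(dRY, M),}
#'
#' where the covariance uses the population convention (divide by `N`), so
#' the identity `NE = CE + SE` is exact.
#'
#' @param Y_O observed per-species mixture yields (m^2).
#' @param M monoculture references (m^2, positive).
#' @param RY_E expected relative yields (default equal proportions `1/N`).
#' @return list with `NE`, `CE`, `SE`, `dRY`, `mean_dRY`, `mean_M`.
#' @export
#' @examples
#' partition(Y_O = c(6, 12), M = c(10, 20))  # NE = 3, CE = 3, SE = 0
partition <- function(Y_O, M, RY_E = rep(1 / length(Y_O), length(Y_O))) {
  n <- length(Y_O)
  stopifnot(n >= 1, length(M) == n, length(RY_E) == n, all(M > 0),
            all(Y_O >= 0))
  if (abs(sum(RY_E) - 1) > 1e-9) stop("expected relative yields must sum to 1")
  ry_o <- Y_O / M
  d_ry <- ry_o - RY_E
  ne <- sum(Y_O) - sum(RY_E * M)
  ce <- n * mean(d_ry) * mean(M)
  se <- n * (mean(d_ry * M) - mean(d_ry) * mean(M))  # population covariance
  list(NE = ne, CE = ce, SE = se, dRY = d_ry,
       mean_dRY = mean(d_ry), mean_M = mean(M))
}

#' Partition every mixture plot of a yield table
#'
#' @param yt a `yield_table` from [build_yield_table()].
#' @return data.frame of class `partition_result`: `plot_id`, `richness`,
#'   `myco_level`, `NE`, `CE`, `SE`, `mean_dRY`, `mean_M` (m^2 basal-area
#'   increment per year).
#' @export
partition_effects <- function(yt) {
  stopifnot(nrow(yt) > 0L)
  res <- lapply(split(seq_len(nrow(yt)), yt$plot_id), function(ix) {
    p <- partition(yt$Y_O[ix], yt$M[ix], yt$RY_E[ix])
    data.frame(plot_id = yt$plot_id[ix[1L]], richness = yt$richness[ix[1L]],
               myco_level = yt$myco_level[ix[1L]],
               NE = p$NE, CE = p$CE, SE = p$SE,
               mean_dRY = p$mean_dRY, mean_M = p$mean_M,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("partition_result", "data.frame")
  out
}
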