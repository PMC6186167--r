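#' The valid treatment cells
#'
#' Treatments cross species richness (1, 2, 4) with mycorrhizal level
#' (AMF, EMF, Both). A one-species plot necessarily has a single mycorrhizal
#' type, so the (1, Both) cell does not exist: 8 valid treatments remain.
#'
#' @return data.frame with columns `richness` (integer) and `myco_level`
#'   (character), 8 rows.
#' @export
valid_treatments <- function() {
  g <- expand.grid(richness = c(1L, 2L, 4L),
                   myco_level = c("AMF", "EMF", "Both"),
                   stringsAsFactors = FALSE)
  g <- g[!(g$richness == 1L & g$myco_level == "Both"), ]
  rownames(g) <- NULL
  g
}

treatment_label <- function(richness, myco_level) paste0(richness, "_", myco_level)

#' Enumerate all species compositions for a treatment
#'
#' Within-type treatments use all richness-subsets of the matching pool.
#' "Both" treatments are constrained to an equal split across mycorrhizal
#' types (1 AMF + 1 EMF at richness 2; 2 + 2 at richness 4), the only split
#' under which five-species pools yield 25 two-species and 100 four-species
#' mixed combinations.
#'
#' @param pools a `species_pools` object.
#' @param richness 1, 2 or 4.
#' @param myco_level "AMF", "EMF" or "Both".
#' @return list of sorted character vectors (one per composition).
#' @export
#' @examples
#' p <- species_pools(paste0("A", 1:5), paste0("E", 1:5))
#' length(enumerate_compositions(p, 2, "Both"))  # 25
enumerate_compositions <- function(pools, richness, myco_level) {
  stopifnot(inherits(pools, "species_pools"))
  vt <- valid_treatments()
  if (!any(vt$richness == richness & vt$myco_level == myco_level))
    stop("invalid treatment: richness ", richness, ", myco_level ", myco_level)
  subsets <- function(x, k) {
    if (k == length(x)) return(list(sort(x)))
    lapply(asplit(utils::combn(sort(x), k), 2L), as.character)
  }
  if (myco_level == "AMF") return(subsets(pools$amf_pool, richness))
  if (myco_level == "EMF") return(subsets(pools$emf_pool, richness))
  half <- richness / 2L
  a <- subsets(pools$amf_pool, half)
  e <- subsets(pools$emf_pool, half)
  out <- vector("list", length(a) * length(e))
  k <- 0L
  for (i in seq_along(a)) for (j in seq_along(e)) {
    k <- k + 1L
    out[[k]] <- sort(c(a[[i]], e[[j]]))
  }
  out
}

#' Select a species-balanced subset of compositions
#'
#' Chooses exactly `k` compositions such that every eligible species occurs
#' the same number of times `t = k * richness / S` (S = number of distinct
#' species across the candidate compositions). Uses seeded randomized
#' backtracking over compositions, pruning any partial choice in which a
#' species already exceeds its target; deterministic for a fixed seed.
#'
#' @param compositions list of equal-length species vectors
#'   (from [enumerate_compositions()]).
#' @param k number of compositions to keep.
#' @param seed integer seed.
#' @param max_restarts restarts before giving up.
#' @return list of `k` compositions.
#' @export
select_balanced_subset <- function(compositions, k, seed = 1L, max_restarts = 100L) {
  stopifnot(length(compositions) >= 1, k >= 1, k <= length(compositions))
  richness <- length(compositions[[1L]])
  if (any(lengths(compositions) != richness))
    stop("compositions must all have the same richness")
  species <- sort(unique(unlist(compositions)))
  s <- length(species)
  target <- k * richness / s
  if (target != round(target))
    stop("balanced subset infeasible: occurrence target ", k, "*", richness,
         "/", s, " = ", signif(target, 4), " is not an integer")
  target <- as.integer(round(target))
  if (k == length(compositions)) return(compositions)

  memb <- vapply(compositions, function(cp) species %in% cp, logical(s))
  found <- NULL
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      ord <- sample(length(compositions))
      counts <- integer(s)
      chosen <- integer(0)
      rec <- function(pos, counts, chosen) {
        if (length(chosen) == k)
          return(if (sum(counts) == k * richness && all(counts == target)) chosen else NULL)
        if (pos > length(ord)) return(NULL)
        # feasibility: remaining picks must be able to fill every deficit
        remaining <- k - length(chosen)
        if (length(ord) - pos + 1L < remaining) return(NULL)
        if (any(target - counts > remaining)) return(NULL)
        idx <- ord[pos]
        cnew <- counts + memb[, idx]
        if (all(cnew <= target)) {
          r <- rec(pos + 1L, cnew, c(chosen, idx))
          if (!is.null(r)) return(r)
        }
        rec(pos + 1L, counts, chosen)
      }
      res <- rec(1L, counts, chosen)
      if (!is.null(res)) { found <- res; break }
    }
  })
  if (is.null(found))
    stop("no balanced subset found within ", max_restarts, " restarts")
  compositions[sort(found)]
}

default_replication_rules <- function() {
  list(mono_reps = 2L, two_within = "all", two_both_k = 10L,
       four_within_reps = 2L, four_both_k = 10L)
}

#' Assemble the full plot list (unplaced)
#'
#' Applies the standard replication rules to five-species AMF and EMF pools:
#' every monoculture twice (20 plots); all 10 two-species combinations within
#' each type once; a balanced subset of 10 of the 25 mixed two-species
#' combinations; all 5 four-species combinations within each type twice; and
#' a balanced subset of 10 of the 100 mixed four-species combinations —
#' 80 plots in total, with every species occurring equally often in every
#' treatment cell. Plot ids are assigned in a canonical treatment order and
#' are stable for a fixed seed.
#'
#' @param pools a `species_pools` object with 5 species per type.
#' @param seed integer seed (drives the balanced-subset searches).
#' @param rules replication rules, see `default_replication_rules()`.
#' @return data.frame of class `plot_design` with columns `plot_id`,
#'   `richness`, `myco_level`, `composition` (semicolon-joined sorted
#'   species labels).
#' @export
assemble_design <- function(pools, seed = 1L, rules = default_replication_rules()) {
  stopifnot(inherits(pools, "species_pools"))
  if (length(pools$amf_pool) != 5L || length(pools$emf_pool) != 5L)
    stop("replication rules assume pools of exactly 5 species per type")
  seeds <- split_seed(seed, 2L)
  rows <- list()
  add <- function(richness, myco, comps, reps = 1L) {
    for (cp in comps) for (r in seq_len(reps)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        richness = as.integer(richness), myco_level = myco,
        composition = paste(sort(cp), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  for (sp in sort(c(pools$amf_pool, pools$emf_pool))) {
    myco <- if (sp %in% pools$amf_pool) "AMF" else "EMF"
    add(1L, myco, list(sp), rules$mono_reps)
  }
  add(2L, "AMF", enumerate_compositions(pools, 2L, "AMF"))
  add(2L, "EMF", enumerate_compositions(pools, 2L, "EMF"))
  add(2L, "Both", select_balanced_subset(
    enumerate_compositions(pools, 2L, "Both"), rules$two_both_k, seed = seeds[1L]))
  add(4L, "AMF", enumerate_compositions(pools, 4L, "AMF"), rules$four_within_reps)
  add(4L, "EMF", enumerate_compositions(pools, 4L, "EMF"), rules$four_within_reps)
  add(4L, "Both", select_balanced_subset(
    enumerate_compositions(pools, 4L, "Both"), rules$four_both_k, seed = seeds[2L]))
  design <- do.call(rbind, rows)
  design <- cbind(plot_id = sprintf("P%03d", seq_len(nrow(design))), design,
                  stringsAsFactors = FALSE)
  class(design) <- c("plot_design", "data.frame")
  design
}

design_species <- function(design) {
  lapply(strsplit(design$composition, ";", fixed = TRUE), sort)
}

#' Species occurrence counts per treatment cell
#'
#' Diagnostic/checker for the design-wide balance property: within every
#' treatment cell each eligible species should occur equally often.
#'
#' @param design a `plot_design` data.frame.
#' @return data.frame with `richness`, `myco_level`, `species`, `n_plots`.
#' @export
species_occurrence <- function(design) {
  sp <- design_species(design)
  long <- data.frame(
    richness = rep(design$richness, lengths(sp)),
    myco_level = rep(design$myco_level, lengths(sp)),
    species = unlist(sp), stringsAsFactors = FALSE)
  out <- stats::aggregate(list(n_plots = rep(1L, nrow(long))),
                          long[c("richness", "myco_level", "species")], sum)
  out[order(out$richness, out$myco_level, out$species), , drop = FALSE]
}
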