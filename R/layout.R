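## Spatial randomization of plots onto block grids, plus the independent
## constraint checker and the within-plot planting pattern.

moore_neighbors <- function(r, c, nr, nc) {
  dr <- rep(-1:1, each = 3L); dc <- rep(-1:1, times = 3L)
  keep <- !(dr == 0L & dc == 0L)
  rr <- r + dr[keep]; cc <- c + dc[keep]
  ok <- rr >= 0L & rr < nr & cc >= 0L & cc < nc
  cbind(row = rr[ok], col = cc[ok])
}

#' Check spatial layout constraints of a placed design
#'
#' Independent validator for the two randomization preconditions, applied
#' within each block on its grid (8-cell Moore neighborhoods, 0-based
#' coordinates):
#'
#' * c1 — no two plots of the same treatment are adjacent (orthogonally or
#'   diagonally);
#' * c2 — among the up-to-8 plots surrounding any focal plot, no treatment
#'   appears more than twice.
#'
#' @param design a placed `plot_design` (columns `block`, `row`, `col`,
#'   `richness`, `myco_level`).
#' @return list with `ok` (logical) and `violations` (data.frame with
#'   `block`, `row`, `col`, `constraint`, `detail`).
#' @export
check_layout <- function(design) {
  need <- c("block", "row", "col", "richness", "myco_level")
  if (!all(need %in% names(design))) stop("design is not placed (missing block/row/col)")
  viol <- list()
  push <- function(b, r, c, cons, detail)
    viol[[length(viol) + 1L]] <<- data.frame(block = b, row = r, col = c,
                                             constraint = cons, detail = detail,
                                             stringsAsFactors = FALSE)
  trt <- treatment_label(design$richness, design$myco_level)
  for (b in sort(unique(design$block))) {
    sel <- design$block == b
    key <- paste(design$row[sel], design$col[sel])
    if (anyDuplicated(key))
      push(b, NA_integer_, NA_integer_, "unique-cell", "duplicated grid cell")
    nr <- max(design$row[sel]) + 1L; nc <- max(design$col[sel]) + 1L
    grid <- matrix(NA_character_, nr, nc)
    grid[cbind(design$row[sel] + 1L, design$col[sel] + 1L)] <- trt[sel]
    for (i in which(sel)) {
      nb <- moore_neighbors(design$row[i], design$col[i], nr, nc)
      nbt <- grid[cbind(nb[, 1L] + 1L, nb[, 2L] + 1L)]
      nbt <- nbt[!is.na(nbt)]
      if (any(nbt == trt[i]))
        push(b, design$row[i], design$col[i], "c1",
             paste0("treatment ", trt[i], " adjacent to itself"))
      tab <- table(nbt)
      if (any(tab > 2L))
        push(b, design$row[i], design$col[i], "c2",
             paste0("treatment ", names(tab)[which.max(tab)], " occurs ",
                    max(tab), "x in neighborhood"))
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(block = integer(), row = integer(), col = integer(),
               constraint = character(), detail = character())
  list(ok = nrow(violations) == 0L, violations = violations)
}

# Moore adjacency list for an nr x nc grid, cells numbered row-major
# (1-based). Cached per grid dimension.
.nbr_cache <- new.env(parent = emptyenv())
neighbor_list <- function(nr, nc) {
  key <- paste(nr, nc)
  if (!is.null(.nbr_cache[[key]])) return(.nbr_cache[[key]])
  nl <- vector("list", nr * nc)
  for (r in 0:(nr - 1L)) for (c in 0:(nc - 1L)) {
    nb <- moore_neighbors(r, c, nr, nc)
    nl[[r * nc + c + 1L]] <- nb[, 1L] * nc + nb[, 2L] + 1L
  }
  .nbr_cache[[key]] <- nl
  nl
}

# Greedy seeded placement of treatment labels on one nr x nc grid.
# Visits cells in random order; at each cell draws uniformly among the
# treatments (or "empty" slots) whose placement keeps c1 and c2 intact for
# every cell of the grid. Returns a treatment matrix or NULL on dead end.
place_block <- function(counts, nr, nc) {
  ncell <- nr * nc
  n_empty <- ncell - sum(counts)
  if (n_empty < 0L) stop("grid capacity below the number of plots")
  trts <- names(counts)
  nt <- length(trts)
  pool <- c(as.integer(counts), n_empty)        # slot nt + 1 = empty cells
  nbr <- neighbor_list(nr, nc)
  grid <- integer(ncell)                        # 0 = unassigned, nt+1 = empty
  # nbcount[t, cell] = placed plots of treatment t among cell's neighbors
  nbcount <- matrix(0L, nt, ncell)
  for (cell in sample(ncell)) {
    nb <- nbr[[cell]]
    cand <- which(pool > 0L)
    if (any(nbcount[, cell] > 2L)) cand <- cand[cand == nt + 1L]   # c2 at focal
    ok <- vapply(cand, function(t) {
      if (t > nt) return(TRUE)
      if (nbcount[t, cell] > 0L) return(FALSE)  # c1
      all(nbcount[t, nb] < 2L)                  # c2 at surrounding focals
    }, logical(1L))
    cand <- cand[ok]
    if (length(cand) == 0L) return(NULL)
    pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    grid[cell] <- pick
    pool[pick] <- pool[pick] - 1L
    if (pick <= nt) nbcount[pick, nb] <- nbcount[pick, nb] + 1L
  }
  out <- matrix(NA_character_, nr, nc)
  filled <- grid <= nt
  cells <- which(filled)
  out[cbind((cells - 1L) %/% nc + 1L, (cells - 1L) %% nc + 1L)] <- trts[grid[filled]]
  matrix(out, nr, nc)
}

#' Randomize plots onto block grids under adjacency constraints
#'
#' Splits the plots evenly across blocks (balanced within each treatment),
#' then places each block's plots on its grid by seeded restart sampling
#' until the layout satisfies both adjacency constraints (see
#' [check_layout()]). Deterministic for a fixed seed.
#'
#' @param design an unplaced `plot_design` from [assemble_design()].
#' @param blocks number of blocks (default 2).
#' @param grid_rows,grid_cols grid dimensions per block (default 5 x 8).
#' @param seed integer seed.
#' @param max_restarts restart budget per block.
#' @return the design with `block`, `row`, `col` columns added (0-based,
#'   row-major grid coordinates).
#' @export
randomize_layout <- function(design, blocks = 2L, grid_rows = 5L, grid_cols = 8L,
                             seed = 1L, max_restarts = 1000L) {
  stopifnot(nrow(design) >= 1, blocks >= 1)
  trt <- treatment_label(design$richness, design$myco_level)
  if (nrow(design) %% blocks != 0L)
    stop("plots do not split evenly across ", blocks, " blocks")
  per_block <- nrow(design) / blocks
  if (per_block > grid_rows * grid_cols)
    stop("grid capacity (", grid_rows * grid_cols,
         ") below plots per block (", per_block, ")")
  seeds <- split_seed(seed, blocks + 1L)

  # balanced block assignment: within each treatment spread replicates
  # round-robin over blocks (random order), then fix up any totals mismatch
  block_of <- with_seed(seeds[blocks + 1L], {
    bo <- integer(nrow(design))
    for (t in unique(trt)) {
      idx <- sample(which(trt == t))
      bo[idx] <- rep_len(sample(blocks), length(idx))
    }
    # rebalance totals if treatment counts don't divide evenly
    repeat {
      tab <- tabulate(bo, blocks)
      if (max(tab) - min(tab) <= 0L) break
      from <- which.max(tab); to <- which.min(tab)
      mv <- sample(which(bo == from), 1L)
      bo[mv] <- to
    }
    bo
  })

  out <- design
  out$block <- block_of
  out$row <- NA_integer_; out$col <- NA_integer_
  for (b in seq_len(blocks)) {
    idx <- which(block_of == b)
    counts <- table(trt[idx])
    grid <- with_seed(seeds[b], {
      g <- NULL
      for (r in seq_len(max_restarts)) {
        g <- place_block(as.integer(counts) |> stats::setNames(names(counts)),
                         grid_rows, grid_cols)
        if (!is.null(g)) break
      }
      g
    })
    if (is.null(grid))
      stop("no constraint-satisfying layout for block ", b, " within ",
           max_restarts, " restarts; tightest constraint: same-treatment ",
           "Moore adjacency (c1) with ", max(counts), " plots of one treatment")
    # map this block's plots of each treatment onto its cells, randomly
    with_seed(seeds[b] + 1L, {
      for (t in names(counts)) {
        cells <- which(grid == t, arr.ind = TRUE)
        plots <- sample(idx[trt[idx] == t])
        stopifnot(nrow(cells) == length(plots))
        out$row[plots] <- cells[, 1L] - 1L
        out$col[plots] <- cells[, 2L] - 1L
      }
    })
  }
  chk <- check_layout(out)
  if (!chk$ok) stop("internal error: generated layout fails the checker")
  class(out) <- c("plot_design", "data.frame")
  out
}

#' Within-plot planting layout
#'
#' Places the composition's species on the 14-row x 10-column planting grid
#' (140 trees at 1 m spacing). Cells are walked in boustrophedon (snake)
#' order and species are assigned cyclically, which (i) gives every species
#' exactly `140 / richness` trees and (ii) interleaves species so that for
#' richness 2 and 4 no two orthogonally adjacent trees are conspecific.
#' The central 8 x 8 sub-grid (rows 3-10, columns 1-8, 0-based) is flagged
#' as the measurement core of 64 trees.
#'
#' @param species character vector of the plot's species (richness must
#'   divide 140).
#' @param seed optional seed; if given, the cyclic species order is shuffled
#'   (deterministically) instead of alphabetical.
#' @return data.frame with `row`, `col` (0-based), `species_id`, `is_core`.
#' @export
planting_layout <- function(species, seed = NULL) {
  species <- sort(unique(as.character(species)))
  k <- length(species)
  n_rows <- 14L; n_cols <- 10L
  if ((n_rows * n_cols) %% k != 0L)
    stop("richness ", k, " does not divide ", n_rows * n_cols, " planting positions")
  if (!is.null(seed)) species <- with_seed(seed, sample(species))
  r <- rep(0:(n_rows - 1L), each = n_cols)
  c_fwd <- rep(0:(n_cols - 1L), times = n_rows)
  cc <- ifelse(r %% 2L == 0L, c_fwd, n_cols - 1L - c_fwd)
  snake <- r * n_cols + c_fwd     # walk order index
  sp <- species[(snake %% k) + 1L]
  data.frame(row = r, col = cc, species_id = sp,
             is_core = r >= 3L & r <= 10L & cc >= 1L & cc <= 8L,
             stringsAsFactors = FALSE)
}

#' Validate a full design against its structural invariants
#'
#' Re-checks everything claimed by the generator: unique plot ids, one plot
#' per grid cell, composition sizes matching richness, mycorrhizal
#' consistency of compositions (when pools are supplied), replication
#' counts, design-wide species balance, and — if the design is placed —
#' the adjacency constraints of [check_layout()].
#'
#' @param design a `plot_design` data.frame (placed or not).
#' @param pools optional `species_pools` for mycorrhizal consistency checks.
#' @return character vector of violation messages (empty if valid).
#' @export
validate_design <- function(design, pools = NULL) {
  msgs <- character()
  say <- function(...) msgs <<- c(msgs, paste0(...))
  if (anyDuplicated(design$plot_id)) say("duplicated plot_id")
  sp <- design_species(design)
  bad <- lengths(sp) != design$richness
  if (any(bad)) say("composition size != richness for: ",
                    paste(design$plot_id[bad], collapse = ", "))
  if (any(vapply(sp, anyDuplicated, integer(1L)) > 0L))
    say("duplicated species within a composition")
  vt <- valid_treatments()
  key <- treatment_label(design$richness, design$myco_level)
  if (!all(key %in% treatment_label(vt$richness, vt$myco_level)))
    say("invalid treatment cells present")
  if (!is.null(pools)) {
    for (i in seq_len(nrow(design))) {
      a <- sum(sp[[i]] %in% pools$amf_pool)
      e <- sum(sp[[i]] %in% pools$emf_pool)
      if (a + e != design$richness[i]) { say("unknown species in ", design$plot_id[i]); next }
      ok <- switch(design$myco_level[i],
                   AMF = e == 0L, EMF = a == 0L, Both = a == e)
      if (!ok) say("mycorrhizal level inconsistent with composition in ",
                   design$plot_id[i])
    }
  }
  occ <- species_occurrence(design)
  for (g in split(occ, treatment_label(occ$richness, occ$myco_level))) {
    if (length(unique(g$n_plots)) != 1L)
      say("unequal species occurrence in treatment cell ",
          treatment_label(g$richness[1L], g$myco_level[1L]))
  }
  if (all(c("block", "row", "col") %in% names(design))) {
    chk <- check_layout(design)
    if (!chk$ok)
      say("layout constraint violations: ",
          paste(unique(chk$violations$constraint), collapse = ", "))
  }
  msgs
}
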