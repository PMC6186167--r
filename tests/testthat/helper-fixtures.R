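# Shared fixtures, all built in code.

demo_traits <- function() {
  read_trait_table(system.file("extdata", "example_traits_synthetic.csv",
                               package = "mycodiv", mustWork = TRUE))
}

demo_pools <- function() species_pools(paste0("A", 1:5), paste0("E", 1:5))

# random mixed-type trait table (numeric + categorical, optional NAs)
rand_trait_table <- function(n = 8, seed = 1, na_frac = 0) {
  set.seed(seed)
  x <- data.frame(
    species = sprintf("sp%02d", seq_len(n)),
    mycorrhizal_type = sample(c("AMF", "EMF"), n, replace = TRUE),
    t_num1 = rnorm(n), t_num2 = runif(n, 0, 100),
    t_cat = sample(letters[1:3], n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (na_frac > 0) {
    for (cl in c("t_num1", "t_num2", "t_cat")) {
      hit <- runif(n) < na_frac
      # never blank out a whole row
      hit[1] <- FALSE
      x[[cl]][hit] <- NA
    }
  }
  trait_table(x)
}

# independent double-sum oracle for Rao's Q
brute_rao <- function(d, p) {
  q <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) q <- q + d[i, j] * p[i] * p[j]
  q
}

# random valid yield table components for partition property tests
rand_partition_input <- function(n) {
  list(Y_O = runif(n, 0, 30), M = runif(n, 0.5, 30), RY_E = rep(1 / n, n))
}

# a tiny placed design data.frame built by hand
placed_design <- function(rows, cols, richness, myco, block = 1L) {
  data.frame(plot_id = sprintf("P%02d", seq_along(rows)), block = block,
             row = rows, col = cols, richness = richness, myco_level = myco,
             composition = "x", stringsAsFactors = FALSE)
}

# exhaustive feasibility oracle for the adjacency constraints: can `counts`
# plots per treatment be placed on an nr x nc grid so that the layout passes
# check_layout()? Depth-first over cells with pruning.
layout_feasible <- function(counts, nr, nc) {
  trts <- names(counts)
  nt <- length(trts)
  pool <- c(as.integer(counts), nr * nc - sum(counts))
  nbr <- lapply(seq_len(nr * nc), function(cell) {
    r <- (cell - 1L) %/% nc; c <- (cell - 1L) %% nc
    nb <- expand.grid(dr = -1:1, dc = -1:1)
    nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
    rr <- r + nb$dr; cc <- c + nb$dc
    ok <- rr >= 0 & rr < nr & cc >= 0 & cc < nc
    rr[ok] * nc + cc[ok] + 1L
  })
  grid <- integer(nr * nc)
  rec <- function(cell, pool) {
    if (cell > nr * nc) return(TRUE)
    nbdone <- nbr[[cell]][nbr[[cell]] < cell]
    for (t in which(pool > 0L)) {
      if (t <= nt) {
        if (any(grid[nbdone] == t)) next                      # c1
        ok2 <- TRUE
        for (f in nbr[[cell]])                                # c2 at focals
          if (sum(grid[nbr[[f]]] == t) >= 2L) { ok2 <- FALSE; break }
        if (!ok2) next
      }
      grid[cell] <<- t
      p2 <- pool; p2[t] <- p2[t] - 1L
      if (rec(cell + 1L, p2)) return(TRUE)
      grid[cell] <<- 0L
    }
    FALSE
  }
  rec(1L, pool)
}

# one-species-per-plot design wrapper to drive simulate_inventory by hand
toy_design <- function(compositions, richness, myco) {
  d <- data.frame(
    plot_id = sprintf("T%02d", seq_along(compositions)),
    richness = as.integer(richness), myco_level = myco,
    composition = vapply(compositions, function(x) paste(sort(x), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  class(d) <- c("plot_design", "data.frame")
  d
}
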