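# Trait tables, Gower dissimilarity, Rao's Q, pool selection.

test_that("trait_table rejects malformed input", {
  expect_error(trait_table(data.frame(species = "a")), "mycorrhizal_type")
  expect_error(trait_table(data.frame(species = c("a", "a"),
                                      mycorrhizal_type = "AMF", t = 1:2)),
               "duplicated")
  expect_error(trait_table(data.frame(species = "a", mycorrhizal_type = "XMF",
                                      t = 1)), "AMF")
  expect_error(trait_table(data.frame(species = "a", mycorrhizal_type = "AMF")),
               "trait column")
  expect_error(trait_table(data.frame(species = c("a", "b"),
                                      mycorrhizal_type = "AMF",
                                      t = c(NA, NA))), "entirely missing")
})

test_that("gower_distance matches hand arithmetic on the spec examples", {
  # one numeric trait {0, 5, 10}: range-normalized absolute differences
  tt <- trait_table(data.frame(species = c("a", "b", "c"),
                               mycorrhizal_type = c("AMF", "AMF", "EMF"),
                               h = c(0, 5, 10)))
  d <- gower_distance(tt)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 1.0)
  # identical rows -> 0
  tt2 <- trait_table(data.frame(species = c("a", "b"),
                                mycorrhizal_type = c("AMF", "EMF"),
                                h = c(3, 3), col = c("red", "red")))
  expect_warning(d2 <- gower_distance(tt2), "zero range")  # h dropped
  expect_equal(d2["a", "b"], 0)
  # single categorical trait, mismatching -> 1
  tt3 <- trait_table(data.frame(species = c("a", "b"),
                                mycorrhizal_type = c("AMF", "EMF"),
                                col = c("red", "blue")))
  expect_equal(gower_distance(tt3)["a", "b"], 1)
})

test_that("gower_distance rejects degenerate inputs", {
  expect_error(gower_distance(trait_table(data.frame(
    species = "a", mycorrhizal_type = "AMF", t = 1))), "two species")
  tt <- trait_table(data.frame(species = c("a", "b"),
                               mycorrhizal_type = c("AMF", "EMF"),
                               t = c(1, 1)))
  expect_warning(expect_error(gower_distance(tt), "no usable trait"))
})

test_that("gower matrix is a bounded symmetric dissimilarity (property)", {
  for (seed in 1:8) {
    tt <- rand_trait_table(n = 7, seed = seed, na_frac = if (seed %% 2) 0.2 else 0)
    d <- gower_distance(tt)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, nrow(tt)))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("gower agrees with the cluster::daisy oracle", {
  skip_if_not_installed("cluster")
  tt <- rand_trait_table(n = 10, seed = 42)
  d <- gower_distance(tt)
  df <- as.data.frame(tt)[, c("t_num1", "t_num2", "t_cat")]
  df$t_cat <- factor(df$t_cat)
  do <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(unname(d), unname(do), tolerance = 1e-10)
})

test_that("rao_q handles the stated edge cases", {
  expect_equal(rao_q(matrix(0, 1, 1), 1), 0)           # single species
  expect_equal(rao_q(matrix(c(0, 1, 1, 0), 2), c(0.5, 0.5)), 0.5)
  expect_equal(rao_q(matrix(0, 4, 4)), 0)              # zero distances
  expect_error(rao_q(matrix(c(0, 1, 1, 0), 2), c(0.6, 0.6)), "sum to 1")
  expect_error(rao_q(matrix(c(0, 1, 1, 0), 2), c(1.5, -0.5)), "nonnegative")
  expect_error(rao_q(matrix(c(0, 1, 1, 0), 2), 1), "length")
})

test_that("rao_q equals the brute-force double sum and is permutation invariant", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:8, 1)
    d <- matrix(runif(n * n), n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    p <- runif(n); p <- p / sum(p)
    expect_equal(rao_q(d, p), brute_rao(d, p), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(rao_q(d[perm, perm], p[perm]), rao_q(d, p), tolerance = 1e-12)
  }
})

test_that("select_pools returns forced pools unchanged when counts equal pool size", {
  tt <- demo_traits()
  p <- select_pools(tt, pool_size = 5)
  expect_s3_class(p, "species_pools")
  expect_setequal(p$amf_pool, tt$species[tt$mycorrhizal_type == "AMF"])
  expect_setequal(p$emf_pool, tt$species[tt$mycorrhizal_type == "EMF"])
  expect_equal(p$method, "exhaustive")
})

test_that("select_pools matches a brute-force oracle with 6 AMF candidates", {
  tt <- rand_trait_table(n = 11, seed = 7)
  tt$mycorrhizal_type <- c(rep("AMF", 6), rep("EMF", 5))
  d <- gower_distance(tt)
  amf <- sort(tt$species[tt$mycorrhizal_type == "AMF"])
  emf <- sort(tt$species[tt$mycorrhizal_type == "EMF"])
  objs <- combn(amf, 5, function(a) mean(d[a, emf]))
  p <- select_pools(tt, pool_size = 5)
  expect_equal(p$objective_value, min(objs), tolerance = 1e-12)
  expect_setequal(p$emf_pool, emf)
})

test_that("select_pools is invariant to adding an irrelevant duplicate candidate", {
  tt <- rand_trait_table(n = 11, seed = 7)
  tt$mycorrhizal_type <- c(rep("AMF", 6), rep("EMF", 5))
  p <- select_pools(tt, pool_size = 5)
  # clone of an already-optimal AMF species: same traits, new label
  clone <- tt[tt$species == p$amf_pool[1], ]
  clone$species <- "zz_clone"
  tt2 <- trait_table(rbind(as.data.frame(tt), clone))
  p2 <- select_pools(tt2, pool_size = 5)
  expect_equal(p2$objective_value, p$objective_value, tolerance = 1e-12)
})

test_that("heuristic search attains the exhaustive optimum on enumerable instances", {
  tt <- rand_trait_table(n = 14, seed = 3)
  tt$mycorrhizal_type <- c(rep("AMF", 7), rep("EMF", 7))
  exact <- select_pools(tt, pool_size = 4)
  heur <- select_pools(tt, pool_size = 4, exhaustive_limit = 2,
                       seed = 5, n_restarts = 25)
  expect_equal(heur$method, "swap-search")
  expect_gte(heur$objective_value, exact$objective_value - 1e-12)
  expect_equal(heur$objective_value, exact$objective_value, tolerance = 1e-9)
})

test_that("select_pools rejects pools that are too small", {
  tt <- rand_trait_table(n = 6, seed = 1)
  tt$mycorrhizal_type <- c(rep("AMF", 2), rep("EMF", 4))
  expect_error(select_pools(tt, pool_size = 3), "at least 3")
})
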