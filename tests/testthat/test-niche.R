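# Niche configurations and resource-capture quadrature.

test_that("scenario configs have the stated geometry", {
  p <- demo_pools()
  # neutral: fully degenerate
  n <- sample_niche_config(p, "neutral", seed = 1)
  expect_equal(nrow(n$species), 10L)
  expect_length(unique(n$species$cx), 1L)
  expect_length(unique(n$species$rate), 1L)
  expect_length(unique(n$species$radius), 1L)
  # complementarity with regions separated by more than 2 * radius:
  # every between-type disk pair is disjoint
  cc <- sample_niche_config(p, "complementarity", seed = 2, radius = 0.08,
                            amf_region = c(0.05, 0.05, 0.30, 0.95),
                            emf_region = c(0.70, 0.05, 0.95, 0.95))
  s <- cc$species
  a <- s[s$mycorrhizal_type == "AMF", ]; e <- s[s$mycorrhizal_type == "EMF", ]
  dist2 <- outer(a$cx, e$cx, "-")^2 + outer(a$cy, e$cy, "-")^2
  expect_true(all(sqrt(dist2) > 2 * 0.08))
  # determinism and scenario validation
  expect_identical(sample_niche_config(p, "selection", seed = 5),
                   sample_niche_config(p, "selection", seed = 5))
  expect_error(sample_niche_config(p, "drift", seed = 1))
})

test_that("selection scenario nests one dominant disk", {
  cfg <- sample_niche_config(demo_pools(), "selection", seed = 3)
  s <- cfg$species
  expect_length(unique(s$cx), 1L)  # concentric
  expect_equal(sum(s$radius == max(s$radius)), 1L)
  dom <- s$species_id[which.max(s$radius)]
  expect_equal(s$rate[s$species_id == dom] / max(s$rate[s$species_id != dom]),
               cfg$params$dominant_rate_advantage)
})

test_that("single-disk capture matches the analytic circle area", {
  p <- demo_pools()
  cfg <- sample_niche_config(p, "neutral", seed = 1, radius = 0.2)
  cap <- community_capture(cfg, p$amf_pool[1], resolution = 400)
  expect_equal(cap$capture[[1]], pi * 0.04, tolerance = 0.01)
  expect_equal(cap$union_area, cap$capture[[1]])
})

test_that("identical disks split capture exactly in half", {
  p <- demo_pools()
  cfg <- sample_niche_config(p, "neutral", seed = 1, radius = 0.2)
  two <- community_capture(cfg, p$amf_pool[1:2], resolution = 200)
  expect_equal(two$capture[[1]], two$capture[[2]])
  expect_equal(two$capture[[1]], two$union_area / 2, tolerance = 1e-12)
})

test_that("disjoint disks capture their full areas", {
  cfg <- sample_niche_config(demo_pools(), "complementarity", seed = 2,
                             radius = 0.08,
                             amf_region = c(0.1, 0.1, 0.3, 0.9),
                             emf_region = c(0.7, 0.1, 0.9, 0.9))
  one_a <- community_capture(cfg, "A1", resolution = 200)
  one_e <- community_capture(cfg, "E1", resolution = 200)
  pair <- community_capture(cfg, c("A1", "E1"), resolution = 200)
  expect_equal(pair$capture[["A1"]], one_a$capture[["A1"]])
  expect_equal(pair$capture[["E1"]], one_e$capture[["E1"]])
  expect_equal(pair$union_area, sum(pair$capture))
})

test_that("two-disk capture matches the analytic lens-area oracle", {
  # equal disks radius r at distance u: overlap (lens) area
  # L = 2 r^2 acos(u / 2r) - (u / 2) sqrt(4 r^2 - u^2); each species
  # captures pi r^2 - L / 2
  p <- species_pools(c("A1"), c("E1"))
  cfg <- sample_niche_config(p, "neutral", seed = 1, radius = 0.15)
  cfg$species$cx <- c(0.40, 0.55)  # u = 0.15 = r: strong overlap
  r <- 0.15; u <- 0.15
  lens <- 2 * r^2 * acos(u / (2 * r)) - (u / 2) * sqrt(4 * r^2 - u^2)
  cap <- community_capture(cfg, c("A1", "E1"), resolution = 400)
  expect_equal(cap$capture[["A1"]], pi * r^2 - lens / 2, tolerance = 0.01)
  expect_equal(cap$union_area, 2 * pi * r^2 - lens, tolerance = 0.01)
})

test_that("capture conserves, never exceeds the box, and is monotone (property)", {
  p <- demo_pools()
  for (seed in 1:10) {
    set.seed(seed)
    cfg <- sample_niche_config(p, "complementarity", seed = seed,
                               radius = runif(1, 0.05, 0.3))
    sp <- sample(cfg$species$species_id, sample(2:6, 1))
    cap <- community_capture(cfg, sp, resolution = 80)
    expect_equal(sum(cap$capture), cap$union_area, tolerance = 1e-12)
    expect_lte(cap$union_area, 1)
    # adding a species never increases an incumbent's capture
    extra <- sample(setdiff(cfg$species$species_id, sp), 1)
    cap2 <- community_capture(cfg, c(sp, extra), resolution = 80)
    expect_true(all(cap2$capture[sp] <= cap$capture[sp] + 1e-12))
  }
})

test_that("capture converges as the quadrature is refined", {
  cfg <- sample_niche_config(demo_pools(), "complementarity", seed = 4)
  sp <- cfg$species$species_id[1:4]
  c1 <- community_capture(cfg, sp, resolution = 100)
  c2 <- community_capture(cfg, sp, resolution = 200)
  c4 <- community_capture(cfg, sp, resolution = 400)
  err1 <- max(abs(c1$capture - c4$capture))
  err2 <- max(abs(c2$capture - c4$capture))
  expect_lt(err2, err1 + 1e-6)   # O(1/R) refinement
  expect_lt(err2, 0.01)
})

test_that("community_capture validates its inputs", {
  cfg <- sample_niche_config(demo_pools(), "neutral", seed = 1)
  expect_error(community_capture(cfg, character(0)), "empty")
  expect_error(community_capture(cfg, "nope"), "unknown species")
  expect_error(community_capture(cfg, "A1", resolution = 10), "resolution")
})
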