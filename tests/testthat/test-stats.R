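# Bootstrap group summaries, mixed models, variance-explained R2.

test_that("nakagawa_r2 matches hand arithmetic and its bounds", {
  r2 <- nakagawa_r2(1, 1, 2)
  expect_equal(r2$r2_marginal, 0.25)
  expect_equal(r2$r2_conditional, 0.50)
  r2b <- nakagawa_r2(2, 0, 3)
  expect_equal(r2b$r2_marginal, r2b$r2_conditional)
  expect_equal(nakagawa_r2(0, 1, 1)$r2_marginal, 0)
  expect_error(nakagawa_r2(0, 0, 0), "zero")
  expect_error(nakagawa_r2(-1, 1, 1), "nonnegative")
  set.seed(1)
  for (i in 1:20) {
    v <- runif(3)
    r <- nakagawa_r2(v[1], v[2], v[3])
    expect_gte(r$r2_conditional, r$r2_marginal)
    expect_gte(r$r2_marginal, 0)
    expect_lte(r$r2_conditional, 1)
  }
})

test_that("group_summary handles degenerate and symmetric cases", {
  d <- data.frame(richness = rep(c(2, 4), each = 5), myco_level = "AMF",
                  v = c(rep(1, 5), rnorm(5)))
  gs <- group_summary(d, "v", n_boot = 200, seed = 3)
  # constant group: interval collapses to the point
  expect_equal(gs$lower[gs$richness == 2], 1)
  expect_equal(gs$upper[gs$richness == 2], 1)
  # sign flip negates and swaps the bounds (same seed, same resamples)
  d2 <- d; d2$v <- -d2$v
  gs2 <- group_summary(d2, "v", n_boot = 200, seed = 3)
  expect_equal(gs2$lower, -gs$upper, tolerance = 1e-12)
  expect_equal(gs2$upper, -gs$lower, tolerance = 1e-12)
  expect_equal(gs2$mean, -gs$mean)
  # size-1 group: undefined interval, flagged NA
  d3 <- data.frame(richness = c(2, 4, 4), myco_level = "x", v = 1:3)
  gs3 <- group_summary(d3, "v", n_boot = 50, seed = 1)
  expect_true(is.na(gs3$lower[gs3$n == 1]))
  expect_true(is.na(gs3$excludes_zero[gs3$n == 1]))
})

test_that("bootstrap intervals narrow with group size and cover at the nominal rate", {
  width <- function(n, seed) {
    set.seed(seed)
    d <- data.frame(richness = 2, myco_level = "AMF", v = rnorm(n, 1, 1))
    gs <- group_summary(d, "v", n_boot = 500, seed = seed)
    gs$upper - gs$lower
  }
  expect_lt(width(100, 7), width(10, 7))

  # coverage simulation: i.i.d. N(1, 1), n = 30 -> the 95% interval covers 1
  # in about 95% of replicates (percentile bootstrap undercovers slightly)
  nrep <- 400
  covered <- logical(nrep)
  for (r in seq_len(nrep)) {
    set.seed(1000 + r)
    d <- data.frame(richness = 2, myco_level = "AMF", v = rnorm(30, 1, 1))
    gs <- group_summary(d, "v", n_boot = 1000, seed = r)
    covered[r] <- gs$lower <= 1 && gs$upper >= 1
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

sim_lmm <- function(seed, n_groups = 60, reps = 2, beta = 0.5,
                    sd_alpha = 1, sd_eps = 1) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = reps)
  rich <- rep(sample(c(1, 2, 4), n_groups, replace = TRUE), each = reps)
  myco <- rep(sample(c("AMF", "EMF", "Both"), n_groups, replace = TRUE),
              each = reps)
  alpha <- rnorm(n_groups, 0, sd_alpha)
  y <- 1 + beta * log2(rich) + alpha[g] + rnorm(length(g), 0, sd_eps)
  data.frame(y = y, richness = rich, myco_level = myco,
             composition = paste0("c", g))
}

test_that("fit_mixed_model collapses to OLS when the random term is absent", {
  # degenerate limit built exactly: antithetic residuals within every group,
  # so group means sit exactly on the fixed-effect surface and the REML
  # random-intercept variance is estimated at its boundary (zero)
  d <- sim_lmm(1, sd_alpha = 0)
  e <- abs(rnorm(nrow(d) / 2, 0, 1))
  d$y <- 1 + 0.5 * log2(d$richness) + as.vector(rbind(e, -e))
  fit <- suppressWarnings(fit_mixed_model(d, "y"))
  expect_true(fit$singular)
  expect_lt(fit$varcomp$var_random, 1e-8)
  ols <- lm(y ~ log2(richness) + relevel(factor(myco_level), "AMF"), data = d)
  expect_equal(unname(fit$coefficients$estimate),
               unname(coef(ols)), tolerance = 1e-4)
})

test_that("fit_mixed_model is invariant to row order and recovers known parameters", {
  d <- sim_lmm(2)
  f1 <- fit_mixed_model(d, "y")
  f2 <- fit_mixed_model(d[sample(nrow(d)), ], "y")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f1$varcomp$var_random, f2$varcomp$var_random, tolerance = 1e-6)

  # parameter recovery at reduced scale (full grid in the acceptance suite)
  ests <- vapply(1:20, function(s) {
    f <- fit_mixed_model(sim_lmm(s), "y")
    f$coefficients$estimate[f$coefficients$term == ".rich"]
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.5), 3 * mc_se)
})

test_that("fit_mixed_model produces coherent variance components and R2", {
  d <- sim_lmm(4)
  fit <- fit_mixed_model(d, "y")
  vc <- fit$varcomp
  expect_true(all(c(vc$var_fixed, vc$var_random, vc$var_resid) >= 0))
  expect_lte(vc$r2_marginal, vc$r2_conditional)
  expect_lte(vc$r2_conditional, 1)
  expect_equal(nakagawa_r2(vc$var_fixed, vc$var_random, vc$var_resid)$r2_marginal,
               vc$r2_marginal)
  expect_error(fit_mixed_model(d, "nope"), "missing columns")
  d1 <- d; d1$composition <- "c1"
  expect_error(fit_mixed_model(d1, "y"), "2 levels")
})
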