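#' Bootstrap group summaries of partition components
#'
#' Per treatment group (richness x mycorrhizal level by default), computes
#' the mean and a nonparametric percentile bootstrap confidence interval,
#' resampling plots within the group (the plot is the experimental unit).
#' Groups whose interval excludes zero are flagged — the usual criterion
#' for declaring a biodiversity effect significantly different from zero.
#'
#' @param data data.frame of per-plot values (e.g. a `partition_result`).
#' @param value name of the value column.
#' @param groups character vector of grouping column names.
#' @param n_boot bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return data.frame with group columns, `n`, `mean`, `lower`, `upper`,
#'   `excludes_zero`. Size-1 groups get `NA` bounds and `excludes_zero = NA`.
#' @export
group_summary <- function(data, value, groups = c("richness", "myco_level"),
                          n_boot = 1000L, level = 0.95, seed = 1L) {
  stopifnot(value %in% names(data), all(groups %in% names(data)),
            n_boot >= 1L, level > 0, level < 1)
  x <- data[[value]]
  key <- interaction(data[groups], drop = TRUE, lex.order = TRUE)
  alpha <- (1 - level) / 2
  seeds <- split_seed(seed, nlevels(key))
  rows <- lapply(seq_along(levels(key)), function(gi) {
    v <- x[key == levels(key)[gi]]
    g <- data[match(levels(key)[gi], key), groups, drop = FALSE]
    n <- length(v)
    if (n < 2L) {
      ci <- c(NA_real_, NA_real_)
    } else {
      bm <- with_seed(seeds[gi], vapply(seq_len(n_boot), function(b)
        mean(v[sample.int(n, n, replace = TRUE)]), numeric(1L)))
      ci <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE, type = 7)
    }
    cbind(g, data.frame(n = n, mean = mean(v), lower = ci[1L], upper = ci[2L],
                        excludes_zero = if (anyNA(ci)) NA else ci[1L] > 0 | ci[2L] < 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a random-intercept linear mixed model
#'
#' Standard inference model for plot-level responses of a diversity
#' experiment: fixed effects of species richness (numeric, optionally
#' log2-transformed) and mycorrhizal level (plus optionally their
#' interaction and a block covariate), and a random intercept for community
#' composition — plots sharing a species composition are not independent
#' replicates of the richness gradient. Estimated by REML via
#' \pkg{lme4}; fixed effects are reported with Wald z tests.
#'
#' @param data data.frame with the response, `richness`, `myco_level`, a
#'   `composition` column, and optionally `block`.
#' @param response name of the response column (e.g. `"NE"`, `"CE"`,
#'   `"SE"`, or a productivity column).
#' @param richness_scale `"log2"` (default) or `"raw"`.
#' @param interaction include the richness x mycorrhizal interaction.
#' @param include_block add block as a fixed covariate.
#' @param reference_level reference level of `myco_level` (default "AMF").
#' @return object of class `myco_lmm`: list with `model` (the merMod),
#'   `coefficients` (estimate, SE, z, p), `varcomp` (a [nakagawa_r2()]
#'   input/output bundle), `singular`, `formula`.
#' @export
fit_mixed_model <- function(data, response, richness_scale = c("log2", "raw"),
                            interaction = FALSE, include_block = FALSE,
                            reference_level = "AMF") {
  richness_scale <- match.arg(richness_scale)
  need <- c(response, "richness", "myco_level", "composition")
  if (!all(need %in% names(data)))
    stop("missing columns: ", paste(setdiff(need, names(data)), collapse = ", "))
  d <- data
  d$.y <- d[[response]]
  d$.rich <- if (richness_scale == "log2") log2(d$richness) else d$richness
  d$myco_level <- stats::relevel(factor(d$myco_level), ref = reference_level)
  d$composition <- factor(d$composition)
  if (nlevels(d$composition) < 2L)
    stop("composition grouping needs at least 2 levels")
  fe <- if (interaction) ".rich * myco_level" else ".rich + myco_level"
  if (include_block) fe <- paste(fe, "+ factor(block)")
  fml <- stats::as.formula(paste(".y ~", fe, "+ (1 | composition)"))
  fit <- lme4::lmer(fml, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit: random-intercept variance estimated at zero")

  co <- summary(fit)$coefficients
  z <- co[, "Estimate"] / co[, "Std. Error"]
  coefficients <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                             se = co[, "Std. Error"], z = z,
                             p = 2 * stats::pnorm(-abs(z)),
                             row.names = NULL, stringsAsFactors = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_random <- vc$vcov[vc$grp == "composition"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  # fixed-effect variance: population variance of the linear predictor
  pred <- stats::model.matrix(fit) %*% lme4::fixef(fit)
  var_fixed <- mean((pred - mean(pred))^2)
  r2 <- nakagawa_r2(var_fixed, var_random, var_resid)

  structure(list(model = fit, coefficients = coefficients,
                 varcomp = c(list(var_fixed = var_fixed,
                                  var_random = var_random,
                                  var_resid = var_resid), r2),
                 singular = singular, formula = fml, response = response),
            class = "myco_lmm")
}

#' @export
print.myco_lmm <- function(x, ...) {
  cat("Random-intercept mixed model for", x$response, "\n")
  cat("  ", deparse(x$formula), "\n")
  print(x$coefficients, digits = 4)
  with(x$varcomp, cat(sprintf(
    "  var(fixed) %.4g, var(composition) %.4g, var(resid) %.4g\n  R2 marginal %.3f, conditional %.3f%s\n",
    var_fixed, var_random, var_resid, r2_marginal, r2_conditional,
    if (x$singular) "  [singular fit]" else "")))
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-components decomposition of explained variation:
#' `R2_marginal = var_f / (var_f + var_a + var_e)` (fixed effects alone) and
#' `R2_conditional = (var_f + var_a) / (var_f + var_a + var_e)` (fixed plus
#' random effects), with `var_f` the variance of the fixed-effect linear
#' predictor, `var_a` the random-intercept variance, `var_e` the residual
#' variance.
#'
#' @param var_fixed,var_random,var_resid nonnegative variance components,
#'   not all zero.
#' @return list with `r2_marginal`, `r2_conditional`.
#' @export
#' @examples
#' nakagawa_r2(1, 1, 2)  # 0.25, 0.50
nakagawa_r2 <- function(var_fixed, var_random, var_resid) {
  v <- c(var_fixed, var_random, var_resid)
  stopifnot(length(v) == 3L, all(is.finite(v)))
  if (any(v < 0)) stop("variance components must be nonnegative")
  tot <- sum(v)
  if (tot == 0) stop("all variance components are zero")
  list(r2_marginal = var_fixed / tot,
       r2_conditional = (var_fixed + var_random) / tot)
}
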