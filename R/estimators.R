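# Assemble an mr_result from an estimate and SE. CI and p use the normal
# distribution unless df is supplied (then Student t, as for MR-Egger with
# few instruments).
new_mr_result <- function(method, n_snp, beta, se, df = NULL) {
  if (is.null(df) || !is.finite(df) || df <= 0) {
    crit <- stats::qnorm(0.975)
    pval <- p_from_z(beta / se)
  } else {
    crit <- stats::qt(0.975, df)
    pval <- pmax(2 * stats::pt(-abs(beta / se), df), .Machine$double.xmin)
  }
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  structure(
    list(
      method = method, n_snp = as.integer(n_snp),
      beta = beta, se = se, ci_low = ci_low, ci_high = ci_high, pval = pval,
      odds_ratio = exp(beta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high)
    ),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "<mr_result> %s: n_snp = %d, beta = %.4g (se %.4g), OR = %.3g [%.3g, %.3g], p = %.3g\n",
    x$method, x$n_snp, x$beta, x$se, x$odds_ratio, x$or_ci_low, x$or_ci_high,
    x$pval
  ))
  invisible(x)
}

#' Flatten one or more mr_result objects to a data frame
#' @param ... `mr_result` objects, or lists of them.
#' @return One row per result with the standard report columns.
#' @export
mr_result_table <- function(...) {
  res <- list(...)
  if (length(res) == 1 && !inherits(res[[1]], "mr_result")) res <- res[[1]]
  do.call(rbind, lapply(res, function(r) {
    data.frame(method = r$method, n_snp = r$n_snp, beta = r$beta, se = r$se,
               or = r$odds_ratio, or_ci_low = r$or_ci_low,
               or_ci_high = r$or_ci_high, pval = r$pval)
  }))
}

variants_of <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  h$variants
}

# first-order Wald ratios and their variances for a harmonized set
wald_components <- function(v) {
  list(ratio = v$big_gamma / v$gamma,
       var = v$se_big_gamma^2 / v$gamma^2)
}

#' Wald ratio estimate for a single variant
#'
#' beta = Gamma / gamma with the first-order (delta-method) standard error
#' se(Gamma) / |gamma|; the uncertainty of the SNP-exposure effect is
#' ignored, the convention shared by all the multi-variant estimators here.
#'
#' @param v a single-variant `harmonized_set`, or a list/one-row data frame
#'   with fields `gamma`, `se_gamma`, `big_gamma`, `se_big_gamma`.
#' @return An `mr_result` with `method = "wald_ratio"`.
#' @export
mr_wald_ratio <- function(v) {
  if (inherits(v, "harmonized_set")) v <- variants_of(v)
  v <- as.list(as.data.frame(v))
  if (length(v$gamma) != 1) mr_abort("wald ratio is a single-variant estimate")
  if (v$gamma == 0) mr_abort("degenerate instrument: gamma = 0")
  new_mr_result("wald_ratio", 1L, v$big_gamma / v$gamma,
                v$se_big_gamma / abs(v$gamma))
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure effects
#' through the origin with weights 1/se(Gamma)^2; equivalently the
#' precision-weighted mean of the per-variant Wald ratios. The
#' multiplicative random-effects model (the default, and the primary
#' estimator of a metabolite screen) scales the fixed-effect standard error
#' by sqrt(Q/(J-1)) floored at 1, so heterogeneity can widen but never
#' shrink the interval.
#'
#' @param h a `harmonized_set` (>= 1 variant for fixed, >= 2 for random).
#' @param model `"random"` (default) or `"fixed"`.
#' @return An `mr_result` with `method = "ivw"`.
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  v <- variants_of(h)
  j <- nrow(v)
  min_j <- if (model == "random") 2L else 1L
  if (j < min_j) {
    mr_abort(sprintf("IVW (%s) needs at least %d instruments, got %d",
                     model, min_j, j))
  }
  w <- 1 / v$se_big_gamma^2
  s_gg <- sum(w * v$gamma^2)
  beta <- sum(w * v$gamma * v$big_gamma) / s_gg
  se_fixed <- sqrt(1 / s_gg)
  if (model == "fixed" || j == 1) {
    return(new_mr_result("ivw", j, beta, se_fixed))
  }
  q <- sum(w * (v$big_gamma - beta * v$gamma)^2)
  se <- se_fixed * max(1, sqrt(q / (j - 1)))
  new_mr_result("ivw", j, beta, se)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the SNP-outcome on the SNP-exposure effects
#' with an unconstrained intercept (weights 1/se(Gamma)^2), after orienting
#' every variant so gamma >= 0. The slope is the causal estimate under the
#' InSIDE assumption; the intercept estimates the average directional
#' pleiotropy and feeds the Egger intercept test. Standard errors use
#' multiplicative overdispersion floored at 1 and Student-t inference with
#' J - 2 degrees of freedom.
#'
#' @param h a `harmonized_set` with >= 3 variants.
#' @return A list: `result` (`mr_result`, `method = "mr_egger"`),
#'   `intercept`, `intercept_se`, `intercept_p`, and `sigma` (the
#'   unfloored residual scale).
#' @export
mr_egger <- function(h) {
  v <- variants_of(h)
  j <- nrow(v)
  if (j < 3) mr_abort("MR-Egger needs at least 3 instruments")
  flip <- sign(v$gamma)
  flip[flip == 0] <- 1
  x <- v$gamma * flip
  y <- v$big_gamma * flip
  w <- 1 / v$se_big_gamma^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  sigma2 <- sum(w * resid^2) / (j - 2)
  infl <- max(1, sigma2)
  se_slope <- sqrt(infl * sw / det)
  se_intercept <- sqrt(infl * swxx / det)
  intercept_p <- pmax(2 * stats::pt(-abs(intercept / se_intercept), j - 2),
                      .Machine$double.xmin)
  list(
    result = new_mr_result("mr_egger", j, slope, se_slope, df = j - 2),
    intercept = intercept,
    intercept_se = se_intercept,
    intercept_p = intercept_p,
    sigma = sqrt(sigma2)
  )
}

# weighted-median point estimate from ratios and (unnormalized) weights
weighted_median_estimate <- function(ratio, weight) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- weight[ord] / sum(weight)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(ratio[1])
  if (0.5 >= p[length(p)]) return(ratio[length(p)])
  stats::approx(p, ratio, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Orders the per-variant Wald ratios, weights each by the inverse of its
#' first-order variance, and interpolates the weighted 50% quantile using
#' midpoint cumulative positions p_j = sum(w_1..w_j) - w_j/2. Consistent
#' whenever variants carrying more than half of the weight are valid
#' instruments. The standard error comes from a seeded parametric bootstrap:
#' gamma and Gamma are resampled from normal distributions with their
#' reported standard errors and the estimate recomputed.
#'
#' @param h a `harmonized_set` with >= 3 variants.
#' @param n_boot bootstrap draws (>= 100; default 1000).
#' @param seed integer seed for the bootstrap (mandatory).
#' @return An `mr_result` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  v <- variants_of(h)
  j <- nrow(v)
  if (j < 3) mr_abort("weighted median needs at least 3 instruments")
  if (n_boot < 100) mr_abort("n_boot must be >= 100")
  if (missing(seed)) mr_abort("weighted median requires an explicit seed")
  wc <- wald_components(v)
  est <- weighted_median_estimate(wc$ratio, 1 / wc$var)
  boots <- withr::with_seed(seed, {
    g_star <- matrix(stats::rnorm(n_boot * j, mean = rep(v$gamma, each = n_boot),
                                  sd = rep(v$se_gamma, each = n_boot)),
                     nrow = n_boot)
    bg_star <- matrix(stats::rnorm(n_boot * j, mean = rep(v$big_gamma, each = n_boot),
                                   sd = rep(v$se_big_gamma, each = n_boot)),
                      nrow = n_boot)
    ratio_star <- bg_star / g_star
    var_star <- sweep(1 / g_star^2, 2, v$se_big_gamma^2, `*`)
    vapply(seq_len(n_boot), function(b) {
      weighted_median_estimate(ratio_star[b, ], 1 / var_star[b, ])
    }, numeric(1))
  })
  new_mr_result("weighted_median", j, est, stats::sd(boots))
}
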