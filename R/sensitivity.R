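#' Cochran's Q heterogeneity test
#'
#' Q = sum_j w_j (b_j - b_ivw)^2 across the per-variant Wald ratios b_j,
#' with first-order inverse-variance weights w_j = gamma_j^2/se(Gamma_j)^2
#' and the fixed-effect IVW estimate as center; chi-square with J - 1
#' degrees of freedom under homogeneity. p < 0.05 flags heterogeneity
#' among the instrument-specific causal estimates.
#'
#' @param h a `harmonized_set` with >= 2 variants.
#' @return A list: `q_stat`, `q_df`, `q_p`.
#' @export
cochran_q <- function(h) {
  v <- variants_of(h)
  j <- nrow(v)
  if (j < 2) mr_abort("Cochran's Q needs at least 2 instruments")
  wc <- wald_components(v)
  w <- 1 / wc$var
  center <- sum(w * wc$ratio) / sum(w)
  q <- sum(w * (wc$ratio - center)^2)
  list(q_stat = q, q_df = j - 1L,
       q_p = max(stats::pchisq(q, j - 1, lower.tail = FALSE),
                 .Machine$double.xmin))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept triple of the [mr_egger()] fit: a nonzero intercept
#' estimates the average direct (pleiotropic) effect of the instruments on
#' the outcome, and p < 0.05 flags directional horizontal pleiotropy.
#'
#' @param h a `harmonized_set` with >= 3 variants.
#' @return A list: `intercept`, `se`, `p`.
#' @export
egger_intercept_test <- function(h) {
  fit <- mr_egger(h)
  list(intercept = fit$intercept, se = fit$intercept_se, p = fit$intercept_p)
}

#' Heterogeneity and pleiotropy diagnostics for one exposure-outcome pair
#'
#' Assembles Cochran's Q, the Egger intercept test, and the MR-PRESSO global
#' test into one report with the pass/fail flags the candidate screen
#' consumes: `heterogeneity_ok` iff the Q-test p >= `alpha`, and
#' `pleiotropy_ok` iff both the intercept and the PRESSO global p are
#' >= `alpha`.
#'
#' @param h a `harmonized_set` with >= 4 variants (PRESSO's minimum).
#' @param n_sim PRESSO simulation count (default 1000).
#' @param seed integer seed for PRESSO (mandatory).
#' @param alpha flag threshold (default 0.05).
#' @param presso optional precomputed [mr_presso()] output to reuse.
#' @return A list of class `sensitivity_report`: `q_stat`, `q_df`, `q_p`,
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`,
#'   `presso_global_p`, and `flags` (`heterogeneity_ok`, `pleiotropy_ok`).
#' @export
sensitivity_report <- function(h, n_sim = 1000, seed, alpha = 0.05,
                               presso = NULL) {
  q <- cochran_q(h)
  eg <- egger_intercept_test(h)
  if (is.null(presso)) {
    if (missing(seed)) mr_abort("sensitivity_report requires a seed for MR-PRESSO")
    presso <- mr_presso(h, n_sim = n_sim, seed = seed)
  }
  gp <- presso$report$global_p
  structure(
    list(
      q_stat = q$q_stat, q_df = q$q_df, q_p = q$q_p,
      egger_intercept = eg$intercept,
      egger_intercept_se = eg$se,
      egger_intercept_p = eg$p,
      presso_global_p = gp,
      flags = list(
        heterogeneity_ok = q$q_p >= alpha,
        pleiotropy_ok = eg$p >= alpha && gp >= alpha
      )
    ),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_report> Q = %.3g (df %d, p %.3g); Egger intercept %.3g (p %.3g); PRESSO global p %.3g\n",
    x$q_stat, x$q_df, x$q_p, x$egger_intercept, x$egger_intercept_p,
    x$presso_global_p
  ))
  invisible(x)
}
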