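# leave-one-out fixed-effect IVW slopes, one per variant, in closed form
loo_ivw_slopes <- function(gamma, big_gamma, w) {
  s_xy <- sum(w * gamma * big_gamma)
  s_xx <- sum(w * gamma^2)
  (s_xy - w * gamma * big_gamma) / (s_xx - w * gamma^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Simulation-based detection and correction of horizontal pleiotropy.
#' The observed statistic is the weighted residual sum of squares
#' RSS = sum_j w_j (Gamma_j - beta_(-j) gamma_j)^2, where beta_(-j) is the
#' leave-one-out fixed-effect IVW slope and w_j = 1/se(Gamma_j)^2. Its null
#' distribution is built by drawing, `n_sim` times, Gamma_j* from
#' Normal(beta_(-j) gamma_j, se(Gamma_j)) and recomputing RSS with the same
#' leave-one-out scheme; the global p-value is the upper-tail fraction with
#' a +1/(n_sim+1) continuity correction. Each variant's observed weighted
#' squared residual is compared with its simulated distribution to give a
#' per-variant outlier p-value, Bonferroni-adjusted over the J variants;
#' variants with adjusted p below `outlier_alpha` are flagged and the
#' outlier-corrected estimate is the random-effects IVW on the remaining
#' variants. When outliers are flagged, a distortion test compares the
#' raw-vs-corrected slope change against the change induced by removing
#' random subsets of the same size.
#'
#' @param h a `harmonized_set` with >= 4 variants.
#' @param n_sim simulated null datasets (>= 100; default 1000).
#' @param seed integer seed (mandatory).
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   per-variant outlier test (default 0.05).
#' @param distortion whether to run the distortion test when outliers are
#'   flagged (default TRUE).
#' @return A list with `report` (class `presso_report`: `global_rss_observed`,
#'   `global_p`, `outlier_ids`, `outlier_p`, `distortion_p`, `n_sim`, `seed`),
#'   `raw` (random-effects IVW on all variants) and `corrected`
#'   (random-effects IVW without flagged outliers; `NULL` when no outliers
#'   are flagged is never the case -- it equals `raw` then -- but it is
#'   `NULL` when fewer than 2 variants survive correction).
#' @export
mr_presso <- function(h, n_sim = 1000, seed, outlier_alpha = 0.05,
                      distortion = TRUE) {
  v <- variants_of(h)
  j <- nrow(v)
  if (j < 4) mr_abort("MR-PRESSO needs at least 4 instruments")
  if (n_sim < 100) mr_abort("n_sim must be >= 100")
  if (missing(seed)) mr_abort("MR-PRESSO requires an explicit seed")

  w <- 1 / v$se_big_gamma^2
  beta_loo <- loo_ivw_slopes(v$gamma, v$big_gamma, w)
  obs_resid2 <- w * (v$big_gamma - beta_loo * v$gamma)^2
  rss_obs <- sum(obs_resid2)

  sims <- withr::with_seed(seed, {
    # n_sim x j matrix of simulated outcome effects under the no-pleiotropy null
    bg_star <- matrix(
      stats::rnorm(n_sim * j,
                   mean = rep(beta_loo * v$gamma, each = n_sim),
                   sd = rep(v$se_big_gamma, each = n_sim)),
      nrow = n_sim
    )
    s_xx <- sum(w * v$gamma^2)
    s_xy_star <- bg_star %*% (w * v$gamma)                  # n_sim x 1
    # leave-one-out slopes for every sim: (S_xy* - w_j g_j Gamma*_j) / (S_xx - w_j g_j^2)
    num <- sweep(-sweep(bg_star, 2, w * v$gamma, `*`), 1, as.numeric(s_xy_star), `+`)
    den <- s_xx - w * v$gamma^2
    beta_loo_star <- sweep(num, 2, den, `/`)
    resid2_star <- sweep((bg_star - sweep(beta_loo_star, 2, v$gamma, `*`))^2,
                         2, w, `*`)
    list(resid2 = resid2_star, rss = rowSums(resid2_star))
  })

  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  outlier_p_raw <- (1 + colSums(sweep(sims$resid2, 2, obs_resid2, `>=`))) /
    (n_sim + 1)
  outlier_p <- pmin(1, outlier_p_raw * j)
  names(outlier_p) <- v$variant_id
  flagged <- which(outlier_p < outlier_alpha)

  raw <- mr_ivw(h, model = "random")
  corrected <- raw
  distortion_p <- NA_real_
  if (length(flagged)) {
    keep <- setdiff(seq_len(j), flagged)
    if (length(keep) >= 2) {
      h_corr <- h
      h_corr$variants <- v[keep, , drop = FALSE]
      corrected <- mr_ivw(h_corr, model = "random")
      if (distortion) {
        d_obs <- (raw$beta - corrected$beta) / abs(corrected$beta)
        d_null <- withr::with_seed(seed + 1L, {
          vapply(seq_len(n_sim), function(s) {
            drop_s <- sample.int(j, length(flagged))
            ks <- setdiff(seq_len(j), drop_s)
            b <- sum(w[ks] * v$gamma[ks] * v$big_gamma[ks]) /
              sum(w[ks] * v$gamma[ks]^2)
            (raw$beta - b) / abs(b)
          }, numeric(1))
        })
        distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
      }
    } else {
      corrected <- NULL
      warning("all (or nearly all) variants flagged as outliers; corrected estimate undefined",
              call. = FALSE)
    }
  }
  if (!is.null(corrected)) {
    corrected$method <- if (length(flagged)) "mr_presso_corrected" else "mr_presso_raw"
  }
  raw$method <- "mr_presso_raw"

  report <- structure(
    list(
      global_rss_observed = rss_obs,
      global_p = global_p,
      outlier_ids = v$variant_id[flagged],
      outlier_p = outlier_p,
      distortion_p = distortion_p,
      n_sim = n_sim,
      seed = seed
    ),
    class = "presso_report"
  )
  list(report = report, raw = raw, corrected = corrected)
}

#' @export
print.presso_report <- function(x, ...) {
  cat(sprintf(
    "<presso_report> RSS_obs = %.4g, global p = %.4g, %d outlier(s)%s\n",
    x$global_rss_observed, x$global_p, length(x$outlier_ids),
    if (length(x$outlier_ids))
      sprintf(" [%s]", paste(x$outlier_ids, collapse = ", ")) else ""
  ))
  invisible(x)
}
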