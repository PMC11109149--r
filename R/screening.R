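#' Bonferroni-corrected significance threshold
#'
#' Divides the nominal level by the number of tests; with the conventional
#' alpha = 0.05 over a screen of 486 metabolites the threshold is
#' 0.05/486 ~ 1.03e-4.
#'
#' @param alpha nominal significance level in (0, 1).
#' @param m number of tests, >= 1 (vectorized).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 486) {
  if (alpha <= 0 || alpha >= 1) mr_abort("alpha must lie in (0, 1)")
  if (!is.numeric(m) || !length(m) || any(m < 1 | m != round(m))) {
    mr_abort("m must be a positive integer")
  }
  alpha / m
}

method_sign <- function(res) {
  if (is.null(res)) return(NA_real_)
  sign(res$beta)
}

#' Screen exposures with the multi-criterion candidate rule
#'
#' Applies, per exposure, the three-part rule of a metabolite MR screen:
#' (1) the IVW p-value is significant at `alpha`; (2) no evidence of
#' heterogeneity or horizontal pleiotropy in the sensitivity report (by
#' default only the pleiotropy flags are enforced and heterogeneity is
#' reported but not exclusionary; set `strict_heterogeneity = TRUE` to also
#' require the Q-test to pass); (3) the signs of the IVW, MR-Egger,
#' weighted-median and MR-PRESSO estimates agree (the PRESSO
#' outlier-corrected estimate is used when outliers were removed, the raw
#' one otherwise; a zero estimate counts as inconsistent). A fourth,
#' stricter tier flags candidates whose IVW p-value survives Bonferroni
#' correction over `m` tests.
#'
#' @param results named list (one element per exposure) of lists with
#'   components `ivw` (`mr_result`), `egger` ([mr_egger()] output),
#'   `weighted_median` (`mr_result`) and `presso` ([mr_presso()] output).
#'   A missing component marks the exposure unevaluable, never silently
#'   passed.
#' @param sens named list of [sensitivity_report()]s, same names.
#' @param strict_heterogeneity require `heterogeneity_ok` for a pass.
#' @param alpha nominal significance level (default 0.05).
#' @param m number of tests for the Bonferroni tier (default 486).
#' @return A data frame with one row per exposure: ivw statistics, the four
#'   method signs, `direction_consistent`, the sensitivity flags,
#'   `passes_screen`, `bonferroni_significant`, and `evaluable`.
#' @export
screen_candidates <- function(results, sens, strict_heterogeneity = FALSE,
                              alpha = 0.05, m = 486) {
  stopifnot(length(results) > 0, !is.null(names(results)))
  thr <- bonferroni_threshold(alpha, m)
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    s <- sens[[id]]
    required <- c("ivw", "egger", "weighted_median", "presso")
    evaluable <- !is.null(r) && all(required %in% names(r)) &&
      !any(vapply(r[required], is.null, logical(1))) && !is.null(s)
    if (!evaluable) {
      return(data.frame(
        exposure_id = id, ivw_beta = NA_real_, ivw_p = NA_real_,
        sign_ivw = NA_real_, sign_egger = NA_real_, sign_wm = NA_real_,
        sign_presso = NA_real_, direction_consistent = NA,
        heterogeneity_ok = NA, pleiotropy_ok = NA,
        passes_screen = NA, bonferroni_significant = NA, evaluable = FALSE
      ))
    }
    presso_est <- if (length(r$presso$report$outlier_ids) &&
                      !is.null(r$presso$corrected)) {
      r$presso$corrected
    } else {
      r$presso$raw
    }
    signs <- c(
      ivw = method_sign(r$ivw),
      egger = method_sign(r$egger$result),
      wm = method_sign(r$weighted_median),
      presso = method_sign(presso_est)
    )
    consistent <- all(signs != 0) && length(unique(signs)) == 1
    het_ok <- isTRUE(s$flags$heterogeneity_ok)
    ple_ok <- isTRUE(s$flags$pleiotropy_ok)
    passes <- r$ivw$pval < alpha && consistent && ple_ok &&
      (het_ok || !strict_heterogeneity)
    data.frame(
      exposure_id = id, ivw_beta = r$ivw$beta, ivw_p = r$ivw$pval,
      sign_ivw = signs[["ivw"]], sign_egger = signs[["egger"]],
      sign_wm = signs[["wm"]], sign_presso = signs[["presso"]],
      direction_consistent = consistent,
      heterogeneity_ok = het_ok, pleiotropy_ok = ple_ok,
      passes_screen = passes,
      bonferroni_significant = r$ivw$pval < thr,
      evaluable = TRUE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run all four MR estimators on one harmonized set
#'
#' Convenience wrapper used by the screening and pipeline layers: IVW
#' (random-effects), MR-Egger, weighted median, and MR-PRESSO, with the
#' derived seeds split deterministically from `seed`.
#'
#' @param h a `harmonized_set` with >= 4 variants.
#' @param seed integer base seed.
#' @param n_boot weighted-median bootstrap draws.
#' @param n_sim MR-PRESSO simulation count.
#' @return A list with components `ivw`, `egger`, `weighted_median`,
#'   `presso`, ready for [screen_candidates()].
#' @export
mr_all <- function(h, seed, n_boot = 1000, n_sim = 1000) {
  list(
    ivw = mr_ivw(h, model = "random"),
    egger = mr_egger(h),
    weighted_median = mr_weighted_median(h, n_boot = n_boot, seed = seed),
    presso = mr_presso(h, n_sim = n_sim, seed = seed + 1L)
  )
}

#' Reverse MR: test the outcome's effect on each candidate exposure
#'
#' Re-runs the full pipeline with the roles swapped -- the disease outcome
#' becomes the exposure, each candidate metabolite the outcome -- using the
#' same instrument-selection parameters and estimators as the forward
#' analysis. A candidate's forward finding is supported
#' (`reverse_mr_null = TRUE`) when the reverse IVW p-value is >= `alpha`
#' and the other three methods are concordantly non-significant.
#'
#' @param outcome_as_exposure the outcome [study_table()], now instrumented.
#' @param candidates named list of candidate-exposure [study_table()]s, now
#'   used as outcomes.
#' @param ld an [ld_source()] covering the outcome's instrument region pairs.
#' @param params an [instrument_params()] list.
#' @param seed integer base seed.
#' @param n_boot,n_sim as in [mr_all()].
#' @param alpha significance level (default 0.05).
#' @return A data frame, one row per candidate: `n_snp`, the four p-values,
#'   `reverse_mr_null` and `evaluable`.
#' @export
reverse_mr <- function(outcome_as_exposure, candidates, ld,
                       params = instrument_params(), seed,
                       n_boot = 1000, n_sim = 1000, alpha = 0.05) {
  stopifnot(length(candidates) > 0, !is.null(names(candidates)))
  iv <- suppressWarnings(build_instrument_set(outcome_as_exposure, ld, params))
  rows <- lapply(names(candidates), function(id) {
    base <- data.frame(
      exposure_id = outcome_as_exposure$trait_id, outcome_id = id,
      n_snp = NA_integer_, ivw_p = NA_real_, egger_p = NA_real_,
      wm_p = NA_real_, presso_p = NA_real_,
      reverse_mr_null = NA, evaluable = FALSE
    )
    if (nrow(iv$instruments) < 4) return(base)
    h <- harmonize(iv, candidates[[id]])
    if (nrow(h$variants) < 4) return(base)
    fits <- mr_all(h, seed = seed, n_boot = n_boot, n_sim = n_sim)
    presso_est <- if (length(fits$presso$report$outlier_ids) &&
                      !is.null(fits$presso$corrected)) {
      fits$presso$corrected
    } else {
      fits$presso$raw
    }
    ps <- c(fits$ivw$pval, fits$egger$result$pval,
            fits$weighted_median$pval, presso_est$pval)
    data.frame(
      exposure_id = outcome_as_exposure$trait_id, outcome_id = id,
      n_snp = fits$ivw$n_snp, ivw_p = ps[1], egger_p = ps[2],
      wm_p = ps[3], presso_p = ps[4],
      reverse_mr_null = all(ps >= alpha), evaluable = TRUE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
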