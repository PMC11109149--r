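# Builders shared across test files. Everything is generated in code; no
# fixture files.

make_records <- function(n = 3, seed = 1) {
  withr::with_seed(seed, {
    pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"),
                    ncol = 2, byrow = TRUE)
    idx <- sample.int(4, n, replace = TRUE)
    data.frame(
      variant_id = sprintf("rs%05d", seq_len(n)),
      chrom = as.character(sample(1:2, n, replace = TRUE)),
      pos = sort(sample.int(5e7, n)),
      effect_allele = pairs[idx, 1],
      other_allele = pairs[idx, 2],
      eaf = runif(n, 0.05, 0.95),
      beta = rnorm(n, 0, 0.1),
      se = runif(n, 0.005, 0.05),
      pval = runif(n, 1e-12, 1),
      n = rep(7824L, n)
    )
  })
}

make_table <- function(n = 3, seed = 1, ...) {
  study_table(make_records(n, seed), trait_id = "trait_test", ...)
}

# harmonized sets with a common causal slope plus noise, for oracle checks
random_harmonized <- function(j, seed, beta = 0.3) {
  withr::with_seed(seed, {
    gamma <- runif(j, 0.05, 0.3) * sample(c(-1, 1), j, replace = TRUE)
    se_g <- runif(j, 0.005, 0.02)
    se_bg <- runif(j, 0.01, 0.05)
    bg <- beta * gamma + rnorm(j, 0, se_bg)
    harmonized_set(gamma, se_g, bg, se_bg)
  })
}

# minimal estimator-result stand-ins for exercising the screening rule
fake_result <- function(beta, se = 0.1, method = "ivw", n_snp = 10) {
  metabomr:::new_mr_result(method, n_snp, beta, se)
}

fake_fits <- function(b_ivw, b_egger = b_ivw, b_wm = b_ivw, b_presso = b_ivw,
                      ivw_p = NULL) {
  ivw <- fake_result(b_ivw)
  if (!is.null(ivw_p)) ivw$pval <- ivw_p
  list(
    ivw = ivw,
    egger = list(result = fake_result(b_egger, method = "mr_egger"),
                 intercept = 0, intercept_se = 1, intercept_p = 0.9),
    weighted_median = fake_result(b_wm, method = "weighted_median"),
    presso = list(
      report = list(outlier_ids = character(), global_p = 0.5),
      raw = fake_result(b_presso, method = "mr_presso_raw"),
      corrected = NULL
    )
  )
}

fake_sens <- function(het_ok = TRUE, ple_ok = TRUE) {
  structure(
    list(
      q_stat = 1, q_df = 9, q_p = if (het_ok) 0.5 else 0.01,
      egger_intercept = 0, egger_intercept_se = 1,
      egger_intercept_p = if (ple_ok) 0.5 else 0.01,
      presso_global_p = if (ple_ok) 0.5 else 0.01,
      flags = list(heterogeneity_ok = het_ok, pleiotropy_ok = ple_ok)
    ),
    class = "sensitivity_report"
  )
}

binom_bounds99 <- function(p, n) {
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}
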