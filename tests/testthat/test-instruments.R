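test_that("p-value selection keeps exactly the sub-threshold records", {
  tab <- make_table(10, seed = 5)
  tab$records$pval <- rep(0.5, 10)
  expect_equal(nrow(select_by_pvalue(tab, 1e-5)$records), 0)

  tab$records$pval[4] <- 9e-6  # just under the threshold
  kept <- select_by_pvalue(tab, 1e-5)
  expect_equal(kept$records$variant_id, tab$records$variant_id[4])
  tab$records$pval[4] <- 1e-5  # exactly at the threshold: strict <, excluded
  expect_equal(nrow(select_by_pvalue(tab, 1e-5)$records), 0)

  # brute-force scan oracle on a random table, order preserved
  tab <- make_table(200, seed = 6)
  got <- select_by_pvalue(tab, 0.3)$records$variant_id
  want <- tab$records$variant_id[which(tab$records$pval < 0.3)]
  expect_identical(got, want)
})

test_that("greedy LD clumping matches an independent reference implementation", {
  # no LD at all: input unchanged
  tab <- make_table(8, seed = 7)
  ids <- tab$records$variant_id
  all_zero <- ld_source(expand.grid(variant_id_a = ids, variant_id_b = ids,
                                    stringsAsFactors = FALSE) |>
                          transform(r2 = 0))
  expect_identical(ld_clump(tab, all_zero)$records, tab$records)

  # two correlated variants 10 kb apart: the lower-p one wins
  rec <- make_records(2)
  rec$chrom <- "1"; rec$pos <- c(1e6, 1e6 + 1e4)
  rec$pval <- c(1e-8, 1e-6)
  tab2 <- study_table(rec, "t")
  ld2 <- ld_source(data.frame(variant_id_a = rec$variant_id[1],
                              variant_id_b = rec$variant_id[2], r2 = 0.5))
  expect_equal(ld_clump(tab2, ld2)$records$variant_id, rec$variant_id[1])

  # reference implementation of the greedy rule, written independently as a
  # while-loop over a dense matrix
  clump_oracle <- function(rec, r2m, r2_max, window_kb) {
    rem <- rec[order(rec$pval, rec$chrom, rec$pos), ]
    kept <- character()
    while (nrow(rem) > 0) {
      top <- rem[1, ]
      kept <- c(kept, top$variant_id)
      near <- rem$chrom == top$chrom &
        abs(rem$pos - top$pos) <= window_kb * 1000
      drop <- near & r2m[rem$variant_id, top$variant_id] >= r2_max
      drop[1] <- TRUE
      rem <- rem[!drop, , drop = FALSE]
    }
    sort(kept)
  }

  for (seed in c(21, 22, 23)) {
    rec <- make_records(20, seed = seed)
    rec$chrom <- "1"
    rec$pos <- withr::with_seed(seed, sort(sample.int(3e6, 20)))  # dense region
    ids <- rec$variant_id
    r2m <- withr::with_seed(seed + 50, {
      m <- matrix(runif(400)^3, 20, 20, dimnames = list(ids, ids))
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- 1
      m
    })
    pairs <- which(upper.tri(r2m), arr.ind = TRUE)
    ld <- ld_source(data.frame(variant_id_a = ids[pairs[, 1]],
                               variant_id_b = ids[pairs[, 2]],
                               r2 = r2m[pairs]))
    got <- sort(ld_clump(study_table(rec, "t"), ld, r2_max = 0.1,
                         window_kb = 500)$records$variant_id)
    expect_identical(got, clump_oracle(rec, r2m, 0.1, 500))
  }
})

test_that("clumping errors on an LD pair it needs but cannot look up", {
  rec <- make_records(2)
  rec$chrom <- "1"; rec$pos <- c(1e6, 1.1e6)
  tab <- study_table(rec, "t")
  expect_error(ld_clump(tab, ld_source(NULL)), "LD r2 unavailable.*rs00001")
})

test_that("clump output contains no retained pair violating the rule", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      rec <- make_records(15, seed = 300 + rep)
      rec$chrom <- "1"
      rec$pos <- sort(sample.int(2e6, 15))
      ids <- rec$variant_id
      m <- matrix(runif(225)^2, 15, 15, dimnames = list(ids, ids))
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      pairs <- which(upper.tri(m), arr.ind = TRUE)
      ld <- ld_source(data.frame(variant_id_a = ids[pairs[, 1]],
                                 variant_id_b = ids[pairs[, 2]],
                                 r2 = m[pairs]))
      kept <- ld_clump(study_table(rec, "t"), ld, r2_max = 0.05,
                       window_kb = 500)$records
      if (nrow(kept) > 1) {
        cmb <- combn(seq_len(nrow(kept)), 2)
        for (c_i in seq_len(ncol(cmb))) {
          a <- cmb[1, c_i]; b <- cmb[2, c_i]
          within <- kept$chrom[a] == kept$chrom[b] &&
            abs(kept$pos[a] - kept$pos[b]) <= 5e5
          if (within) {
            expect_lt(ld_r2(ld, kept$variant_id[a], kept$variant_id[b]), 0.05)
          }
        }
      }
    }
  })
})

test_that("variance explained matches the summary-statistic formula", {
  expect_equal(variance_explained(0.3, 0, 0.01, 7824), 0)
  expect_equal(variance_explained(0.3, 0.1, 0.01, 7824), 0.01262,
               tolerance = 1e-3)
  # symmetric in eaf <-> 1 - eaf since the 2 EAF (1-EAF) factor is
  expect_equal(variance_explained(0.2, 0.07, 0.012, 5000),
               variance_explained(0.8, 0.07, 0.012, 5000))
  expect_error(variance_explained(0, 0.1, 0.01, 100), "strictly inside")
  expect_error(variance_explained(1, 0.1, 0.01, 100), "strictly inside")
})

test_that("F-statistic follows ((N-K-1)/K) R2/(1-R2) and the Wald identity", {
  expect_equal(f_statistic(0, 1000), 0)
  r2 <- variance_explained(0.3, 0.1, 0.01, 7824)
  expect_equal(f_statistic(r2, 7824, k = 1), 100, tolerance = 0.01)
  # asymptotic identity F ~ (beta/se)^2 for small r2, k = 1
  withr::with_seed(41, {
    for (rep in 1:20) {
      eaf <- runif(1, 0.05, 0.95); beta <- runif(1, 0.01, 0.1)
      se <- runif(1, 0.01, 0.05); n <- 50000
      r2 <- variance_explained(eaf, beta, se, n)
      if (r2 < 0.05) {
        expect_equal(f_statistic(r2, n, 1), (beta / se)^2, tolerance = 0.05)
      }
    }
  })
  # strictly increasing in r2
  f <- f_statistic(seq(0.001, 0.03, by = 0.001), 7824, 1)
  expect_true(all(diff(f) > 0))
  expect_error(f_statistic(0.01, 2, k = 1), "exceed")
})

test_that("instrument building composes the filters with monotone counts", {
  sim <- simulate_pair(scenario_config(n_snps = 10, beta_causal = 0.3,
                                       gamma_sd = 0.5, seed = 11))
  iv <- build_instrument_set(sim$exposure, ld_source(sim$ld))
  expect_equal(nrow(iv$instruments), 10)  # strong independent instruments all retained
  cnt <- iv$counts
  expect_true(cnt[["input"]] >= cnt[["after_pvalue"]] &&
                cnt[["after_pvalue"]] >= cnt[["after_clump"]] &&
                cnt[["after_clump"]] >= cnt[["final"]])
  expect_true(all(iv$instruments$f_stat >= 10))
  expect_true(all(iv$instruments$pval < 1e-5))
})

test_that("the weak-instrument filter is strict: F at the bound kept, below dropped", {
  # craft variants around F = 10 by inverting F = (n-2) r2/(1-r2) with
  # r2 = beta^2 / (beta^2 + n se^2)
  beta_for_f <- function(f, n, se) {
    ratio <- f / (n - 2)          # r2/(1-r2)
    sqrt(ratio * n * se^2)
  }
  n <- 1000L; se <- 0.01
  rec <- make_records(2)
  rec$chrom <- c("1", "2"); rec$pos <- c(1e6, 1e6)
  rec$se <- se; rec$n <- n
  rec$beta <- c(beta_for_f(10, n, se), beta_for_f(9.9, n, se))
  rec$pval <- 2 * pnorm(-abs(rec$beta / rec$se))
  tab <- study_table(rec, "t")
  # set the bound to the exactly-computed F of variant 1, so the boundary
  # case F == f_min exercises the strict "lower than" exclusion rule
  f1 <- f_statistic(variance_explained(rec$eaf[1], rec$beta[1], se, n), n, 1)
  expect_equal(f1, 10, tolerance = 1e-9)
  params <- instrument_params(p_threshold = 0.5, f_min = f1)
  iv <- build_instrument_set(tab, ld_source(NULL), params)
  expect_equal(iv$instruments$variant_id, rec$variant_id[1])
  expect_equal(iv$instruments$f_stat, 10, tolerance = 1e-9)
  # nudging the bound infinitesimally above F excludes the variant
  params$f_min <- f1 * (1 + 1e-12)
  iv2 <- suppressWarnings(build_instrument_set(tab, ld_source(NULL), params))
  expect_equal(nrow(iv2$instruments), 0)
})

test_that("an exposure with no surviving instruments warns and returns empty", {
  tab <- make_table(5, seed = 9)
  tab$records$pval <- 0.9
  expect_warning(iv <- build_instrument_set(tab, ld_source(NULL)),
                 "no instruments")
  expect_equal(nrow(iv$instruments), 0)
})
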