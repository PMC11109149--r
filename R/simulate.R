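#' Configuration for one synthetic exposure-outcome scenario
#'
#' Defines the generating conditions of a paired exposure/outcome GWAS
#' summary-statistics dataset with known causal truth. Defaults emulate the
#' statistical shape of a serum-metabolite MR screen against sepsis:
#' a continuous exposure study of 7824 individuals, a binary outcome study
#' of 486,484 individuals with 11,643 cases, between 7 and 37 instruments
#' per exposure, and per-variant expected F-statistics above 10.
#'
#' @param n_snps number of intended instruments; `NULL` (default) draws one
#'   value uniformly from 7..37 per scenario.
#' @param maf_range interval within (0, 0.5\] for minor-allele frequencies
#'   (default \[0.1, 0.45\]).
#' @param gamma_sd standard deviation of true SNP-exposure effects on the
#'   standardized-metabolite scale (default 0.15, which places typical
#'   expected per-variant F well above the weak-instrument bound).
#' @param n_exposure exposure study size (default 7824).
#' @param n_outcome outcome study size (default 486,484).
#' @param case_fraction case fraction of the binary outcome
#'   (default 11643/486484).
#' @param beta_causal true causal effect of the exposure on the outcome,
#'   log-odds per SD (default 0).
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of per-variant direct
#'   (horizontally pleiotropic) effects on the outcome; mean 0 with sd > 0
#'   is balanced pleiotropy, nonzero mean is directional (defaults 0, 0).
#' @param outlier_frac fraction of variants planted as gross pleiotropic
#'   outliers (default 0; the count is `round(outlier_frac * n_snps)`).
#' @param outlier_scale outlier offset in units of that variant's outcome
#'   standard error (default 10).
#' @param f_expected_min floor on the expected per-variant F-statistic when
#'   drawing true SNP-exposure effects (default 20, so that realized
#'   F-statistics essentially never drop below the conventional
#'   weak-instrument bound of 10, emulating a screen whose weakest retained
#'   instrument still had F well above 10).
#' @param ld_block_size number of LD decoy variants to add, each correlated
#'   with a distinct instrument, for exercising clumping (default 0).
#' @param ld_r2 pairwise r2 between a decoy and its parent instrument
#'   (default 0.5).
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_snps = NULL, maf_range = c(0.1, 0.45),
                            gamma_sd = 0.15, n_exposure = 7824,
                            n_outcome = 486484,
                            case_fraction = 11643 / 486484,
                            beta_causal = 0,
                            pleiotropy_mean = 0, pleiotropy_sd = 0,
                            outlier_frac = 0, outlier_scale = 10,
                            f_expected_min = 20,
                            ld_block_size = 0, ld_r2 = 0.5,
                            seed) {
  if (missing(seed) || !is_count(abs(seed) + 1)) {
    mr_abort("scenario_config requires an integer seed")
  }
  stopifnot(
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    gamma_sd >= 0, pleiotropy_sd >= 0,
    case_fraction > 0, case_fraction < 1,
    outlier_frac >= 0, outlier_frac <= 1
  )
  structure(
    list(
      n_snps = n_snps, maf_range = maf_range, gamma_sd = gamma_sd,
      n_exposure = n_exposure, n_outcome = n_outcome,
      case_fraction = case_fraction, beta_causal = beta_causal,
      pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
      outlier_frac = outlier_frac, outlier_scale = outlier_scale,
      f_expected_min = f_expected_min,
      ld_block_size = ld_block_size, ld_r2 = ld_r2,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

# non-palindromic allele pairs used for generated variants
SIM_ALLELE_PAIRS <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"),
                           ncol = 2, byrow = TRUE)

#' Simulate a paired exposure/outcome summary-statistics dataset
#'
#' Draws, per variant: a minor-allele frequency; a true SNP-exposure effect
#' whose magnitude is drawn from Normal(0, gamma_sd) and resampled until the
#' expected per-variant F-statistic n_exposure * R2/(1 - R2) (with
#' R2 = 2 maf (1-maf) gamma^2 on the standardized scale) exceeds
#' `f_expected_min`, matching the instrument regime of a metabolite GWAS
#' screen. The effect allele is oriented to the exposure-increasing allele
#' (gamma > 0), which gives directional pleiotropy a well-defined sign
#' relative to the instruments; an observed exposure effect gamma + noise with
#' se = 1/sqrt(2 maf (1-maf) n_exposure); a true outcome effect
#' beta_causal * gamma + alpha, where alpha is the horizontally pleiotropic
#' direct effect (offset by `outlier_scale` outcome-SEs, random sign, for
#' planted outliers); and an observed outcome effect with
#' se = 1/sqrt(2 maf (1-maf) n_outcome * cf * (1-cf)), the normal
#' approximation to a logistic GWAS on the log-odds scale. Variants are laid
#' out on two synthetic chromosomes, 2 Mb apart, so the intended instruments
#' are mutually independent under a 500 kb window; optional LD decoys are
#' placed 10 kb from their parent instrument with the configured r2.
#'
#' @param cfg a [scenario_config()].
#' @return A list: `exposure` and `outcome` [study_table()]s, `truth`
#'   (data frame of per-variant true `gamma_true`, `alpha`, `is_outlier`,
#'   `is_decoy` plus attributes-free columns `beta_causal` and `seed`), and
#'   `ld` (pairwise r2 data frame suitable for [ld_source()]).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(cfg$seed, {
    j <- cfg$n_snps %||% sample(7:37, 1)
    maf <- stats::runif(j, cfg$maf_range[1], cfg$maf_range[2])
    vx <- 2 * maf * (1 - maf)

    f_floor <- cfg$f_expected_min %||% 20
    gamma_true <- numeric(j)
    for (i in seq_len(j)) {
      ok <- FALSE
      for (attempt in seq_len(10000)) {
        g <- abs(stats::rnorm(1, 0, cfg$gamma_sd))
        r2 <- vx[i] * g^2
        if (r2 < 1 && cfg$n_exposure * r2 / (1 - r2) > f_floor) {
          gamma_true[i] <- g
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        mr_abort("gamma_sd too small to reach the expected-F floor at this n_exposure")
      }
    }

    se_g <- 1 / sqrt(vx * cfg$n_exposure)
    beta_x <- gamma_true + stats::rnorm(j, 0, se_g)

    cf <- cfg$case_fraction
    se_bg <- 1 / sqrt(vx * cfg$n_outcome * cf * (1 - cf))
    alpha <- stats::rnorm(j, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    n_out_planted <- round(cfg$outlier_frac * j)
    is_outlier <- rep(FALSE, j)
    if (n_out_planted > 0) {
      idx <- sample.int(j, n_out_planted)
      is_outlier[idx] <- TRUE
      alpha[idx] <- alpha[idx] +
        cfg$outlier_scale * se_bg[idx] * sample(c(-1, 1), n_out_planted, replace = TRUE)
    }
    big_gamma_true <- cfg$beta_causal * gamma_true + alpha
    beta_y <- big_gamma_true + stats::rnorm(j, 0, se_bg)

    pair_idx <- sample.int(nrow(SIM_ALLELE_PAIRS), j, replace = TRUE)
    variant_id <- sprintf("rs%d%04d", cfg$seed %% 100000L, seq_len(j))
    chrom <- as.character(1 + (seq_len(j) %% 2))
    pos <- 1000000L + as.integer(2e6) * as.integer(seq_len(j) %/% 2)

    rec_x <- data.frame(
      variant_id = variant_id, chrom = chrom, pos = pos,
      effect_allele = SIM_ALLELE_PAIRS[pair_idx, 1],
      other_allele = SIM_ALLELE_PAIRS[pair_idx, 2],
      eaf = maf, beta = beta_x, se = se_g,
      pval = p_from_z(beta_x / se_g), n = cfg$n_exposure
    )
    rec_y <- data.frame(
      variant_id = variant_id, chrom = chrom, pos = pos,
      effect_allele = SIM_ALLELE_PAIRS[pair_idx, 1],
      other_allele = SIM_ALLELE_PAIRS[pair_idx, 2],
      eaf = maf, beta = beta_y, se = se_bg,
      pval = p_from_z(beta_y / se_bg), n = cfg$n_outcome
    )
    truth <- data.frame(
      variant_id = variant_id, gamma_true = gamma_true, alpha = alpha,
      is_outlier = is_outlier, is_decoy = FALSE,
      beta_causal = cfg$beta_causal, seed = cfg$seed
    )
    ld <- data.frame(variant_id_a = character(), variant_id_b = character(),
                     r2 = numeric())

    n_decoys <- min(cfg$ld_block_size, j)
    if (n_decoys > 0) {
      di <- seq_len(n_decoys)
      decoy_id <- sprintf("%s_decoy", variant_id[di])
      att <- sqrt(cfg$ld_r2)
      g_dec <- att * gamma_true[di]
      se_dec <- se_g[di]
      beta_dec <- g_dec + stats::rnorm(n_decoys, 0, se_dec)
      rec_dec_x <- data.frame(
        variant_id = decoy_id, chrom = chrom[di], pos = pos[di] + 10000L,
        effect_allele = SIM_ALLELE_PAIRS[pair_idx[di], 1],
        other_allele = SIM_ALLELE_PAIRS[pair_idx[di], 2],
        eaf = maf[di], beta = beta_dec, se = se_dec,
        pval = p_from_z(beta_dec / se_dec), n = cfg$n_exposure
      )
      bg_dec <- cfg$beta_causal * g_dec
      beta_dec_y <- bg_dec + stats::rnorm(n_decoys, 0, se_bg[di])
      rec_dec_y <- data.frame(
        variant_id = decoy_id, chrom = chrom[di], pos = pos[di] + 10000L,
        effect_allele = SIM_ALLELE_PAIRS[pair_idx[di], 1],
        other_allele = SIM_ALLELE_PAIRS[pair_idx[di], 2],
        eaf = maf[di], beta = beta_dec_y, se = se_bg[di],
        pval = p_from_z(beta_dec_y / se_bg[di]), n = cfg$n_outcome
      )
      rec_x <- rbind(rec_x, rec_dec_x)
      rec_y <- rbind(rec_y, rec_dec_y)
      truth <- rbind(truth, data.frame(
        variant_id = decoy_id, gamma_true = g_dec, alpha = 0,
        is_outlier = FALSE, is_decoy = TRUE,
        beta_causal = cfg$beta_causal, seed = cfg$seed
      ))
      ld <- data.frame(
        variant_id_a = variant_id[di], variant_id_b = decoy_id,
        r2 = cfg$ld_r2
      )
    }

    exposure <- study_table(
      rec_x, trait_id = sprintf("sim_exposure_%d", cfg$seed),
      trait_name = "synthetic metabolite", trait_type = "continuous",
      n_total = cfg$n_exposure
    )
    outcome <- study_table(
      rec_y, trait_id = sprintf("sim_outcome_%d", cfg$seed),
      trait_name = "synthetic binary outcome", trait_type = "binary",
      n_total = cfg$n_outcome,
      n_cases = round(cfg$case_fraction * cfg$n_outcome)
    )
    list(exposure = exposure, outcome = outcome, truth = truth, ld = ld)
  })
}

#' Simulate a multi-exposure screening batch
#'
#' Generates `n_exposures` scenarios from a template configuration, with a
#' designated subset of truly causal exposures (the rest are generated with
#' `beta_causal = 0`). Per-exposure seeds are derived deterministically as
#' `cfg$seed + index`.
#'
#' @param n_exposures number of exposures to simulate.
#' @param causal_ids character vector of exposure ids (of the form
#'   `met_001`, ...) to generate as causal with the template's
#'   `beta_causal`.
#' @param cfg template [scenario_config()]; its `beta_causal` is the causal
#'   exposures' effect.
#' @return A list: `scenarios` (named list of [simulate_pair()] outputs) and
#'   `manifest` (data frame: `exposure_id`, `beta_causal`, `n_snps`,
#'   `seed`).
#' @export
simulate_batch <- function(n_exposures, causal_ids = character(), cfg) {
  stopifnot(inherits(cfg, "scenario_config"), is_count(n_exposures))
  ids <- sprintf("met_%03d", seq_len(n_exposures))
  if (!all(causal_ids %in% ids)) {
    mr_abort("causal_ids must be a subset of the generated exposure ids")
  }
  scenarios <- vector("list", n_exposures)
  names(scenarios) <- ids
  manifest <- vector("list", n_exposures)
  for (i in seq_len(n_exposures)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    cfg_i$beta_causal <- if (ids[i] %in% causal_ids) cfg$beta_causal else 0
    sc <- simulate_pair(cfg_i)
    sc$exposure$trait_id <- ids[i]
    scenarios[[i]] <- sc
    manifest[[i]] <- data.frame(
      exposure_id = ids[i], beta_causal = cfg_i$beta_causal,
      n_snps = sum(!sc$truth$is_decoy), seed = cfg_i$seed
    )
  }
  list(scenarios = scenarios, manifest = do.call(rbind, manifest))
}
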