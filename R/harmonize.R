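ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) {
  chartr("ACGT", "TGCA", x)
}

is_palindromic <- function(a1, a2) {
  a2 == complement_allele(a1)
}

#' Align exposure instruments and outcome associations to a common allele
#'
#' For each instrument, locates the same variant in the outcome table and
#' re-expresses the outcome effect per copy of the exposure's effect allele,
#' yielding the per-variant (gamma, Gamma) pairs that every MR estimator
#' consumes. Variants absent from the outcome are dropped
#' (`missing_in_outcome`); allele pairs that match after swapping
#' effect/other have their outcome beta negated and frequency reflected
#' (`flipped = TRUE`); strand-complement representations are complemented
#' first; incompatible pairs are dropped (`allele_mismatch`).
#'
#' Palindromic variants (A/T, C/G) cannot be strand-resolved from alleles
#' alone and are handled per `palindrome_policy`:
#' \describe{
#'   \item{`"infer_by_eaf"` (default)}{align by allele-frequency agreement,
#'     but drop when either study's EAF lies within `ambiguity_window` of
#'     0.5 (default window 0.08, i.e. EAF in \[0.42, 0.58\]), where
#'     frequency carries no strand information.}
#'   \item{`"drop"`}{always drop (`palindromic_ambiguous`).}
#'   \item{`"keep"`}{align by allele labels as if strand were known.}
#' }
#'
#' The exposure's EAF remains authoritative for instrument strength; the
#' outcome EAF is used only for palindrome inference.
#'
#' @param instruments an `instrument_set` from [build_instrument_set()], or a
#'   [study_table()] whose records are all instruments.
#' @param outcome outcome [study_table()].
#' @param palindrome_policy `"infer_by_eaf"`, `"drop"`, or `"keep"`.
#' @param ambiguity_window half-width of the EAF ambiguity band around 0.5.
#' @return An object of class `harmonized_set` with elements `exposure_id`,
#'   `outcome_id`, `variants` (columns `variant_id`, `gamma`, `se_gamma`,
#'   `big_gamma`, `se_big_gamma`, `flipped`) and `drop_log`
#'   (`variant_id`, `reason`).
#' @export
harmonize <- function(instruments, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop", "keep"),
                      ambiguity_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(outcome, "study_table"))
  if (inherits(instruments, "instrument_set")) {
    exp_rec <- instruments$instruments
    exposure_id <- instruments$exposure_id
  } else if (inherits(instruments, "study_table")) {
    exp_rec <- instruments$records
    exposure_id <- instruments$trait_id
  } else {
    mr_abort("instruments must be an instrument_set or study_table")
  }
  out_rec <- outcome$records
  out_idx <- match(exp_rec$variant_id, out_rec$variant_id)

  kept <- list()
  dropped <- list()
  for (i in seq_len(nrow(exp_rec))) {
    vid <- exp_rec$variant_id[i]
    j <- out_idx[i]
    if (is.na(j)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(variant_id = vid, reason = "missing_in_outcome")
      next
    }
    ea_x <- exp_rec$effect_allele[i]; oa_x <- exp_rec$other_allele[i]
    ea_y <- out_rec$effect_allele[j]; oa_y <- out_rec$other_allele[j]
    beta_y <- out_rec$beta[j]
    eaf_y <- out_rec$eaf[j]

    pal <- is_palindromic(ea_x, oa_x)
    action <- NULL  # "keep", "flip", or a drop reason
    if (pal) {
      same <- (ea_y == ea_x && oa_y == oa_x) ||
        (ea_y == complement_allele(ea_x) && oa_y == complement_allele(oa_x))
      swapped <- (ea_y == oa_x && oa_y == ea_x)
      if (!(same || swapped)) {
        action <- "allele_mismatch"
      } else if (palindrome_policy == "drop") {
        action <- "palindromic_ambiguous"
      } else if (palindrome_policy == "keep") {
        # for a palindrome same-orientation and complement coincide; trust labels
        action <- if (ea_y == ea_x) "keep" else "flip"
      } else {  # infer_by_eaf
        ambiguous <- abs(exp_rec$eaf[i] - 0.5) <= ambiguity_window ||
          abs(eaf_y - 0.5) <= ambiguity_window
        if (ambiguous) {
          action <- "palindromic_ambiguous"
        } else {
          # same strand orientation iff both studies report the minor (or
          # both the major) allele as effect allele
          action <- if ((exp_rec$eaf[i] < 0.5) == (eaf_y < 0.5)) "keep" else "flip"
        }
      }
    } else {
      if (ea_y == ea_x && oa_y == oa_x) {
        action <- "keep"
      } else if (ea_y == oa_x && oa_y == ea_x) {
        action <- "flip"
      } else if (complement_allele(ea_y) == ea_x &&
                 complement_allele(oa_y) == oa_x) {
        action <- "keep"
      } else if (complement_allele(ea_y) == oa_x &&
                 complement_allele(oa_y) == ea_x) {
        action <- "flip"
      } else {
        action <- "allele_mismatch"
      }
    }

    if (action %in% c("keep", "flip")) {
      flip <- action == "flip"
      kept[[length(kept) + 1L]] <- data.frame(
        variant_id = vid,
        gamma = exp_rec$beta[i],
        se_gamma = exp_rec$se[i],
        big_gamma = if (flip) -beta_y else beta_y,
        se_big_gamma = out_rec$se[j],
        eaf_outcome = if (flip) 1 - eaf_y else eaf_y,
        flipped = flip
      )
    } else {
      dropped[[length(dropped) + 1L]] <-
        data.frame(variant_id = vid, reason = action)
    }
  }

  empty_var <- data.frame(
    variant_id = character(), gamma = numeric(), se_gamma = numeric(),
    big_gamma = numeric(), se_big_gamma = numeric(), eaf_outcome = numeric(),
    flipped = logical()
  )
  structure(
    list(
      exposure_id = exposure_id,
      outcome_id = outcome$trait_id,
      variants = if (length(kept)) do.call(rbind, kept) else empty_var,
      drop_log = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(variant_id = character(), reason = character())
    ),
    class = "harmonized_set"
  )
}

#' Construct a harmonized set directly from effect vectors
#'
#' Convenience constructor for simulation studies and tests where the
#' variant-level effects are already aligned.
#'
#' @param gamma,se_gamma SNP-exposure effects and standard errors.
#' @param big_gamma,se_big_gamma SNP-outcome effects and standard errors
#'   (log-odds scale for binary outcomes).
#' @param variant_id optional identifiers (defaults `snp_1`, `snp_2`, ...).
#' @param exposure_id,outcome_id trait labels.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(gamma, se_gamma, big_gamma, se_big_gamma,
                           variant_id = NULL,
                           exposure_id = "exposure", outcome_id = "outcome") {
  stopifnot(length(gamma) == length(se_gamma),
            length(gamma) == length(big_gamma),
            length(gamma) == length(se_big_gamma))
  if (any(se_gamma <= 0) || any(se_big_gamma <= 0)) {
    mr_abort("standard errors must be > 0")
  }
  variant_id <- variant_id %||% sprintf("snp_%d", seq_along(gamma))
  structure(
    list(
      exposure_id = exposure_id,
      outcome_id = outcome_id,
      variants = data.frame(
        variant_id = variant_id, gamma = gamma, se_gamma = se_gamma,
        big_gamma = big_gamma, se_big_gamma = se_big_gamma,
        eaf_outcome = NA_real_, flipped = FALSE
      ),
      drop_log = data.frame(variant_id = character(), reason = character())
    ),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d variants retained, %d dropped\n",
              x$exposure_id, x$outcome_id, nrow(x$variants), nrow(x$drop_log)))
  invisible(x)
}
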