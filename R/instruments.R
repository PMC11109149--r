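#' Subset a summary-statistics table by association p-value
#'
#' Keeps exactly the records with `pval < p_threshold` (strict inequality),
#' preserving row order. The conventional threshold for metabolite GWAS
#' instrument discovery is 1e-5.
#'
#' @param table a [study_table()].
#' @param p_threshold p-value threshold in (0, 1).
#' @return A [study_table()] with the retained records.
#' @export
select_by_pvalue <- function(table, p_threshold = 1e-5) {
  stopifnot(inherits(table, "study_table"))
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    mr_abort("p_threshold must lie in (0, 1)")
  }
  keep <- table$records$pval < p_threshold
  out <- table
  out$records <- table$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Pairwise LD lookup source
#'
#' Wraps a three-column table (`variant_id_a`, `variant_id_b`, `r2`) of
#' pairwise squared correlations into a lookup object. The symmetric closure
#' is implied; self-pairs return 1. A pair that clumping needs but that is
#' absent from the table is an error, never a silent zero, so an incomplete
#' LD panel cannot masquerade as independence.
#'
#' @param pairs data frame with columns `variant_id_a`, `variant_id_b`, `r2`
#'   (each `r2` in \[0, 1\]).
#' @return An object of class `ld_source`.
#' @export
ld_source <- function(pairs) {
  if (is.null(pairs) || (is.data.frame(pairs) && nrow(pairs) == 0)) {
    pairs <- data.frame(variant_id_a = character(), variant_id_b = character(),
                        r2 = numeric())
  }
  stopifnot(all(c("variant_id_a", "variant_id_b", "r2") %in% names(pairs)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) mr_abort("LD r2 must lie in [0, 1]")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  env <- new.env(parent = emptyenv())
  if (nrow(pairs)) {
    k <- key(as.character(pairs$variant_id_a), as.character(pairs$variant_id_b))
    for (i in seq_along(k)) assign(k[i], pairs$r2[i], envir = env)
  }
  structure(list(env = env, key = key), class = "ld_source")
}

#' Read an LD matrix file
#'
#' Tab-separated, three columns: `variant_id_a`, `variant_id_b`, `r2`.
#' @param path file path.
#' @return An [ld_source()].
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) mr_abort(sprintf("file not found: %s", path))
  ld_source(read_tsv(path))
}

#' Look up pairwise LD r-squared
#'
#' @param ld an [ld_source()].
#' @param a,b variant identifiers (vectorized, recycled).
#' @return Numeric vector of r2 values; errors on a missing pair.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_source"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (a[i] == b[i]) {
      out[i] <- 1
      next
    }
    k <- ld$key(a[i], b[i])
    if (!exists(k, envir = ld$env, inherits = FALSE)) {
      mr_abort(sprintf("LD r2 unavailable for pair %s - %s", a[i], b[i]))
    }
    out[i] <- get(k, envir = ld$env, inherits = FALSE)
  }
  out
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining variant with the lowest p-value and removes
#' every other remaining variant on the same chromosome within `window_kb`
#' whose r2 with it is `>= r2_max`. Variants on different chromosomes or
#' beyond the window are treated as independent (r2 = 0) without consulting
#' the LD source. Ties on p-value are broken by (chrom, pos), lowest first,
#' so the result is deterministic.
#'
#' @param table a [study_table()] (typically the output of
#'   [select_by_pvalue()]).
#' @param ld an [ld_source()]; must cover every same-chromosome pair within
#'   the window.
#' @param r2_max LD pruning threshold (default 0.01).
#' @param window_kb clumping window in kilobases (default 500).
#' @return A [study_table()] of mutually independent variants, in the
#'   original row order.
#' @export
ld_clump <- function(table, ld, r2_max = 0.01, window_kb = 500) {
  stopifnot(inherits(table, "study_table"))
  rec <- table$records
  if (nrow(rec) <= 1) return(table)
  ord <- order(rec$pval, rec$chrom, rec$pos)
  window_bp <- window_kb * 1000
  alive <- rep(TRUE, nrow(rec))
  kept <- logical(nrow(rec))
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & rec$chrom == rec$chrom[i] &
                    abs(rec$pos - rec$pos[i]) <= window_bp)
    if (length(cand)) {
      r2 <- ld_r2(ld, rec$variant_id[i], rec$variant_id[cand])
      alive[cand[r2 >= r2_max]] <- FALSE
    }
  }
  out <- table
  out$records <- rec[kept, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Per-variant proportion of exposure variance explained
#'
#' R2 = 2 EAF (1-EAF) beta^2 / (2 EAF (1-EAF) beta^2 + 2 EAF (1-EAF) N se^2),
#' the standard summary-statistic approximation for a variant's contribution
#' to a standardized continuous exposure. Vectorized.
#'
#' @param eaf effect-allele frequency, strictly inside (0, 1).
#' @param beta per-allele effect estimate.
#' @param se standard error of `beta`, > 0.
#' @param n study sample size.
#' @return R2 values in \[0, 1).
#' @export
variance_explained <- function(eaf, beta, se, n) {
  if (any(eaf <= 0 | eaf >= 1)) {
    mr_abort("eaf must lie strictly inside (0, 1)")
  }
  if (any(se <= 0)) mr_abort("se must be > 0")
  if (any(n <= 0)) mr_abort("n must be > 0")
  v <- 2 * eaf * (1 - eaf)
  num <- v * beta^2
  num / (num + v * n * se^2)
}

#' Instrument-strength F-statistic
#'
#' F = ((N - K - 1) / K) * (R2 / (1 - R2)). For the per-variant weak
#' instrument filter this is called with `k = 1` and that variant's R2;
#' F below 10 conventionally marks a weak instrument.
#'
#' @param r2 variance explained, in \[0, 1).
#' @param n sample size; must exceed `k + 1`.
#' @param k number of instruments in the model (default 1).
#' @return F values, >= 0. Vectorized over `r2`.
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1)) mr_abort("r2 must lie in [0, 1)")
  if (any(n <= k + 1)) mr_abort("n must exceed k + 1")
  ((n - k - 1) / k) * (r2 / (1 - r2))
}

#' Instrument-selection parameters
#'
#' Defaults are the standard settings of metabolite-GWAS MR screens:
#' association p < 1e-5, pairwise LD r2 < 0.01 within 500 kb, and per-variant
#' F >= 10.
#'
#' @param p_threshold association p-value threshold.
#' @param r2_max LD pruning threshold.
#' @param window_kb clumping window in kilobases.
#' @param f_min minimum per-variant F-statistic (variants with F strictly
#'   below this are excluded).
#' @return A named list of class `instrument_params`.
#' @export
instrument_params <- function(p_threshold = 1e-5, r2_max = 0.01,
                              window_kb = 500, f_min = 10) {
  structure(
    list(p_threshold = p_threshold, r2_max = r2_max,
         window_kb = window_kb, f_min = f_min),
    class = "instrument_params"
  )
}

#' Select genetic instruments for one exposure
#'
#' Composes the full selection: p-value filter, greedy LD clumping,
#' per-variant R2 and F (with `k = 1`), and the weak-instrument exclusion
#' `F < f_min`. Per-stage counts are recorded for the run log.
#'
#' @param table exposure [study_table()].
#' @param ld an [ld_source()].
#' @param params an [instrument_params()] list.
#' @return An object of class `instrument_set`: `exposure_id`,
#'   `instruments` (variant records plus `r2` and `f_stat` columns),
#'   `selection_params`, and per-stage `counts`. Empty sets are returned
#'   with a warning rather than an error, so a screen can skip the exposure.
#' @export
build_instrument_set <- function(table, ld, params = instrument_params()) {
  stopifnot(inherits(table, "study_table"))
  n_input <- nrow(table$records)
  sig <- select_by_pvalue(table, params$p_threshold)
  clumped <- ld_clump(sig, ld, r2_max = params$r2_max,
                      window_kb = params$window_kb)
  rec <- clumped$records
  if (nrow(rec)) {
    rec$r2 <- variance_explained(rec$eaf, rec$beta, rec$se, rec$n)
    rec$f_stat <- f_statistic(rec$r2, rec$n, k = 1)
    rec <- rec[rec$f_stat >= params$f_min, , drop = FALSE]
    rownames(rec) <- NULL
  } else {
    rec$r2 <- numeric(0)
    rec$f_stat <- numeric(0)
  }
  if (nrow(rec) == 0) {
    warning(sprintf("no instruments survive selection for exposure '%s'",
                    table$trait_id), call. = FALSE)
  }
  structure(
    list(
      exposure_id = table$trait_id,
      instruments = rec,
      selection_params = params,
      counts = c(input = n_input, after_pvalue = nrow(sig$records),
                 after_clump = nrow(clumped$records), final = nrow(rec))
    ),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "<instrument_set> %s: %d instruments (input %d -> p-filter %d -> clump %d -> F-filter %d)\n",
    x$exposure_id, nrow(x$instruments), x$counts[["input"]],
    x$counts[["after_pvalue"]], x$counts[["after_clump"]], x$counts[["final"]]
  ))
  invisible(x)
}
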