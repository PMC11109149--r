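#' @keywords internal
"_PACKAGE"

# canonical column order of the on-disk summary-statistics dialect
SUMSTATS_COLUMNS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)

#' Construct a GWAS summary-statistics table
#'
#' A `study_table` bundles per-variant association records for one trait with
#' the trait metadata (identifier, type, study sizes) that downstream modules
#' need: instrument selection reads `n` per variant, harmonization reads the
#' alleles and allele frequencies, and the estimators consume betas and
#' standard errors on the linear scale for continuous traits and on the
#' log-odds scale for binary traits.
#'
#' @param records data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   Alleles are upcased; rows are kept in input order.
#' @param trait_id short machine identifier of the trait.
#' @param trait_name human-readable trait name (defaults to `trait_id`).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n_total total study sample size.
#' @param n_cases number of cases; required iff `trait_type = "binary"`.
#' @return An object of class `study_table`.
#' @export
study_table <- function(records, trait_id, trait_name = trait_id,
                        trait_type = c("continuous", "binary"),
                        n_total = NULL, n_cases = NULL) {
  trait_type <- match.arg(trait_type)
  records <- validate_variant_records(records)
  if (is.null(n_total)) {
    n_total <- if (nrow(records)) max(records$n) else NA_integer_
  }
  if (trait_type == "binary") {
    if (is.null(n_cases)) {
      mr_abort("binary trait requires n_cases")
    }
    if (!is.null(n_total) && !is.na(n_total) &&
        (n_cases <= 0 || n_cases >= n_total)) {
      mr_abort("n_cases must satisfy 0 < n_cases < n_total")
    }
  }
  structure(
    list(
      trait_id = as.character(trait_id),
      trait_name = as.character(trait_name),
      trait_type = trait_type,
      n_total = as.integer(n_total),
      n_cases = if (is.null(n_cases)) NA_integer_ else as.integer(n_cases),
      records = records
    ),
    class = "study_table"
  )
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf(
    "<study_table> %s (%s, %s), %d variants, n_total = %s%s\n",
    x$trait_id, x$trait_name, x$trait_type, nrow(x$records),
    format(x$n_total, big.mark = ","),
    if (!is.na(x$n_cases)) sprintf(", n_cases = %s", format(x$n_cases, big.mark = ",")) else ""
  ))
  invisible(x)
}

# Validate and canonicalize per-variant records; errors carry row indices.
validate_variant_records <- function(records) {
  if (!is.data.frame(records)) mr_abort("records must be a data frame")
  missing_cols <- setdiff(SUMSTATS_COLUMNS, names(records))
  if (length(missing_cols)) {
    mr_abort(sprintf("missing mandatory column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }
  records <- records[SUMSTATS_COLUMNS]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    coerced <- suppressWarnings(as.numeric(records[[col]]))
    bad <- which(is.na(coerced) & !is.na(records[[col]]))
    if (length(bad)) {
      mr_abort(sprintf("column '%s' fails numeric coercion", col), bad)
    }
    na_rows <- which(is.na(coerced))
    if (length(na_rows)) {
      mr_abort(sprintf("column '%s' has missing values", col), na_rows)
    }
    records[[col]] <- coerced
  }
  records$pos <- as.integer(records$pos)
  records$n <- as.integer(records$n)

  dup <- duplicated(records$variant_id)
  if (any(dup)) {
    mr_abort(sprintf("duplicate variant_id: %s",
                     paste(unique(records$variant_id[dup]), collapse = ", ")))
  }
  checks <- list(
    "eaf outside [0,1]" = records$eaf < 0 | records$eaf > 1,
    "se must be > 0" = records$se <= 0,
    "pval outside (0,1]" = records$pval <= 0 | records$pval > 1,
    "effect_allele equals other_allele" =
      records$effect_allele == records$other_allele,
    "pos must be a positive integer" = records$pos < 1,
    "n must be a positive integer" = records$n < 1
  )
  for (msg in names(checks)) {
    bad <- which(checks[[msg]])
    if (length(bad)) mr_abort(msg, bad)
  }
  rownames(records) <- NULL
  records
}

sidecar_path <- function(path) paste0(path, ".meta")

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited summary-statistics file into a validated [study_table()].
#' The delimiter (tab or comma) is detected from the header line unless
#' declared in `dialect$sep`. Trait metadata is taken, in order of precedence,
#' from the `meta` argument, from a `<path>.meta` sidecar file of
#' `key=value` lines (`trait_id`, `trait_name`, `trait_type`, `n_total`,
#' `n_cases`), or from defaults (file stem as id, continuous trait, maximum
#' per-variant `n` as the study size).
#'
#' @param path file to read.
#' @param dialect optional named list/vector mapping canonical column names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the column names used in the file; may also
#'   carry a `sep` entry (`"\t"` or `","`).
#' @param meta optional named list of trait metadata overriding the sidecar.
#' @return A [study_table()].
#' @export
read_sumstats <- function(path, dialect = NULL, meta = NULL) {
  if (!file.exists(path)) mr_abort(sprintf("file not found: %s", path))
  dialect <- as.list(dialect)
  sep <- dialect$sep
  dialect$sep <- NULL
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "")
  # apply dialect renames (canonical <- file column)
  for (canon in names(dialect)) {
    src <- dialect[[canon]]
    if (!src %in% names(raw)) {
      mr_abort(sprintf("dialect maps '%s' to missing column '%s'", canon, src))
    }
    names(raw)[names(raw) == src] <- canon
  }
  missing_cols <- setdiff(SUMSTATS_COLUMNS, names(raw))
  if (length(missing_cols)) {
    mr_abort(sprintf("missing mandatory column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }

  side <- sidecar_path(path)
  side_meta <- if (file.exists(side)) read_keyvalue(side) else list()
  meta <- utils::modifyList(side_meta, as.list(meta))
  trait_id <- meta$trait_id %||% sub("\\.[^.]*$", "", basename(path))
  study_table(
    records = raw,
    trait_id = trait_id,
    trait_name = meta$trait_name %||% trait_id,
    trait_type = meta$trait_type %||% "continuous",
    n_total = if (!is.null(meta$n_total)) as.integer(meta$n_total) else NULL,
    n_cases = if (!is.null(meta$n_cases)) as.integer(meta$n_cases) else NULL
  )
}

#' Write a GWAS summary-statistics table
#'
#' Writes the canonical tab-delimited serialization (fixed header, one row per
#' variant) plus a `<path>.meta` sidecar with the trait metadata, such that
#' `read_sumstats(write_sumstats(t))` reproduces `t` field by field.
#'
#' @param table a [study_table()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "study_table"))
  out <- table$records
  # full precision so the round trip is lossless to double resolution
  for (col in c("eaf", "beta", "se", "pval")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  write_tsv(out, path)
  meta <- c(
    trait_id = table$trait_id,
    trait_name = table$trait_name,
    trait_type = table$trait_type,
    n_total = as.character(table$n_total),
    if (!is.na(table$n_cases)) c(n_cases = as.character(table$n_cases))
  )
  writeLines(paste0(names(meta), "=", meta), sidecar_path(path))
  invisible(path)
}

read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  out <- lapply(kv, function(x) trimws(x[2]))
  names(out) <- vapply(kv, function(x) trimws(x[1]), character(1))
  out
}
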