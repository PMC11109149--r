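`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() without the call, with optional offending row indices
mr_abort <- function(msg, rows = NULL) {
  if (!is.null(rows) && length(rows)) {
    msg <- sprintf("%s [rows: %s]", msg, paste(rows, collapse = ", "))
  }
  stop(msg, call. = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# two-sided normal p for z; guarded away from exact 0 so p stays in (0, 1]
p_from_z <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x > 0 && x == round(x)
}
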