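#' Construct a metabolite pathway library
#'
#' A pathway library maps pathway names to sets of compound identifiers
#' (e.g. KEGG C-numbers) over a declared background metabolome -- the
#' population from which the hypergeometric over-representation test draws.
#'
#' @param pathways named list of character vectors of compound ids; every
#'   pathway must be non-empty.
#' @param background character vector of all mappable compound ids; defaults
#'   to the union of the pathway members. Every pathway member must belong
#'   to the background.
#' @return An object of class `pathway_library`.
#' @export
pathway_library <- function(pathways, background = NULL) {
  stopifnot(is.list(pathways), length(pathways) > 0, !is.null(names(pathways)))
  pathways <- lapply(pathways, function(x) unique(as.character(x)))
  if (any(lengths(pathways) == 0)) mr_abort("pathways must be non-empty")
  members <- unique(unlist(pathways, use.names = FALSE))
  if (is.null(background)) {
    background <- members
  } else {
    background <- unique(as.character(background))
    stray <- setdiff(members, background)
    if (length(stray)) {
      mr_abort(sprintf("pathway compound(s) absent from background: %s",
                       paste(utils::head(stray, 5), collapse = ", ")))
    }
  }
  structure(list(pathways = pathways, background = background),
            class = "pathway_library")
}

#' @export
print.pathway_library <- function(x, ...) {
  cat(sprintf("<pathway_library> %d pathways over a background of %d compounds\n",
              length(x$pathways), length(x$background)))
  invisible(x)
}

#' Load a pathway library from a compound-set file
#'
#' One pathway per line, tab-separated: name, description, then the member
#' compound ids (a GMT-like dialect). An optional line starting with
#' `#BACKGROUND` followed by tab-separated ids declares the background
#' metabolome explicitly; otherwise the background is the union of all
#' pathway members.
#'
#' @param path file to read.
#' @return A [pathway_library()].
#' @export
load_pathway_library <- function(path) {
  if (!file.exists(path)) mr_abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  background <- NULL
  pathways <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (fields[1] == "#BACKGROUND") {
      background <- fields[-1]
      next
    }
    if (startsWith(fields[1], "#")) next
    if (length(fields) < 3) {
      mr_abort(sprintf("malformed pathway line %d: need name, description, members", i))
    }
    pathways[[fields[1]]] <- fields[-(1:2)]
  }
  if (!length(pathways)) mr_abort("no pathways found in file")
  pathway_library(pathways, background)
}

#' Write a pathway library to a compound-set file
#'
#' Inverse of [load_pathway_library()].
#'
#' @param lib a [pathway_library()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_pathway_library <- function(lib, path) {
  stopifnot(inherits(lib, "pathway_library"))
  lines <- c(
    paste(c("#BACKGROUND", lib$background), collapse = "\t"),
    vapply(names(lib$pathways), function(nm) {
      paste(c(nm, nm, lib$pathways[[nm]]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Metabolite-set over-representation analysis
#'
#' For each pathway of size m over a background of N compounds, tests
#' whether the n mapped query compounds overlap the pathway more than
#' expected by chance: the one-sided upper-tail hypergeometric probability
#' P(X >= k) of the observed k hits, with expected overlap n*m/N. Query ids
#' absent from the background are logged via a warning and excluded from n.
#' A pathway is called significant when p < `alpha` and, if a topology
#' `impact` score is supplied for it, that score exceeds `impact_min`
#' (impact scores are externally computed pathway-topology centralities
#' and are consumed, never derived, here).
#'
#' @param query character vector of candidate compound ids.
#' @param lib a [pathway_library()].
#' @param impact optional named numeric vector of topology impact scores,
#'   named by pathway.
#' @param alpha significance level for the enrichment p (default 0.05).
#' @param impact_min minimum impact for significance when impact is supplied
#'   (default 0.1).
#' @return A data frame sorted by p-value: `pathway_name`, `total`,
#'   `query_size`, `expected`, `hits`, `impact`, `pval`, `significant`.
#'   The vector of unmapped query ids is attached as attribute `unmapped`.
#' @export
over_representation <- function(query, lib, impact = NULL,
                                alpha = 0.05, impact_min = 0.1) {
  stopifnot(inherits(lib, "pathway_library"))
  query <- unique(as.character(query))
  mapped <- intersect(query, lib$background)
  unmapped <- setdiff(query, lib$background)
  if (length(unmapped)) {
    warning(sprintf("%d query id(s) not in background, excluded: %s",
                    length(unmapped), paste(unmapped, collapse = ", ")),
            call. = FALSE)
  }
  if (!length(mapped)) {
    warning("empty mapped query; no enrichment computed", call. = FALSE)
    out <- data.frame(pathway_name = character(), total = integer(),
                      query_size = integer(), expected = numeric(),
                      hits = integer(), impact = numeric(), pval = numeric(),
                      significant = logical())
    attr(out, "unmapped") <- unmapped
    return(out)
  }
  n_bg <- length(lib$background)
  n <- length(mapped)
  rows <- lapply(names(lib$pathways), function(nm) {
    m <- length(lib$pathways[[nm]])
    k <- length(intersect(mapped, lib$pathways[[nm]]))
    # upper tail P(X >= k): phyper counts successes in n draws from m of n_bg
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, m, n_bg - m, n, lower.tail = FALSE)
    imp <- if (!is.null(impact) && nm %in% names(impact)) impact[[nm]] else NA_real_
    data.frame(
      pathway_name = nm, total = m, query_size = n,
      expected = n * m / n_bg, hits = k, impact = imp, pval = p,
      significant = p < alpha & (is.na(imp) | imp > impact_min)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pval, out$pathway_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}
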