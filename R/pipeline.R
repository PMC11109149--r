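#' Read a pipeline run configuration
#'
#' YAML with keys: `out_dir`; `seed`; optional `params`
#' (`p_threshold`, `r2_max`, `window_kb`, `f_min`), `alpha`, `m_tests`,
#' `n_boot`, `n_sim`; `exposures` (list of `id`, optional `name`,
#' `super_pathway`, and `path` to a summary-statistics file); `ld` (path to
#' an LD matrix file); `outcomes` (list of `id`, `path`); optional
#' `reverse: true`; optional `pathway` (`library` path, `compound_map`
#' mapping exposure ids to compound ids, optional `impact` map). Relative
#' paths are resolved against the config file's directory. Every referenced
#' path must exist.
#'
#' @param path YAML file.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) mr_abort(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  }
  for (i in seq_along(cfg$exposures)) {
    cfg$exposures[[i]]$path <- resolve(cfg$exposures[[i]]$path)
  }
  for (i in seq_along(cfg$outcomes)) {
    cfg$outcomes[[i]]$path <- resolve(cfg$outcomes[[i]]$path)
  }
  cfg$ld <- resolve(cfg$ld)
  if (!is.null(cfg$pathway)) cfg$pathway$library <- resolve(cfg$pathway$library)
  cfg$out_dir <- resolve(cfg$out_dir) %||% file.path(base, "mr_run")
  paths <- c(vapply(cfg$exposures, `[[`, character(1), "path"),
             vapply(cfg$outcomes, `[[`, character(1), "path"),
             cfg$ld, cfg$pathway$library)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    mr_abort(sprintf("referenced path(s) do not exist: %s",
                     paste(missing, collapse = ", ")))
  }
  if (is.null(cfg$seed)) mr_abort("run config must declare a seed")
  structure(cfg, class = "run_config")
}

load_entry_table <- function(entry, what) {
  if (!is.null(entry$table)) return(entry$table)
  if (is.null(entry$path)) {
    mr_abort(sprintf("%s entry '%s' has neither a table nor a path",
                     what, entry$id %||% "?"))
  }
  tab <- read_sumstats(entry$path)
  if (!is.null(entry$id)) tab$trait_id <- entry$id
  if (!is.null(entry$name)) tab$trait_name <- entry$name
  tab
}

stage_guard <- function(stage, exposure_id, expr) {
  tryCatch(expr, error = function(e) {
    mr_abort(sprintf("pipeline stage '%s' failed for exposure '%s': %s",
                     stage, exposure_id, conditionMessage(e)))
  })
}

#' Run the full MR screening pipeline
#'
#' Orchestrates, per outcome: instrument selection for every exposure,
#' harmonization, the four estimators, the sensitivity diagnostics, the
#' multi-criterion candidate screen with its Bonferroni tier, optional
#' reverse MR for the screened candidates, and optional pathway
#' over-representation of the candidates' compound ids. Writes one set of
#' tab-delimited reports per outcome into `out_dir` plus a structured run
#' log; a rerun with an identical configuration reproduces every output
#' byte for byte. Exposures whose instrument set is empty or too small for
#' the estimators are reported in the log and the decision table (as
#' unevaluable), never silently dropped.
#'
#' @param cfg a `run_config` from [read_run_config()], or an equivalent
#'   list; for in-memory use, exposure/outcome entries may carry a `table`
#'   ([study_table()]) instead of a `path`, and `cfg$ld` may be an
#'   [ld_source()].
#' @return Invisibly, a named list per outcome with the report data frames
#'   (`estimates`, `sensitivity`, `decisions`, and when configured
#'   `reverse` and `enrichment`), plus `log`.
#' @export
run_full <- function(cfg) {
  if (is.null(cfg$exposures) || is.null(cfg$outcomes)) {
    mr_abort("run config needs exposures and outcomes")
  }
  if (is.null(cfg$seed)) mr_abort("run config must declare a seed")
  params <- do.call(instrument_params, as.list(cfg$params))
  alpha <- cfg$alpha %||% 0.05
  m_tests <- cfg$m_tests %||% 486
  n_boot <- cfg$n_boot %||% 1000
  n_sim <- cfg$n_sim %||% 1000
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  ld <- if (inherits(cfg$ld, "ld_source")) cfg$ld
        else if (!is.null(cfg$ld)) read_ld_matrix(cfg$ld)
        else ld_source(NULL)
  exposures <- lapply(cfg$exposures, load_entry_table, what = "exposure")
  names(exposures) <- vapply(exposures, `[[`, character(1), "trait_id")
  meta <- data.frame(
    exposure_id = names(exposures),
    name = vapply(cfg$exposures, function(e) e$name %||% e$id %||% "", character(1)),
    super_pathway = vapply(cfg$exposures, function(e) e$super_pathway %||% "", character(1))
  )

  out_all <- list()
  log_rows <- list()
  log_add <- function(stage, outcome, exposure, detail) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, outcome = outcome, exposure = exposure, detail = detail
    )
  }

  for (oi in seq_along(cfg$outcomes)) {
    outcome <- load_entry_table(cfg$outcomes[[oi]], what = "outcome")
    oid <- outcome$trait_id
    results <- list()
    sens <- list()
    est_rows <- list()
    sens_rows <- list()

    for (ei in seq_along(exposures)) {
      eid <- names(exposures)[ei]
      seed_i <- as.integer(cfg$seed + 7L * oi + 13L * ei)
      iv <- stage_guard("instruments", eid,
        suppressWarnings(build_instrument_set(exposures[[eid]], ld, params)))
      log_add("instruments", oid, eid,
              paste(names(iv$counts), iv$counts, sep = "=", collapse = ";"))
      if (nrow(iv$instruments) == 0) {
        results[[eid]] <- NULL
        log_add("skip", oid, eid, "no instruments survive selection")
        next
      }
      h <- stage_guard("harmonize", eid, harmonize(iv, outcome))
      log_add("harmonize", oid, eid,
              sprintf("retained=%d;dropped=%d", nrow(h$variants), nrow(h$drop_log)))
      if (nrow(h$variants) < 4) {
        results[[eid]] <- NULL
        log_add("skip", oid, eid, "fewer than 4 harmonized variants")
        next
      }
      fits <- stage_guard("estimators", eid,
                          mr_all(h, seed = seed_i, n_boot = n_boot, n_sim = n_sim))
      results[[eid]] <- fits
      sens[[eid]] <- stage_guard("sensitivity", eid,
        sensitivity_report(h, alpha = alpha, presso = fits$presso))
      fit_list <- list(fits$ivw, fits$egger$result, fits$weighted_median,
                       fits$presso$raw)
      if (!is.null(fits$presso$corrected) &&
          length(fits$presso$report$outlier_ids)) {
        fit_list <- c(fit_list, list(fits$presso$corrected))
      }
      tab <- mr_result_table(fit_list)
      est_rows[[eid]] <- cbind(exposure_id = eid, outcome_id = oid, tab)
      s <- sens[[eid]]
      sens_rows[[eid]] <- data.frame(
        outcome_id = oid, exposure_id = eid,
        name = meta$name[meta$exposure_id == eid],
        super_pathway = meta$super_pathway[meta$exposure_id == eid],
        p_global_test = s$presso_global_p,
        p_heterogeneity = s$q_p,
        p_intercept = s$egger_intercept_p
      )
    }

    evaluated <- names(results)[!vapply(results, is.null, logical(1))]
    decisions <- if (length(evaluated)) {
      screen_candidates(results[evaluated], sens[evaluated],
                        strict_heterogeneity = isTRUE(cfg$strict_heterogeneity),
                        alpha = alpha, m = m_tests)
    } else {
      data.frame()
    }
    skipped <- setdiff(names(exposures), evaluated)
    if (length(skipped) && nrow(decisions)) {
      pad <- decisions[0, ]
      for (sid in skipped) {
        row <- decisions[1, ]
        row[] <- NA
        row$exposure_id <- sid
        row$evaluable <- FALSE
        pad <- rbind(pad, row)
      }
      decisions <- rbind(decisions, pad)
    }
    rbind_all <- function(lst) {
      if (!length(lst)) return(data.frame())
      out <- do.call(rbind, lst)
      rownames(out) <- NULL
      out
    }
    out <- list(
      estimates = rbind_all(est_rows),
      sensitivity = rbind_all(sens_rows),
      decisions = decisions
    )

    if (isTRUE(cfg$reverse) && length(evaluated)) {
      cand_ids <- decisions$exposure_id[isTRUE_vec(decisions$passes_screen)]
      if (length(cand_ids)) {
        out$reverse <- stage_guard("reverse_mr", oid, reverse_mr(
          outcome, exposures[cand_ids], ld, params = params,
          seed = as.integer(cfg$seed + 9999L + oi),
          n_boot = n_boot, n_sim = n_sim, alpha = alpha
        ))
        log_add("reverse_mr", oid, "*", sprintf("candidates=%d", length(cand_ids)))
      }
    }

    if (!is.null(cfg$pathway) && nrow(decisions)) {
      lib <- if (inherits(cfg$pathway$library, "pathway_library")) {
        cfg$pathway$library
      } else {
        load_pathway_library(cfg$pathway$library)
      }
      cmap <- unlist(cfg$pathway$compound_map)
      # enrichment is run on the IVW-significant candidates, as a screen does
      cand <- decisions$exposure_id[isTRUE_vec(decisions$passes_screen)]
      query <- unname(cmap[intersect(cand, names(cmap))])
      impact <- unlist(cfg$pathway$impact)
      out$enrichment <- suppressWarnings(
        over_representation(query, lib, impact = impact, alpha = alpha)
      )
      log_add("pathway", oid, "*",
              sprintf("query=%d;mapped=%d", length(cand), length(query)))
    }

    for (nm in names(out)) {
      if (!is.null(out[[nm]]) && nrow(out[[nm]])) {
        write_tsv(out[[nm]], file.path(cfg$out_dir, sprintf("%s_%s.tsv", nm, oid)))
      }
    }
    out_all[[oid]] <- out
  }

  log_df <- do.call(rbind, log_rows)
  write_tsv(log_df, file.path(cfg$out_dir, "run_log.tsv"))
  out_all$log <- log_df
  invisible(out_all)
}

isTRUE_vec <- function(x) !is.na(x) & x
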