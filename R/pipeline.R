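#' Read and write council CSV files
#'
#' The on-disk schema is one row per council with header
#' `council_id, zone, residence, pplhiv_pct, population, gdp,
#' n_facilities, pct_male, count_5_59, count_60plus`.  Reading validates
#' the header, the categorical level sets and the counts (non-negative
#' integers or empty cells for missing), naming the offending column,
#' value or row in any error.
#'
#' @param path file path.
#' @param records a council data frame.
#' @return `read_council_csv` a validated council data frame;
#'   `write_council_csv` the path, invisibly.
#' @export
read_council_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(council_columns(), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[council_columns()]
  for (col in c("pplhiv_pct", "population", "gdp", "n_facilities", "pct_male",
                "count_5_59", "count_60plus")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_council_records(df)
  df
}

#' @rdname read_council_csv
#' @export
write_council_csv <- function(records, path) {
  validate_council_records(records)
  write.csv(records[council_columns()], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full council count analysis
#'
#' Orchestrates every stage on one dataset: dispersion summaries per age
#' band, residence and zone contingency tables with chi-square
#' independence tests, maximum-likelihood fits for the requested families,
#' and the ranked model-adequacy comparison.  A family whose fit fails is
#' reported as failed (with the error message) while the other families'
#' results are kept; the pipeline errors only if every fit fails.
#'
#' @param records council data frame (e.g. from [read_council_csv()] or
#'   [generate_councils()]).
#' @param spec a [model_spec()]; its `response` selects the modelled count.
#' @param families character vector of families to fit.
#' @param min_complete minimum number of complete cases required.
#' @param provenance optional list recorded verbatim in the report (input
#'   path or generator config and seed).
#' @return an object of class `"countdisp_report"`: a list with
#'   `data_summary`, `descriptive`, `fits`, `failed_fits`, `comparison`
#'   and `provenance`.
#' @examples
#' out <- generate_councils(synth_config(n_councils = 80, seed = 2))
#' rep <- run_analysis(out$records, families = c("poisson", "gp"))
#' rep$comparison
#' @export
run_analysis <- function(records, spec = model_spec(),
                         families = c("poisson", "nb", "gp"),
                         min_complete = 30, provenance = list()) {
  validate_council_records(records)
  families <- vapply(families, match_family, "")
  design <- build_design(records, spec)
  if (design$n_used < min_complete) {
    stop("only ", design$n_used, " complete cases; need at least ",
         min_complete, call. = FALSE)
  }

  data_summary <- list()
  for (col in c("count_5_59", "count_60plus")) {
    v <- records[[col]]
    if (sum(!is.na(v)) >= 2) data_summary[[col]] <- dispersion_summary(v)
  }
  data_summary$total <- dispersion_summary(response_vector(records, "total"))

  descriptive <- list()
  for (fac in c("residence", "zone")) {
    band_col <- if (spec$response == "total") "total" else spec$response
    tab <- count_xtab(records, factor = fac, count_column = band_col)
    descriptive[[fac]] <- list(table = tab, test = chi2_independence(tab))
  }

  fits <- list()
  failed <- list()
  for (fam in families) {
    res <- tryCatch(fit_count_model(design, family = fam),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[[fam]] <- conditionMessage(res)
    } else {
      fits[[fam]] <- res
    }
  }
  if (length(fits) == 0L) {
    stop("all model fits failed: ",
         paste(names(failed), unlist(failed), sep = ": ", collapse = "; "),
         call. = FALSE)
  }
  comparison <- comparison_table(fits)

  structure(
    list(
      schema = "countdisp-report/1",
      data_summary = data_summary,
      descriptive = descriptive,
      fits = fits,
      failed_fits = failed,
      comparison = comparison,
      provenance = c(provenance, list(
        response = spec$response,
        transforms = spec$transforms,
        n_input = nrow(records),
        n_used = design$n_used,
        dropped_rows = design$dropped_rows,
        package_version = as.character(packageVersion("countdisp"))
      ))
    ),
    class = "countdisp_report"
  )
}

#' @export
print.countdisp_report <- function(x, ...) {
  cat("Council count-analysis report (", x$schema, ")\n", sep = "")
  cat("  n =", x$provenance$n_used, "of", x$provenance$n_input,
      "councils; response:", x$provenance$response, "\n")
  for (fac in names(x$descriptive)) {
    cat(sprintf("  %s association: chi2 = %.3f, df = %d, p = %.4g\n",
                fac, x$descriptive[[fac]]$test$statistic,
                x$descriptive[[fac]]$test$df, x$descriptive[[fac]]$test$p_value))
  }
  cat("  model comparison:\n")
  print(x$comparison)
  invisible(x)
}

#' Write an analysis report
#'
#' `format = "json"` writes a single schema-versioned JSON document with
#' full-precision numbers.  `format = "csv-bundle"` writes one CSV per
#' table next to `path` (suffixes `_xtab_<factor>.csv`,
#' `_coefficients.csv`, `_comparison.csv`), mirroring the published table
#' layouts.
#'
#' @param report a `"countdisp_report"`.
#' @param path output path (the JSON file, or the bundle prefix).
#' @param format `"json"` or `"csv-bundle"`.
#' @return the main path written, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv-bundle")) {
  stopifnot(inherits(report, "countdisp_report"))
  format <- match.arg(format)
  if (format == "json") {
    out <- report_to_list(report)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  stem <- sub("\\.csv$", "", path)
  for (fac in names(report$descriptive)) {
    tab <- report$descriptive[[fac]]$table
    df <- data.frame(level = rownames(tab$counts), tab$counts,
                     check.names = FALSE)
    df$p_value <- c(report$descriptive[[fac]]$test$p_value,
                    rep(NA, nrow(df) - 1))
    write.csv(df, paste0(stem, "_xtab_", fac, ".csv"), row.names = FALSE, na = "")
  }
  coefs <- do.call(rbind, lapply(names(report$fits), function(fam) {
    cbind(model = fam, wald_inference(report$fits[[fam]]))
  }))
  write.csv(coefs, paste0(stem, "_coefficients.csv"), row.names = FALSE)
  cmp <- as.data.frame(report$comparison)
  write.csv(cmp, paste0(stem, "_comparison.csv"), row.names = FALSE)
  invisible(paste0(stem, "_comparison.csv"))
}

report_to_list <- function(report) {
  list(
    schema = report$schema,
    provenance = report$provenance,
    data_summary = report$data_summary,
    descriptive = lapply(report$descriptive, function(d) {
      list(
        factor = d$table$row_factor,
        counts = as.data.frame.matrix(d$table$counts),
        percentages = as.data.frame.matrix(round(d$table$percentages, 4)),
        total = d$table$total,
        chi2 = d$test$statistic, df = d$test$df, p_value = d$test$p_value,
        small_expected_warning = d$test$small_expected_warning
      )
    }),
    fits = lapply(report$fits, function(f) {
      list(family = f$family, converged = f$converged, loglik = f$loglik,
           n_used = f$n_used, k_params = f$k_params,
           dispersion = f$dispersion, coefficients = wald_inference(f))
    }),
    failed_fits = report$failed_fits,
    comparison = as.data.frame(report$comparison)
  )
}

#' Read back a JSON report
#'
#' Parses a report written by [write_report()] into a plain list mirroring
#' the JSON structure (fits come back as coefficient tables, not fit
#' objects).
#'
#' @param path path to a JSON report.
#' @return a list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(out$schema, "countdisp-report/1")) {
    stop("not a countdisp-report/1 document: ", path, call. = FALSE)
  }
  out
}
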