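#' Council data schema
#'
#' Fixed level sets for the two categorical predictors.  `zone_levels()`
#' lists the seven administrative zones with the Northern zone first (it is
#' the dummy-coding reference); `residence_levels()` lists Rural (the
#' reference) then Urban.
#'
#' @return character vector of levels.
#' @export
zone_levels <- function() {
  c("Northern", "Central", "Eastern", "Lake", "Southern",
    "Southern Highlands", "Western")
}

#' @rdname zone_levels
#' @export
residence_levels <- function() c("Rural", "Urban")

# Columns every council table must carry.
council_columns <- function() {
  c("council_id", "zone", "residence", "pplhiv_pct", "population", "gdp",
    "n_facilities", "pct_male", "count_5_59", "count_60plus")
}

#' Specify a council count-regression model
#'
#' Captures the modelling choices needed to turn council records into a
#' design matrix and response: which count is the response (the sum of the
#' two age-band counts by default), which per-covariate transforms apply,
#' and which family is fitted.  The default transform log-transforms the
#' two heavy-tailed magnitude covariates (population and GDP) and leaves
#' percentage and count covariates on their raw scale; coefficients are
#' then per log-unit for those two columns.  Reference levels are fixed at
#' Rural residence and the Northern zone.
#'
#' @param response `"total"` (sum of the age-band counts), `"count_5_59"`
#'   or `"count_60plus"`.
#' @param family `"poisson"`, `"nb"` or `"gp"`.
#' @param transforms named list mapping continuous covariate names to
#'   `"identity"`, `"log"` or `"standardize"`.
#' @return an object of class `"model_spec"`.
#' @examples
#' model_spec(response = "total", family = "gp")
#' @export
model_spec <- function(response = c("total", "count_5_59", "count_60plus"),
                       family = c("gp", "nb", "poisson"),
                       transforms = list(population = "log", gdp = "log")) {
  response <- match.arg(response)
  family <- match_family(family[1])
  continuous <- c("pplhiv_pct", "population", "gdp", "n_facilities", "pct_male")
  bad <- setdiff(names(transforms), continuous)
  if (length(bad)) {
    stop("unknown covariate in `transforms`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (tr in transforms) {
    if (!tr %in% c("identity", "log", "standardize")) {
      stop("transforms must be 'identity', 'log' or 'standardize'", call. = FALSE)
    }
  }
  structure(
    list(response = response, family = family, transforms = transforms,
         continuous = continuous,
         reference = list(residence = "Rural", zone = "Northern")),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Council count-model specification\n")
  cat("  response :", x$response, "\n")
  cat("  family   :", x$family, "\n")
  tr <- vapply(x$continuous, function(v) x$transforms[[v]] %||% "identity", "")
  cat("  transforms:", paste(paste0(x$continuous, "=", tr), collapse = ", "), "\n")
  invisible(x)
}

validate_council_records <- function(records) {
  missing_cols <- setdiff(council_columns(), names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_zone <- setdiff(unique(records$zone[!is.na(records$zone)]), zone_levels())
  if (length(bad_zone)) {
    stop("unknown zone level(s): ", paste(bad_zone, collapse = ", "), call. = FALSE)
  }
  bad_res <- setdiff(unique(records$residence[!is.na(records$residence)]),
                     residence_levels())
  if (length(bad_res)) {
    stop("unknown residence level(s): ", paste(bad_res, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("count_5_59", "count_60plus")) {
    v <- records[[col]]
    bad <- which(!is.na(v) & (v < 0 | v != floor(v)))
    if (length(bad)) {
      stop("column ", col, " must hold non-negative integers; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(records)
}

response_vector <- function(records, response) {
  switch(response,
    total = records$count_5_59 + records$count_60plus,
    count_5_59 = records$count_5_59,
    count_60plus = records$count_60plus
  )
}

apply_transform <- function(x, how, name) {
  switch(how,
    identity = x,
    log = {
      if (any(x[!is.na(x)] <= 0)) {
        stop("cannot log-transform `", name, "`: non-positive values present",
             call. = FALSE)
      }
      log(x)
    },
    standardize = (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  )
}

#' Build the regression design matrix from council records
#'
#' Applies the spec's covariate transforms, dummy-codes residence
#' (reference Rural) and zone (reference Northern), drops rows with any
#' missing required field (complete-case analysis) while recording which
#' rows were dropped, and returns the design matrix together with the
#' response.  The full specification yields k = 13 columns: intercept,
#' five continuous covariates, the Urban indicator and six zone indicators.
#'
#' @param records a council data frame (see [read_council_csv()] for the
#'   schema).
#' @param spec a [model_spec()].
#' @return a list of class `"council_design"` with elements `X` (n_used x k
#'   numeric matrix with column names), `y` (response counts), `n_used`,
#'   `dropped_rows` (council ids excluded), and `spec`.
#' @export
build_design <- function(records, spec = model_spec()) {
  if (!inherits(spec, "model_spec")) stop("`spec` must be a model_spec", call. = FALSE)
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  validate_council_records(records)

  y_all <- response_vector(records, spec$response)
  df <- data.frame(
    zone = factor(records$zone, levels = zone_levels()),
    residence = factor(records$residence, levels = residence_levels())
  )
  for (v in spec$continuous) {
    how <- spec$transforms[[v]] %||% "identity"
    df[[v]] <- apply_transform(records[[v]], how, v)
  }
  keep <- complete.cases(df) & !is.na(y_all)
  if (!any(keep)) stop("all rows dropped: no complete cases", call. = FALSE)
  dropped <- records$council_id[!keep]

  X <- model.matrix(
    ~ pplhiv_pct + population + gdp + n_facilities + pct_male + residence + zone,
    data = df[keep, , drop = FALSE]
  )
  colnames(X) <- c("(Intercept)", "pplhiv_pct", "population", "gdp",
                   "n_facilities", "pct_male", "residenceUrban",
                   paste0("zone", zone_levels()[-1]))
  structure(
    list(X = X, y = y_all[keep], n_used = sum(keep),
         dropped_rows = dropped, spec = spec),
    class = "council_design"
  )
}

#' @export
print.council_design <- function(x, ...) {
  cat("Council design: ", x$n_used, " rows x ", ncol(x$X), " columns (",
      length(x$dropped_rows), " row(s) dropped)\n", sep = "")
  invisible(x)
}
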