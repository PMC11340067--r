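# Shared fixtures: the published contingency tables (zone and residence by
# count band, one per age group) and small simulation helpers.

zone_rows <- c("Central", "Eastern", "Lake", "Northern", "Southern",
               "Southern Highlands", "Western")
band_cols <- c("<50", "51-200", ">200")

# Ages 5-59
table1_zone <- function() {
  matrix(c(11, 2, 2,
           11, 5, 8,
           21, 12, 3,
           9, 17, 5,
           16, 7, 0,
           20, 9, 3,
           12, 8, 3),
         ncol = 3, byrow = TRUE, dimnames = list(zone_rows, band_cols))
}
table1_residence <- function() {
  matrix(c(93, 38, 8,
           7, 22, 16),
         ncol = 3, byrow = TRUE, dimnames = list(c("Rural", "Urban"), band_cols))
}

# Ages 60+
table2_zone <- function() {
  matrix(c(12, 3, 0,
           14, 6, 4,
           28, 6, 2,
           13, 14, 4,
           22, 1, 0,
           23, 8, 1,
           16, 7, 0),
         ncol = 3, byrow = TRUE, dimnames = list(zone_rows, band_cols))
}
table2_residence <- function() {
  matrix(c(112, 21, 6,
           16, 24, 5),
         ncol = 3, byrow = TRUE, dimnames = list(c("Rural", "Urban"), band_cols))
}

# Independent brute-force Pearson chi-square oracle: direct O/E arithmetic.
chi2_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = E)
}

# Expand a factor-by-band cell matrix into council records whose banded
# counts reproduce it (representative count per band).
records_from_cells <- function(cells, factor = c("zone", "residence"),
                               count_column = "count_60plus") {
  factor <- match.arg(factor)
  rep_counts <- c(`<50` = 25, `51-200` = 100, `>200` = 300)
  rows <- list()
  id <- 0
  for (lv in rownames(cells)) {
    for (band in colnames(cells)) {
      k <- cells[lv, band]
      if (k == 0) next
      id <- id + 1
      rows[[id]] <- data.frame(
        level = rep(lv, k), count = rep(rep_counts[[band]], k)
      )
    }
  }
  df <- do.call(rbind, rows)
  n <- nrow(df)
  out <- data.frame(
    council_id = sprintf("R%03d", seq_len(n)),
    zone = if (factor == "zone") df$level else "Northern",
    residence = if (factor == "residence") df$level else "Rural",
    pplhiv_pct = 2, population = 1e5, gdp = 1e6,
    n_facilities = 10, pct_male = 50,
    count_5_59 = df$count, count_60plus = df$count,
    stringsAsFactors = FALSE
  )
  out[[count_column]] <- df$count
  out
}

# Small regression simulator on a generic design: intercept plus
# standard-normal covariates, log-link mean exp(X beta).
sim_xy <- function(n, beta, family, disp = NULL, seed = 1) {
  k <- length(beta)
  with_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    expr
  }
  with_seed(seed, {
    X <- cbind(1, matrix(rnorm(n * (k - 1)), n, k - 1))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(k - 1)))
    mu <- exp(drop(X %*% beta))
    y <- sample_counts(family, n, mu, disp = disp, seed = seed + 1000L)
    list(X = X, y = y, mu = mu)
  })
}

# A complete small synthetic council table used across pipeline tests.
small_records <- function(n = 120, seed = 11) {
  generate_councils(synth_config(n_councils = n, seed = seed,
                                 missing_rate = 0))$records
}
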