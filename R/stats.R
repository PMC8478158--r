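# The statistical layer: fixed-effects two-way ANOVA with Tukey HSD
# pairwise comparisons (studentized range), Sidak-adjusted side-by-side
# comparisons, Student's t, and the significance star code.

#' Significance star code
#'
#' Inclusive thresholds: `****` p <= 0.0001, `***` p <= 0.001, `**`
#' p <= 0.01, `*` p <= 0.05, otherwise `ns`.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Character vector of star labels.
#' @export
star_code <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("validation error: p values must lie in [0, 1]")
  out <- rep("ns", length(p))
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p <= 0.001] <- "***"
  out[p <= 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

#' Sidak adjustment for a family of m comparisons
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1; monotone in both `p` and `m`.
#'
#' @param p_raw Vector of raw p values; the family size is `length(p_raw)`
#'   unless `m` is given.
#' @param m Optional family size override.
#' @return Adjusted p values.
#' @export
sidak_pairs <- function(p_raw, m = length(p_raw)) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop("validation error: p values must lie in [0, 1]")
  if (m < 1) stop("family size m must be >= 1")
  pmin(1, 1 - (1 - p_raw)^m)
}

#' Student's t comparison
#'
#' Two-sided Student's t test (pooled variance by default, matching the
#' classical test; Welch available via `var_equal = FALSE`), with the
#' convention that two zero-variance samples with equal means give
#' statistic 0 and p = 1.
#'
#' @param a,b Numeric samples (equal length when `paired = TRUE`).
#' @param paired Paired test flag.
#' @param var_equal Pooled-variance flag (default TRUE).
#' @return A `ComparisonResult` data.frame: `comparison`, `statistic`,
#'   `df`, `p_raw`, `p_adjusted`, `stars`.
#' @export
students_t <- function(a, b, paired = FALSE, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least two observations")
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate && isTRUE(all.equal(mean(a), mean(b)))) {
    stat <- 0; df <- length(a) + length(b) - 2; p <- 1
  } else {
    tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal)
    stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  data.frame(comparison = "a vs b", statistic = stat, df = df,
             p_raw = p, p_adjusted = p, stars = star_code(p),
             stringsAsFactors = FALSE)
}

#' Two-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Fits the fixed-effects model `response ~ A * B` (replicates, typically
#' donors, within cells) and performs Tukey HSD comparisons between the
#' levels of `factor_a` within each level of `factor_b`, using the
#' studentized-range distribution with the pooled ANOVA mean-square
#' error. This mirrors the display convention of per-time-point
#' significance between populations; set `within = NA` for all-pairs
#' comparisons ignoring `factor_b` strata.
#'
#' @param data data.frame holding the response and both factors.
#' @param response,factor_a,factor_b Column names.
#' @param within Either `"b"` (default; pairs of `factor_a` levels within
#'   each `factor_b` level) or `NA` for marginal all-pairs comparisons.
#' @return List with `anova` (the ANOVA table) and `comparisons`, a
#'   `ComparisonResult` data.frame (one row per pair, with
#'   studentized-range adjusted p values and stars). Pairs with an empty
#'   cell are skipped with a flag row.
#' @export
two_way_anova_tukey <- function(data, response, factor_a, factor_b,
                                within = "b") {
  df <- data.frame(y = data[[response]],
                   A = factor(data[[factor_a]]),
                   B = factor(data[[factor_b]]))
  df <- df[stats::complete.cases(df), ]
  if (nlevels(droplevels(df$A)) < 2 || nlevels(droplevels(df$B)) < 2)
    stop("both factors need at least two observed levels")
  fit <- stats::aov(y ~ A * B, data = df)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfres <- an["Residuals", "Df"]
  if (is.na(dfres) || dfres < 1 || is.na(mse))
    stop("no residual degrees of freedom: at least two replicates per ",
         "cell are required")
  k <- nlevels(df$A)

  pair_rows <- function(sub, label_suffix) {
    means <- tapply(sub$y, droplevels(sub$A), mean)
    ns <- tapply(sub$y, droplevels(sub$A), length)
    lv <- names(means)
    if (length(lv) < 2) return(NULL)
    combs <- utils::combn(lv, 2)
    rows <- apply(combs, 2, function(pr) {
      i <- pr[1]; j <- pr[2]
      se <- sqrt(mse / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
      q <- abs(means[[i]] - means[[j]]) / se
      p <- if (mse == 0) as.numeric(means[[i]] == means[[j]])
           else stats::ptukey(q, nmeans = k, df = dfres, lower.tail = FALSE)
      data.frame(comparison = paste0(i, " vs ", j, label_suffix),
                 estimate = means[[i]] - means[[j]],
                 statistic = q, df = dfres, p_raw = p, p_adjusted = p,
                 stars = star_code(p), skipped = FALSE,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  comparisons <- if (identical(within, "b")) {
    do.call(rbind, lapply(levels(df$B), function(b) {
      sub <- df[df$B == b, , drop = FALSE]
      if (nrow(sub) == 0) return(NULL)
      present <- table(droplevels(sub$A))
      skipped <- setdiff(levels(df$A), names(present))
      rows <- pair_rows(sub, paste0(" @ ", b))
      if (length(skipped)) {
        rows <- rbind(rows, data.frame(
          comparison = paste0("(empty cell: ", paste(skipped, collapse = ","),
                              ") @ ", b),
          estimate = NA_real_, statistic = NA_real_, df = dfres,
          p_raw = NA_real_, p_adjusted = NA_real_, stars = NA_character_,
          skipped = TRUE, stringsAsFactors = FALSE))
      }
      rows
    }))
  } else {
    pair_rows(df, "")
  }
  rownames(comparisons) <- NULL
  list(anova = an, comparisons = comparisons, mse = mse, df_residual = dfres)
}
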