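#' Chi-square contingency analysis with adjusted standardized residuals
#'
#' For an r x c table of counts: expected cells `E_ij = row_i * col_j / N`,
#' the chi-square statistic `sum (O - E)^2 / E` on `(r - 1)(c - 1)` degrees of
#' freedom (no continuity correction), and per-cell adjusted standardized
#' residuals `(O - E) / sqrt(E (1 - row_i / N)(1 - col_j / N))`, which are
#' approximately standard normal under independence. Each cell is assigned a
#' significance tier from the two-sided normal tail of its residual
#' (`p<0.001`, `p<0.01`, `p<0.05`, `p<0.1`, `ns`) together with the direction
#' (above/below expected). Rows or columns with zero margins are dropped with
#' a warning.
#'
#' @param observed Matrix (or table) of non-negative counts with at least two
#'   rows and two columns of positive margin.
#' @return An object of class `"contingency_analysis"`: list with `observed`,
#'   `expected`, `statistic`, `df`, `p_value`, `residuals`, `tiers`,
#'   `directions`.
#' @examples
#' ca <- contingency_analysis(matrix(c(30, 10, 10, 30), 2))
#' ca$statistic
#' tidy(ca)
#' @export
contingency_analysis <- function(observed) {
  obs <- as.matrix(observed)
  if (any(obs < 0)) abort("Counts must be non-negative.")
  rs <- rowSums(obs)
  cs <- colSums(obs)
  if (any(rs == 0) || any(cs == 0)) {
    warn("Dropping zero-margin rows/columns from the contingency table.")
    obs <- obs[rs > 0, cs > 0, drop = FALSE]
    rs <- rowSums(obs)
    cs <- colSums(obs)
  }
  if (nrow(obs) < 2 || ncol(obs) < 2) {
    abort("Need at least 2 rows and 2 columns with positive margins.")
  }
  n <- sum(obs)
  expected <- outer(rs, cs) / n
  statistic <- sum((obs - expected)^2 / expected)
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  denom <- sqrt(expected * outer(1 - rs / n, 1 - cs / n))
  residuals <- (obs - expected) / denom
  residuals[obs == expected] <- 0
  tiers <- residual_tier(residuals)
  directions <- ifelse(obs > expected, "above",
                       ifelse(obs < expected, "below", "equal"))
  structure(
    list(observed = obs, expected = expected, statistic = statistic, df = df,
         p_value = pchisq(statistic, df, lower.tail = FALSE),
         residuals = residuals, tiers = tiers, directions = directions),
    class = "contingency_analysis"
  )
}

# two-sided normal tail tiers for an adjusted standardized residual
residual_tier <- function(z) {
  a <- abs(z)
  out <- ifelse(a >= qnorm(1 - 0.001 / 2), "p<0.001",
                ifelse(a >= qnorm(1 - 0.01 / 2), "p<0.01",
                       ifelse(a >= qnorm(1 - 0.05 / 2), "p<0.05",
                              ifelse(a >= qnorm(1 - 0.1 / 2), "p<0.1", "ns"))))
  if (is.matrix(z)) {
    dim(out) <- dim(z)
    dimnames(out) <- dimnames(z)
  }
  out
}

#' @export
print.contingency_analysis <- function(x, ...) {
  cat(sprintf("<contingency_analysis> X2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Compare a numeric variable between groups
#'
#' Delegates to the standard tests: Kruskal-Wallis (>= 2 groups),
#' Mann-Whitney U (2 groups; exact enumeration for group sizes below 20
#' without ties, normal approximation with tie correction otherwise) or
#' Student's t-test (2 groups). Group summaries report medians with quartiles
#' and means with 95% confidence intervals.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the numeric variable and the
#'   grouping variable.
#' @param test `"kruskal_wallis"`, `"mann_whitney"` or `"t_test"`.
#' @return A list of class `"group_comparison"`: `test`, `statistic`,
#'   `p_value`, `summaries` tibble (one row per group: `n`, `mean`,
#'   `ci_low`, `ci_high`, `median`, `q1`, `q3`).
#' @export
compare_groups <- function(data, value, group,
                           test = c("kruskal_wallis", "mann_whitney", "t_test")) {
  test <- match.arg(test)
  x <- data[[value]]
  g <- factor(data[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("Need at least two groups.")
  if (test %in% c("mann_whitney", "t_test") && nlevels(g) != 2) {
    abort("Mann-Whitney and t-test require exactly two groups.")
  }
  fit <- switch(
    test,
    kruskal_wallis = {
      f <- kruskal.test(x, g)
      list(statistic = unname(f$statistic), p_value = f$p.value)
    },
    mann_whitney = {
      xs <- split(x, g)
      exact <- max(lengths(xs)) < 20 && !any(duplicated(x))
      f <- suppressWarnings(wilcox.test(xs[[1]], xs[[2]], exact = exact,
                                        correct = !exact))
      list(statistic = unname(f$statistic), p_value = f$p.value)
    },
    t_test = {
      xs <- split(x, g)
      if (any(lengths(xs) < 2)) abort("t-test needs >= 2 observations per group.")
      if (sd(x) == 0) abort("Degenerate variance: all values identical.")
      f <- t.test(xs[[1]], xs[[2]])
      list(statistic = unname(f$statistic), p_value = f$p.value)
    }
  )
  summaries <- tibble::tibble(group = levels(g)) |>
    dplyr::mutate(purrr::map_dfr(levels(g), function(lev) {
      v <- x[g == lev]
      se <- if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
      tcrit <- if (length(v) > 1) stats::qt(0.975, length(v) - 1) else NA_real_
      tibble::tibble(
        n = length(v), mean = mean(v),
        ci_low = mean(v) - tcrit * se, ci_high = mean(v) + tcrit * se,
        median = median(v), q1 = unname(quantile(v, 0.25)),
        q3 = unname(quantile(v, 0.75))
      )
    }))
  structure(list(test = test, statistic = fit$statistic,
                 p_value = fit$p_value, summaries = summaries),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  print(x$summaries)
  invisible(x)
}

#' Bonferroni correction
#'
#' `adjusted = min(1, m * p)`; reject when the adjusted value is below
#' `alpha`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise significance level.
#' @return A tibble `p`, `p_adjusted`, `reject`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  adj <- stats::p.adjust(p_values, method = "bonferroni")
  tibble::tibble(p = p_values, p_adjusted = adj, reject = adj < alpha)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper with the preconditions made explicit: equal lengths of at
#' least 3 and non-zero variance on both sides.
#'
#' @param x,y Numeric vectors.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance: correlation undefined.")
  cor(x, y)
}
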