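# Segment-level statistical workflow: Shapiro-Wilk-gated descriptives and
# group tests, Spearman correlations, Holm family-wise correction.

shapiro_normal <- function(x, alpha = 0.05) {
  if (length(unique(x)) == 1L || length(x) < 3L || length(x) > 5000L) {
    return(NA)
  }
  stats::shapiro.test(x)$p.value >= alpha
}

#' Descriptive summary with a normality gate
#'
#' Normality is assessed with the Shapiro-Wilk test at `alpha`; normal
#' samples are summarised as mean +/- s.d., non-normal ones as median and
#' interquartile range (type-7 linear-interpolation quartiles). Constant
#' samples are flagged as degenerate (Shapiro-Wilk is undefined there).
#'
#' @param values Numeric sample, `n >= 3`.
#' @param alpha Normality-test significance level.
#' @return One-row tibble: n, normal, mean, sd, median, q1, q3, summary
#'   (formatted string), status.
#' @export
describe_values <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) abort("need at least 3 finite values.")
  normal <- shapiro_normal(values, alpha)
  status <- if (is.na(normal)) "degenerate" else "ok"
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  summary <- if (isTRUE(normal)) {
    sprintf("%.3g ± %.3g", mean(values), sd(values))
  } else {
    sprintf("%.3g [%.3g−%.3g]", q[2], q[1], q[3])
  }
  tibble(n = n, normal = normal, mean = mean(values), sd = sd(values),
         median = q[2], q1 = q[1], q3 = q[3], summary = summary,
         status = status)
}

#' Compare two groups with a normality-gated test
#'
#' If the Shapiro-Wilk test (at `alpha_normality`) accepts normality for
#' both groups, a two-sided Welch's t-test is used; otherwise a two-sided
#' Mann-Whitney U-test (exact enumeration when both `n <= 12` and there are
#' no ties, tie-corrected normal approximation otherwise). Identical pooled
#' values yield `p = 1` with a degenerate flag.
#'
#' @param a,b Numeric samples, each `n >= 3`.
#' @param alpha_normality Significance level of the normality gate.
#' @param exact_max Largest per-group n for exact Mann-Whitney enumeration.
#' @param test `"auto"` applies the normality gate; `"welch"` or
#'   `"mann_whitney"` force that test.
#' @return An object of class `coro_test`; see [tidy.coro_test()].
#' @export
compare_groups <- function(a, b, alpha_normality = 0.05, exact_max = 12L,
                           test = c("auto", "welch", "mann_whitney")) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L) abort("both groups need n >= 3.")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    res <- list(method = "degenerate", statistic = NA_real_, p_value = 1,
                degenerate = TRUE)
  } else {
    na_ <- shapiro_normal(a, alpha_normality)
    nb_ <- shapiro_normal(b, alpha_normality)
    use_welch <- switch(test,
                        auto = isTRUE(na_) && isTRUE(nb_),
                        welch = TRUE,
                        mann_whitney = FALSE)
    if (use_welch) {
      ht <- stats::t.test(a, b, var.equal = FALSE)
      res <- list(method = "welch", statistic = unname(ht$statistic),
                  p_value = ht$p.value, degenerate = FALSE)
    } else {
      ties <- anyDuplicated(pooled) > 0L
      exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
      ht <- suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = !exact))
      res <- list(method = "mann_whitney", statistic = unname(ht$statistic),
                  p_value = ht$p.value, degenerate = FALSE,
                  exact = exact)
    }
  }
  res$summary_a <- describe_values(a)
  res$summary_b <- describe_values(b)
  res$n_a <- length(a); res$n_b <- length(b)
  class(res) <- "coro_test"
  res
}

#' @export
print.coro_test <- function(x, ...) {
  cat(sprintf("<coro_test> %s: p = %.4g (n = %d vs %d)\n  a: %s\n  b: %s\n",
              x$method, x$p_value, x$n_a, x$n_b,
              x$summary_a$summary, x$summary_b$summary))
  invisible(x)
}

#' Spearman rank correlation with significance
#'
#' Average ranks for ties; the p-value uses exact permutation for `n <= 9`
#' without ties and the t-distribution approximation otherwise. Zero rank
#' variance in either variable yields an undefined (NA) correlation with a
#' flag.
#'
#' @param x,y Paired numeric vectors, `n >= 4`.
#' @param exact_max Largest n for the exact permutation p-value.
#' @return One-row tibble (rho, p_value, n, status).
#' @export
spearman_cor <- function(x, y, exact_max = 9L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) abort("need at least 4 complete pairs.")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n,
                  status = "zero_variance"))
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- !ties && n <= exact_max
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact))
  tibble(rho = unname(ht$estimate), p_value = ht$p.value, n = n,
         status = "ok")
}

#' Holm (step-down Bonferroni) adjustment
#'
#' `adjusted_(i) = max_{j <= i} (m - j + 1) p_(j)` over the ascending order,
#' capped at 1, returned in the input order. Adjusted values dominate the
#' raw ones and the procedure controls the family-wise error rate.
#'
#' @param pvalues Numeric p-values in `[0, 1]` (NAs passed through).
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(pvalues, method = "holm")
}

#' Run a matrix of contrasts over a segment table
#'
#' Executes the statistical plan over a tidy segment table (columns `case`,
#' `group`, `segment`, `descriptor`, `value`): group comparisons
#' (normality-gated Welch / Mann-Whitney) and Spearman correlations between
#' descriptor pairs, with Holm adjustment applied within each declared
#' family.
#'
#' @param table Tidy segment table (e.g. from [make_group_samples()] or
#'   [run_case()] outputs).
#' @param plan Tibble describing one test per row, with columns: `family`
#'   (Holm family id), `type` (`"group"` or `"correlation"`), `segment`,
#'   `descriptor` (for group tests), `descriptor_x`, `descriptor_y` (for
#'   correlations). See [default_contrast_plan()].
#' @param groups The two group labels contrasted in group tests.
#' @return A tibble of class `coro_contrasts`: one row per contrast with the
#'   test used, estimate/statistic, raw and Holm-adjusted p-values,
#'   significance flag (adjusted p < 0.05) and group descriptive summaries.
#' @export
run_contrast_matrix <- function(table, plan,
                                groups = c("non_stenosed", "stenosed")) {
  if (!nrow(plan)) abort("empty contrast plan.")
  need <- c("case", "group", "segment", "descriptor", "value")
  if (!all(need %in% names(table))) {
    abort(sprintf("segment table needs columns: %s.",
                  paste(need, collapse = ", ")))
  }
  one <- function(row) {
    seg_tbl <- filter(table, .data$segment == row$segment)
    if (row$type == "group") {
      v <- filter(seg_tbl, .data$descriptor == row$descriptor)
      a <- v$value[v$group == groups[1]]
      b <- v$value[v$group == groups[2]]
      ct <- compare_groups(a, b)
      tibble(family = row$family, type = "group", segment = row$segment,
             contrast = row$descriptor, method = ct$method,
             estimate = NA_real_, statistic = ct$statistic,
             p_raw = ct$p_value,
             summary_1 = ct$summary_a$summary, summary_2 = ct$summary_b$summary)
    } else {
      wide <- seg_tbl |>
        filter(.data$descriptor %in% c(row$descriptor_x, row$descriptor_y)) |>
        tidyr::pivot_wider(id_cols = c("case", "group"),
                           names_from = "descriptor", values_from = "value")
      sc <- spearman_cor(wide[[row$descriptor_x]], wide[[row$descriptor_y]])
      tibble(family = row$family, type = "correlation", segment = row$segment,
             contrast = paste(row$descriptor_x, "~", row$descriptor_y),
             method = "spearman", estimate = sc$rho, statistic = NA_real_,
             p_raw = sc$p_value,
             summary_1 = NA_character_, summary_2 = NA_character_)
    }
  }
  res <- purrr::map_dfr(seq_len(nrow(plan)), function(i) one(plan[i, ]))
  res <- res |>
    group_by(.data$family) |>
    mutate(p_adjusted = holm_adjust(.data$p_raw)) |>
    ungroup() |>
    mutate(significant = !is.na(.data$p_adjusted) & .data$p_adjusted < 0.05)
  class(res) <- c("coro_contrasts", class(res))
  res
}

#' Default contrast plan for a segment table
#'
#' One group-comparison family covering every (segment, descriptor) pair in
#' the table, plus one correlation family per segment pairing each descriptor
#' in `correlate_with` against the others (the correlation-heatmap layout).
#'
#' @param table Tidy segment table.
#' @param correlate_with Descriptors to correlate against all others
#'   (default `"h2"` against every other descriptor).
#' @return A plan tibble for [run_contrast_matrix()].
#' @export
default_contrast_plan <- function(table, correlate_with = "h2") {
  segs <- unique(table$segment)
  descs <- unique(table$descriptor)
  comp <- tidyr::expand_grid(segment = segs, descriptor = descs) |>
    mutate(family = "group_panel", type = "group",
           descriptor_x = NA_character_, descriptor_y = NA_character_)
  corr <- tidyr::expand_grid(segment = segs,
                             descriptor_x = intersect(correlate_with, descs),
                             descriptor_y = descs) |>
    filter(.data$descriptor_x != .data$descriptor_y) |>
    mutate(family = paste0("correlation_", .data$segment),
           type = "correlation", descriptor = NA_character_)
  bind_rows(comp, corr)
}
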