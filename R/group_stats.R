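# Nonparametric group comparisons of endpoint distributions.
#
# Locomotor endpoints are skewed and heavy-tailed, so everything here is
# rank-based: Mann-Whitney for two groups, Kruskal-Wallis plus Dunn's
# control-referenced post-hoc for dose series, medians and interquartile
# ranges for summaries. Quartiles use linear interpolation between order
# statistics (stats::quantile type 7) throughout, the same convention as the
# burst threshold.

#' Significance star codes
#'
#' Maps p values to the conventional star codes with strict-inequality
#' thresholds: `"****"` below 1e-4, `"***"` below 1e-3, `"**"` below 0.01,
#' `"*"` below 0.05, otherwise `"ns"`.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Character vector of star codes.
#' @examples
#' star_code(c(0.03, 0.05, 5e-5))
#' @export
star_code <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Median / interquartile-range summary
#'
#' @param values Numeric vector (NAs dropped).
#' @param quartile_type Quantile convention (default 7).
#' @return One-row tibble: `n`, `median`, `q1`, `q3`, `iqr`.
#' @export
summarize_values <- function(values, quartile_type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("Cannot summarise an empty vector.")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = quartile_type, names = FALSE)
  tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}

#' Per-group endpoint summaries
#'
#' Median and interquartile range of every locomotor endpoint within every
#' treatment group — the summary convention used to report this assay.
#'
#' @param endpoints Endpoint tibble from [compute_endpoints()] (rows may come
#'   from several groups bound together).
#' @param quartile_type Quantile convention (default 7).
#' @return A tidy tibble: `group`, `endpoint`, `n`, `median`, `q1`, `q3`, `iqr`.
#' @export
summarize_endpoints <- function(endpoints, quartile_type = 7) {
  endpoints |>
    tidyr::pivot_longer(
      dplyr::all_of(intersect(endpoint_names, names(endpoints))),
      names_to = "endpoint", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$group, .data$endpoint) |>
    dplyr::reframe(summarize_values(.data$value, quartile_type = quartile_type))
}

#' Mann-Whitney rank test for two groups
#'
#' Wraps the rank-sum test with the small-sample policy fixed: the exact
#' permutation distribution is used when the combined sample size is at most
#' 12 and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Numeric vectors (NAs dropped).
#' @param alternative Passed to [stats::wilcox.test()]; two-sided default.
#' @return One-row tibble: `statistic` (U for `x`), `p_value`, `method`,
#'   `exact`, `stars`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be nonempty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact, correct = TRUE)
  )
  tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = "Mann-Whitney U",
    exact = exact,
    stars = star_code(ht$p.value)
  )
}

# Dunn's rank-based multiple-comparison z statistics against a designated
# control group, with the usual tie correction on the pooled ranks.
dunn_vs_control <- function(values, group, control, p_adjust = "holm") {
  group <- as.character(group)
  keep <- !is.na(values)
  values <- values[keep]
  group <- group[keep]
  if (!control %in% group) abort(sprintf("Control group '%s' not present.", control))
  n_tot <- length(values)
  r <- rank(values)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n_tot - 1))
  var_base <- n_tot * (n_tot + 1) / 12 - tie_term
  rbar <- tapply(r, group, mean)
  n_g <- table(group)
  others <- setdiff(names(rbar), control)
  z <- purrr::map_dbl(others, function(g) {
    (rbar[[g]] - rbar[[control]]) /
      sqrt(var_base * (1 / n_g[[g]] + 1 / n_g[[control]]))
  })
  p <- 2 * pnorm(-abs(z))
  tibble(
    comparison = paste(others, "vs", control),
    group = others,
    z = z,
    p_value = p,
    p_adjusted = p.adjust(p, method = p_adjust),
    stars = star_code(p.adjust(p, method = p_adjust))
  )
}

#' Kruskal-Wallis test with Dunn's control-referenced post-hoc
#'
#' Overall rank test across k groups (tie-corrected H, chi-square reference
#' with k-1 degrees of freedom), followed — when a control group is named —
#' by Dunn's pairwise z tests of each treatment against the control with
#' Holm adjustment. All observations identical is a legal degenerate input
#' (H = 0, p = 1).
#'
#' @param values Numeric vector of observations.
#' @param group Group label for each observation.
#' @param control Name of the control group for the post-hoc contrasts, or
#'   `NULL` to skip the post-hoc.
#' @param p_adjust Multiplicity adjustment method (default `"holm"`).
#' @return A `kw_test` object; use [tidy()] for the per-comparison table and
#'   [glance()] for the overall test.
#' @examples
#' kw <- kruskal_wallis(c(1:3, 4:6, 7:9), rep(c("a", "b", "c"), each = 3))
#' glance(kw)
#' @export
kruskal_wallis <- function(values, group, control = NULL, p_adjust = "holm") {
  group <- as.character(group)
  keep <- !is.na(values)
  values <- values[keep]
  group <- group[keep]
  if (length(unique(group)) < 2) abort("Need at least 2 nonempty groups.")
  if (length(unique(values)) == 1) {
    ht <- list(statistic = c("Kruskal-Wallis chi-squared" = 0), p.value = 1,
               parameter = c(df = length(unique(group)) - 1))
  } else {
    ht <- kruskal.test(values, factor(group))
  }
  comparisons <- if (!is.null(control) && length(unique(values)) > 1) {
    dunn_vs_control(values, group, control, p_adjust = p_adjust)
  } else {
    NULL
  }
  structure(
    list(
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      method = "Kruskal-Wallis with Dunn post-hoc",
      control = control,
      p_adjust = p_adjust,
      comparisons = comparisons,
      stars = star_code(ht$p.value)
    ),
    class = "kw_test"
  )
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf(
    "<kw_test> H = %.4g, df = %d, p = %.4g %s\n",
    x$statistic, x$df, x$p_value, x$stars
  ))
  if (!is.null(x$comparisons)) {
    cat(sprintf("Dunn vs '%s' (%s-adjusted):\n", x$control, x$p_adjust))
    print(as.data.frame(x$comparisons))
  }
  invisible(x)
}

#' @export
tidy.kw_test <- function(x, ...) {
  if (is.null(x$comparisons)) {
    return(tibble(
      comparison = "overall", group = NA_character_, z = NA_real_,
      p_value = x$p_value, p_adjusted = x$p_value, stars = x$stars
    ))
  }
  x$comparisons
}

#' @export
glance.kw_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value, stars = x$stars)
}

#' Compare every endpoint across treatment groups
#'
#' Data-frame-first driver for the whole endpoint battery: with two groups
#' each endpoint is tested by [mann_whitney()]; with more, by
#' [kruskal_wallis()] with Dunn contrasts against `control`. Cells flagged
#' as degenerate by [compute_endpoints()] contribute only their defined
#' endpoints.
#'
#' @param endpoints Endpoint tibble (possibly several groups bound together).
#' @param control Control group name (required for more than two groups).
#' @param p_adjust Multiplicity adjustment for the post-hoc (default holm).
#' @return Tidy tibble: `endpoint`, `comparison`, `method`, `statistic`,
#'   `p_value`, `p_adjusted`, `stars`.
#' @export
compare_endpoints <- function(endpoints, control = NULL, p_adjust = "holm") {
  groups <- unique(endpoints$group)
  if (length(groups) < 2) abort("Need at least two groups to compare.")
  cols <- intersect(endpoint_names, names(endpoints))
  purrr::map_dfr(cols, function(ep) {
    vals <- endpoints[[ep]]
    if (length(groups) == 2) {
      a <- vals[endpoints$group == groups[1]]
      b <- vals[endpoints$group == groups[2]]
      mw <- mann_whitney(a, b)
      tibble(
        endpoint = ep,
        comparison = paste(groups[1], "vs", groups[2]),
        method = mw$method, statistic = mw$statistic,
        p_value = mw$p_value, p_adjusted = mw$p_value, stars = mw$stars
      )
    } else {
      if (is.null(control)) abort("`control` is required for more than two groups.")
      kw <- kruskal_wallis(vals, endpoints$group, control = control, p_adjust = p_adjust)
      dplyr::bind_rows(
        tibble(
          endpoint = ep, comparison = "overall",
          method = "Kruskal-Wallis H", statistic = kw$statistic,
          p_value = kw$p_value, p_adjusted = kw$p_value, stars = kw$stars
        ),
        tidy(kw) |>
          dplyr::transmute(
            endpoint = ep, comparison = .data$comparison,
            method = "Dunn z vs control", statistic = .data$z,
            p_value = .data$p_value, p_adjusted = .data$p_adjusted,
            stars = .data$stars
          )
      )
    }
  })
}
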