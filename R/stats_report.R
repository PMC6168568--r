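# Correlation and rank-test machinery plus report assembly.

#' Pearson correlation with two-sided significance
#'
#' Product-moment correlation with the exact two-sided p-value from the t
#' transform t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of
#' freedom. Invariant under affine rescaling of either variable.
#'
#' @param x,y numeric vectors of equal length, n >= 3, both with nonzero
#'   variance.
#' @return one-row tibble: `r`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_with_p(c(15.0, 33.6, 34.4), c(11, 63, 67))
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) abort_bad_arg("x and y must have equal length")
  if (length(x) < 3) abort_bad_arg("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_bad_arg("degenerate input: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Compare length distributions across groups
#'
#' Kruskal-Wallis rank test (with tie correction) across all groups,
#' followed by pairwise Mann-Whitney U tests: exact when both group sizes
#' are at most 20 and no ties are present, normal approximation otherwise.
#' Pairwise p-values are reported both raw and Bonferroni-adjusted.
#' Quartiles use linear interpolation (quantile type 7).
#'
#' @param data data frame in long format.
#' @param value column of lengths/values (tidy-eval).
#' @param group column of group labels (tidy-eval).
#' @return object of class `length_dist_comparison`: list with `groups`
#'   (per-group n, median, q1, q3), `H`, `df`, `p_kw`, `pairwise`
#'   (`group_1`, `group_2`, `U`, `p_raw`, `p_bonferroni`, `exact`).
#' @export
compare_length_distributions <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  labs <- unique(g)
  if (length(labs) < 2) abort_bad_arg("need at least 2 groups")
  groups <- purrr::map_dfr(labs, function(l) {
    x <- v[g == l]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(group = l, n = length(x), q1 = q[1], median = q[2],
                   q3 = q[3])
  })
  kw <- stats::kruskal.test(v, factor(g))
  pairs <- utils::combn(labs, 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- v[g == pairs[1, k]]; b <- v[g == pairs[2, k]]
    use_exact <- length(a) <= 20 && length(b) <= 20 &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                              correct = !use_exact))
    tibble::tibble(group_1 = pairs[1, k], group_2 = pairs[2, k],
                   U = unname(wt$statistic), p_raw = wt$p.value,
                   exact = use_exact)
  })
  pairwise$p_bonferroni <- pmin(1, pairwise$p_raw * nrow(pairwise))
  structure(list(groups = groups, H = unname(kw$statistic),
                 df = unname(kw$parameter), p_kw = kw$p.value,
                 pairwise = pairwise),
            class = "length_dist_comparison")
}

#' @export
print.length_dist_comparison <- function(x, ...) {
  cat("Kruskal-Wallis: H =", format(x$H, digits = 4), "df =", x$df,
      "p =", format(x$p_kw, digits = 4), "\n")
  print(x$groups)
  cat("Pairwise Mann-Whitney U (raw and Bonferroni-adjusted):\n")
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_length_distributions
#' @param x a `length_dist_comparison`.
#' @param ... unused.
#' @return `tidy()`: the pairwise table; `glance()`: one-row H/p summary.
#' @export
tidy.length_dist_comparison <- function(x, ...) x$pairwise

#' @rdname compare_length_distributions
#' @export
glance.length_dist_comparison <- function(x, ...) {
  tibble::tibble(H = x$H, df = x$df, p_kw = x$p_kw,
                 n_groups = nrow(x$groups), n_total = sum(x$groups$n))
}

#' Assemble a structured analysis report
#'
#' Aggregates the outputs of the pipeline stages into one machine-readable
#' report: assemblies, per-comparison MCD summaries (Table-2 style),
#' breakage-test results and correlations (Table-3 style). Sections left
#' `NULL` stay empty; MCD rows pass through [mcd_summary()] output
#' unchanged.
#'
#' @param assemblies assembly tibble or `NULL`.
#' @param mcd_summaries named list of [mcd_summary()] rows or a tibble with
#'   a `comparison` column, or `NULL`.
#' @param breakage named list of [random_breakage_test()] results or `NULL`.
#' @param correlations named list of [pearson_with_p()] rows or `NULL`.
#' @return object of class `rearrangement_report`: list of tibble sections
#'   `assemblies`, `mcd`, `breakage`, `correlations`.
#' @export
build_report <- function(assemblies = NULL, mcd_summaries = NULL,
                         breakage = NULL, correlations = NULL) {
  bind_named <- function(x, id) {
    if (is.null(x)) return(tibble::tibble())
    if (is.data.frame(x)) return(tibble::as_tibble(x))
    dplyr::bind_rows(purrr::imap(x, function(row, nm) {
      dplyr::bind_cols(tibble::as_tibble(stats::setNames(list(nm), id)), row)
    }))
  }
  mcd <- bind_named(mcd_summaries, "comparison")
  cor <- bind_named(correlations, "correlation")
  brk <- if (is.null(breakage)) tibble::tibble() else
    dplyr::bind_rows(purrr::imap(breakage, function(bt, nm)
      dplyr::bind_cols(tibble::tibble(comparison = nm), glance(bt))))
  structure(list(assemblies = assemblies %||% tibble::tibble(),
                 mcd = mcd, breakage = brk, correlations = cor),
            class = "rearrangement_report")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  for (s in names(x)) {
    cat("==", s, "==\n")
    if (nrow(x[[s]])) print(x[[s]]) else cat("(empty)\n")
  }
  invisible(x)
}

#' Write a report to a directory of TSV tables
#'
#' @param report a `rearrangement_report`.
#' @param dir output directory (created if missing).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(report)) {
    readr::write_tsv(report[[s]], file.path(dir, paste0(s, ".tsv")))
  }
  invisible(report)
}
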