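# Normality-gated two-group comparison for biofilm assay data (crystal
# violet absorbance; confocal viable-cell counts). Each group is first
# checked with a Shapiro-Wilk test; a paired t-test is used only when both
# groups look normal AND the design is paired, otherwise a two-sided
# Mann-Whitney U test (exact enumeration for small tie-free samples,
# tie-corrected continuity-corrected normal approximation otherwise).

#' Shapiro-Wilk normality p-value
#'
#' Thin contract around [stats::shapiro.test()] (Royston's approximation):
#' explicit errors on degenerate inputs, returns the p-value alone. Higher
#' p means more consistent with normality.
#'
#' @param sample numeric vector, 3 <= n <= 5000, not constant.
#' @return The Shapiro-Wilk p-value.
#' @export
#' @examples
#' shapiro_wilk(rnorm(20))
shapiro_wilk <- function(sample) {
  x <- as.numeric(sample)
  if (any(!is.finite(x))) stop("sample must be finite", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (n > 5000L) stop("Shapiro-Wilk requires n <= 5000", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance", call. = FALSE)
  stats::shapiro.test(x)$p.value
}

#' Normality-gated two-group comparison
#'
#' Implements the gating rule used for biofilm assay statistics: if the
#' design is paired and every group passes Shapiro-Wilk normality (p >
#' `alpha_normality`), the means are compared with a two-sided paired
#' t-test; in every other case a two-sided Mann-Whitney U test is used
#' (exact when both groups have n <= 8 and there are no ties, otherwise the
#' tie-corrected normal approximation with continuity correction; ties get
#' mid-ranks). The report records which route was taken.
#'
#' @param group_a,group_b numeric measurement vectors (n >= 3 each);
#'   `group_a` may instead be a `two_group_data` object from
#'   [generate_biofilm_data()], in which case `group_b`, `paired` and
#'   `labels` are taken from it.
#' @param paired is the design paired (default FALSE)?
#' @param labels group labels for reporting.
#' @param alpha significance level for the comparison (default 0.05).
#' @param alpha_normality level of the normality gate (default 0.05).
#' @return A `gated_test_report`: list with `labels`, `n`, `paired`,
#'   `normality_p`, `test_used` (`"paired_t"` or `"mann_whitney_u"`),
#'   `statistic`, `p_value`, `significant` (`p_value < alpha`), `alpha`,
#'   `alpha_normality` and `method`.
#' @export
#' @examples
#' gated_compare(c(10, 11, 12), c(11, 13, 15), paired = TRUE)
gated_compare <- function(group_a, group_b = NULL, paired = FALSE,
                          labels = c("A", "B"), alpha = 0.05,
                          alpha_normality = 0.05) {
  if (inherits(group_a, "two_group_data")) {
    dat <- group_a
    group_b <- dat$group_b
    paired <- dat$paired
    labels <- dat$labels
    group_a <- dat$group_a
  }
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 3L || length(b) < 3L) {
    stop("need at least 3 observations per group", call. = FALSE)
  }
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires equal group lengths", call. = FALSE)
  }
  np <- c(shapiro_wilk(a), shapiro_wilk(b))
  names(np) <- labels
  if (paired && all(np > alpha_normality)) {
    ht <- stats::t.test(a, b, paired = TRUE)
    used <- "paired_t"
  } else {
    n_a <- length(a)
    n_b <- length(b)
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- n_a <= 8L && n_b <= 8L && !ties
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)
    )
    used <- "mann_whitney_u"
  }
  structure(
    list(
      labels = labels,
      n = c(length(a), length(b)),
      paired = paired,
      normality_p = np,
      test_used = used,
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      significant = ht$p.value < alpha,
      alpha = alpha,
      alpha_normality = alpha_normality,
      method = ht$method
    ),
    class = "gated_test_report"
  )
}

#' @export
print.gated_test_report <- function(x, ...) {
  cat(sprintf(
    "<gated_test_report> %s vs %s (n = %d, %d; %s)\n",
    x$labels[1L], x$labels[2L], x$n[1L], x$n[2L],
    if (x$paired) "paired" else "independent"
  ))
  cat(sprintf("  normality p: %s\n",
              paste(sprintf("%s = %.3g", names(x$normality_p),
                            x$normality_p), collapse = ", ")))
  cat(sprintf("  %s: statistic = %.4g, %s%s\n",
              x$test_used, x$statistic, format_p_value(x$p_value),
              if (x$significant) " (significant at alpha = 0.05)" else ""))
  invisible(x)
}

#' Read a two-group measurement table
#'
#' Long format: columns `group` and `value`; or two columns, one per group.
#'
#' @param path input file path.
#' @return List with `group_a`, `group_b`, `labels` (first-appearance
#'   order).
#' @export
read_two_group_tsv <- function(path) {
  if (!file.exists(path)) stop("measurement table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty measurement table: ", path, call. = FALSE)
  if (all(c("group", "value") %in% names(df))) {
    labels <- unique(df$group)
    if (length(labels) != 2L) {
      stop("expected exactly two groups, found ", length(labels), call. = FALSE)
    }
    list(
      group_a = as.numeric(df$value[df$group == labels[1L]]),
      group_b = as.numeric(df$value[df$group == labels[2L]]),
      labels = labels
    )
  } else if (ncol(df) == 2L) {
    list(
      group_a = as.numeric(df[[1L]]),
      group_b = as.numeric(df[[2L]]),
      labels = names(df)
    )
  } else {
    stop("measurement table must be long format (group, value) or ",
         "two columns", call. = FALSE)
  }
}
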