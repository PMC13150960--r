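#' Centered Mann-Whitney U test
#'
#' Computes `U = #\{x_i > y_j\} + 0.5 #\{ties\}` from midranks and reports
#' the centered statistic `U - n1*n2/2`, which is positive when the first
#' group tends to exceed the second and ranges over
#' `[-n1*n2/2, +n1*n2/2]`. The two-sided p-value uses the exact null
#' distribution of U when there are no ties and both groups have at most
#' `exact_max` observations, and otherwise a normal approximation with
#' midranks and tie-corrected variance, without continuity correction.
#'
#' @param x,y Numeric samples for the two groups (x first, e.g. young).
#' @param exact_max Largest group size for which the exact p is used
#'   (default 25).
#' @return Tibble with `u`, `u_centered`, `p_value`, `n1`, `n2`, `method`.
#' @export
mann_whitney_centered <- function(x, y, exact_max = 25) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    method <- "exact"
    if (u > n1 * n2 / 2) {
      p <- 2 * (1 - stats::pwilcox(u - 1, n1, n2))
    } else {
      p <- 2 * stats::pwilcox(u, n1, n2)
    }
    p <- min(1, p)
  } else {
    method <- "normal"
    nt <- n1 + n2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (nt * (nt - 1))
    sigma2 <- n1 * n2 / 12 * ((nt + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  tibble::tibble(u = u, u_centered = u - n1 * n2 / 2, p_value = p,
                 n1 = n1, n2 = n2, method = method)
}

#' Rank-biserial correlation from a centered U
#'
#' `r = U_c / (n1 n2 / 2)`, the Mann-Whitney effect size in `[-1, 1]`:
#' the difference between the probability that a value from group 1
#' exceeds one from group 2 and the reverse.
#'
#' @param u_centered Centered Mann-Whitney statistic `U - n1*n2/2`.
#' @param n1,n2 Group sizes.
#' @return Effect size in `[-1, 1]`.
#' @export
rank_biserial <- function(u_centered, n1, n2) {
  half <- n1 * n2 / 2
  if (any(abs(u_centered) > half + 1e-9)) {
    stop("|u_centered| cannot exceed n1*n2/2", call. = FALSE)
  }
  u_centered / half
}

#' Fisher-z confidence interval for a rank-biserial correlation
#'
#' Transforms r with `atanh`, builds a normal interval with standard error
#' `sqrt((n1 + n2 + 1) / (3 n1 n2))`, and back-transforms with `tanh`.
#'
#' @param r Rank-biserial correlation.
#' @param n1,n2 Group sizes.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `ci_low`, `ci_high`.
#' @export
rank_biserial_ci <- function(r, n1, n2, level = 0.95) {
  if (abs(r) >= 1) {
    warning("|r| = 1: degenerate confidence interval returned")
    return(tibble::tibble(ci_low = sign(r), ci_high = sign(r)))
  }
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - level) / 2) * sqrt((n1 + n2 + 1) / (3 * n1 * n2))
  tibble::tibble(ci_low = tanh(z - hw), ci_high = tanh(z + hw))
}

iqr_string <- function(v, digits = 2) {
  q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.*f to %.*f", digits, q[1], digits, q[2])
}

#' Compare per-participant sleep measures between two groups
#'
#' One Mann-Whitney comparison per measure column: group means (SD),
#' medians (IQR as 25th--75th percentiles), centered U, two-sided p,
#' rank-biserial r with Fisher-z 95% CI, and a significance flag at
#' p < .05. No multiple-testing correction is applied across measures.
#'
#' @param data Data frame with one row per participant, a `group` column,
#'   and numeric measure columns.
#' @param measures Character vector of measure column names; defaults to
#'   every numeric column except `group` identifiers.
#' @param group_col Name of the grouping column (default `"group"`).
#' @param group_order Length-2 character vector giving which level is
#'   group 1 (x, e.g. young) and group 2 (y); defaults to
#'   `c("young", "old")` when present, else the sorted levels.
#' @param level CI level (default 0.95).
#' @return A `group_comparison` tibble, one row per measure, with columns
#'   `measure`, `n1`, `n2`, `mean1`, `sd1`, `mean2`, `sd2`, `median1`,
#'   `iqr1`, `median2`, `iqr2`, `u_centered`, `p_value`,
#'   `r_rank_biserial`, `ci_low`, `ci_high`, `significant`.
#' @export
compare_groups <- function(data, measures = NULL, group_col = "group",
                           group_order = NULL, level = 0.95) {
  stopifnot(is.data.frame(data), group_col %in% names(data))
  g <- as.character(data[[group_col]])
  lv <- unique(g)
  if (length(lv) != 2) stop("exactly two groups are required", call. = FALSE)
  if (is.null(group_order)) {
    group_order <- if (all(c("young", "old") %in% lv)) c("young", "old") else sort(lv)
  }
  if (is.null(measures)) {
    num <- vapply(data, is.numeric, logical(1))
    measures <- setdiff(names(data)[num], c(group_col, "participant_id"))
  }
  rows <- purrr::map_dfr(measures, function(m) {
    xv <- data[[m]][g == group_order[1]]
    yv <- data[[m]][g == group_order[2]]
    xv <- xv[!is.na(xv)]; yv <- yv[!is.na(yv)]
    if (!length(xv) || !length(yv)) {
      stop(sprintf("measure '%s' has no data in one group", m), call. = FALSE)
    }
    mw <- mann_whitney_centered(xv, yv)
    r <- rank_biserial(mw$u_centered, mw$n1, mw$n2)
    ci <- if (abs(r) < 1) rank_biserial_ci(r, mw$n1, mw$n2, level) else
      tibble::tibble(ci_low = sign(r), ci_high = sign(r))
    tibble::tibble(
      measure = m, n1 = mw$n1, n2 = mw$n2,
      mean1 = mean(xv), sd1 = stats::sd(xv),
      mean2 = mean(yv), sd2 = stats::sd(yv),
      median1 = stats::median(xv), iqr1 = iqr_string(xv),
      median2 = stats::median(yv), iqr2 = iqr_string(yv),
      u = mw$u, u_centered = mw$u_centered, p_value = mw$p_value,
      r_rank_biserial = r, ci_low = ci$ci_low, ci_high = ci$ci_high,
      significant = mw$p_value < 0.05
    )
  })
  structure(rows, groups = group_order, level = level,
            class = c("group_comparison", class(rows)))
}

#' Tidy a group comparison
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble of the statistical columns, one row per measure.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("measure", "n1", "n2", "u_centered",
                                 "p_value", "r_rank_biserial",
                                 "ci_low", "ci_high", "significant")])
}

#' One-row summary of a group comparison
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    n_measures = nrow(x),
    n_significant = sum(x$significant),
    group1 = attr(x, "groups")[1],
    group2 = attr(x, "groups")[2],
    conf_level = attr(x, "level")
  )
}

#' Format a group comparison as an aligned text table
#'
#' Mirrors the layout of a per-measure sleep comparison table: mean (SD)
#' and median (IQR) per group, centered U, p, and the effect size with CI.
#' A footer notes that no multiple-testing correction was applied.
#'
#' @param x A `group_comparison`.
#' @return Character vector of formatted lines, invisibly printed.
#' @export
format_comparison_table <- function(x) {
  stopifnot(inherits(x, "group_comparison"))
  gr <- attr(x, "groups")
  hdr <- sprintf("%-24s %-16s %-16s %8s %7s %24s",
                 "Measure", paste0(gr[1], " mean (SD)"),
                 paste0(gr[2], " mean (SD)"), "U_c", "P", "Effect size (95% CI)")
  lines <- vapply(seq_len(nrow(x)), function(i) {
    sprintf("%-24s %-16s %-16s %8s %7.3g %24s%s",
            x$measure[i],
            sprintf("%.2f (%.2f)", x$mean1[i], x$sd1[i]),
            sprintf("%.2f (%.2f)", x$mean2[i], x$sd2[i]),
            format(x$u_centered[i]),
            x$p_value[i],
            sprintf("%.3f (%.3f to %.3f)", x$r_rank_biserial[i],
                    x$ci_low[i], x$ci_high[i]),
            if (x$significant[i]) " *" else "")
  }, character(1))
  out <- c(hdr, strrep("-", nchar(hdr)), lines,
           "* p < .05, uncorrected for multiple comparisons")
  invisible(out)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(format_comparison_table(x), sep = "\n")
  invisible(x)
}
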