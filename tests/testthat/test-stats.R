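test_that("centered U matches hand-enumerated examples", {
  mw <- mann_whitney_centered(c(3, 4), c(1, 2))
  expect_equal(mw$u, 4)
  expect_equal(mw$u_centered, 2)
  expect_equal(mw$p_value, 1 / 3)                  # 2 x 1/6 of C(4,2) splits
  tie <- mann_whitney_centered(5, 5)
  expect_equal(tie$u, 0.5)
  expect_equal(tie$u_centered, 0)
  expect_error(mann_whitney_centered(numeric(), 1), "non-empty")
})

test_that("exact p equals the exhaustive permutation p for small groups", {
  perm_p <- function(x, y) {
    n1 <- length(x); pool <- c(x, y)
    uc_of <- function(idx) {
      r <- rank(pool)
      sum(r[idx]) - n1 * (n1 + 1) / 2 - n1 * (length(pool) - n1) / 2
    }
    obs <- abs(uc_of(seq_len(n1)))
    splits <- utils::combn(length(pool), n1)
    mean(apply(splits, 2, function(idx) abs(uc_of(idx)) >= obs - 1e-9))
  }
  set.seed(51)
  for (i in 1:25) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    mw <- mann_whitney_centered(x, y)
    expect_equal(mw$p_value, perm_p(x, y), tolerance = 1e-12)
  }
})

test_that("the tie-corrected normal approximation matches wilcox.test", {
  set.seed(52)
  for (i in 1:10) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 13, replace = TRUE)
    mw <- mann_whitney_centered(x, y)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    expect_equal(mw$u, unname(wt$statistic))
    expect_equal(mw$p_value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("rank-biserial r reproduces the printed study effect sizes", {
  rows <- list(list(u = 42, r = 0.636), list(u = 45, r = 0.682),
               list(u = -39, r = -0.591), list(u = -18, r = -0.273),
               list(u = 28, r = 0.424), list(u = 27, r = 0.409),
               list(u = 24, r = 0.364), list(u = 10, r = 0.152),
               list(u = 4.5, r = 0.068), list(u = -11, r = -0.167))
  for (row in rows) {
    expect_equal(round(rank_biserial(row$u, 11, 12), 3), row$r)
  }
  expect_equal(rank_biserial(66, 11, 12), 1)
  expect_equal(rank_biserial(-66, 11, 12), -1)
  expect_error(rank_biserial(70, 11, 12), "exceed")
})

test_that("the Fisher-z interval reproduces the printed confidence limits", {
  rows <- list(
    list(u = 42, lo = "0.263", hi = "0.844"),
    list(u = 45, lo = "0.336", hi = "0.866"),
    list(u = -39, lo = "-0.822", hi = "-0.194"),
    list(u = -18, lo = "-0.642", hi = "0.2"),
    list(u = 28, lo = "-0.03", hi = "0.733"),
    list(u = 27, lo = "-0.048", hi = "0.724"),
    list(u = 24, lo = "-0.101", hi = "0.698"),
    list(u = 10, lo = "-0.318", hi = "0.562"),
    list(u = 4.5, lo = "-0.392", hi = "0.501"),
    list(u = -11, lo = "-0.572", hi = "0.304"))
  printed_digits <- function(s) {
    dec <- sub("^-?\\d+\\.?", "", s)
    nchar(dec)
  }
  for (row in rows) {
    ci <- rank_biserial_ci(rank_biserial(row$u, 11, 12), 11, 12)
    expect_equal(round(ci$ci_low, printed_digits(row$lo)), as.numeric(row$lo))
    expect_equal(round(ci$ci_high, printed_digits(row$hi)), as.numeric(row$hi))
  }
})

test_that("the CI is symmetric at r = 0, degenerate at |r| = 1, and shrinks with n", {
  ci0 <- rank_biserial_ci(0, 11, 12)
  expect_equal(ci0$ci_low, -ci0$ci_high)
  expect_warning(ci1 <- rank_biserial_ci(1, 11, 12), "degenerate")
  expect_equal(c(ci1$ci_low, ci1$ci_high), c(1, 1))
  widths <- vapply(c(5, 10, 20, 40), function(n) {
    ci <- rank_biserial_ci(0.4, n, n)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("group comparison is antisymmetric under label swap", {
  set.seed(53)
  d <- tibble::tibble(
    group = rep(c("young", "old"), c(11, 12)),
    m = c(rnorm(11, 1), rnorm(12))
  )
  fwd <- compare_groups(d, "m")
  rev <- compare_groups(d, "m", group_order = c("old", "young"))
  expect_equal(rev$u_centered, -fwd$u_centered)
  expect_equal(rev$r_rank_biserial, -fwd$r_rank_biserial)
  expect_equal(rev$ci_low, -fwd$ci_high)
  expect_equal(rev$p_value, fwd$p_value)
})

test_that("identical groups give zero effect everywhere", {
  d <- tibble::tibble(group = rep(c("young", "old"), each = 6),
                      m = rep(1:6, 2))
  cmp <- compare_groups(d, "m")
  expect_equal(cmp$u_centered, 0)
  expect_equal(cmp$r_rank_biserial, 0)
  expect_false(cmp$significant)
})

test_that("the type-I error rate of the comparison sits near the nominal level", {
  set.seed(54)
  hits <- vapply(1:50, function(i) {
    d <- tibble::tibble(group = rep(c("young", "old"), c(12, 12)),
                        m = rnorm(24))
    compare_groups(d, "m")$significant
  }, logical(1))
  expect_lt(mean(hits), 0.16)                      # ~5% nominal, 50 draws
})

test_that("tidy and glance expose the comparison in broom style", {
  d <- tibble::tibble(group = rep(c("young", "old"), c(5, 5)),
                      a = rnorm(10), b = rnorm(10))
  cmp <- compare_groups(d)
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  gl <- glance(cmp)
  expect_equal(gl$n_measures, 2)
  expect_equal(gl$group1, "young")
  lines <- format_comparison_table(cmp)
  expect_true(any(grepl("uncorrected", lines)))
})
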