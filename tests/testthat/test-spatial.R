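make_sheet_with_omissions <- function(om) {
  sch <- generate_main_schedule(1)
  sh <- score_session(perfect_session(sch))
  sh$position_omissions[] <- 0L
  for (nm in names(om)) sh$position_omissions[[nm]] <- om[[nm]]
  sh
}

test_that("vertical counts sum the upper and lower position sets", {
  sh <- make_sheet_with_omissions(list())
  expect_equal(vertical_counts(sh)$up, 0)
  expect_equal(vertical_counts(sh)$down, 0)
  # maximal omissions: all four up ids and all four down ids are
  # 9-presentation positions, so both sums are 36
  sh2 <- make_sheet_with_omissions(
    stats::setNames(as.list(sh$position_max), names(sh$position_max)))
  expect_equal(vertical_counts(sh2)$up, 36)
  expect_equal(vertical_counts(sh2)$down, 36)
  # side filters restrict the id sets
  sh3 <- make_sheet_with_omissions(list("3" = 4L, "6" = 2L))
  vc <- vertical_counts(sh3, "left_only")
  expect_equal(vc$up, 0)
  expect_equal(vc$down, 6)
  expect_equal(vertical_counts(sh3, "right_only")$down, 0)
})

test_that("signed-rank p-values match exhaustive enumeration and wilcox.test", {
  # all differences one-signed: most extreme one-sided p is 1/2^n
  a <- c(1, 2, 3, 4, 5, 6)
  b <- a + 2
  r <- wilcoxon_signed_rank(a, b, "less")
  expect_equal(r$p_value, 1 / 2^6)
  expect_equal(wilcoxon_signed_rank(b, a, "greater")$p_value, 1 / 2^6)
  # random tie-free pairs: equals both the brute-force oracle and wilcox.test
  set.seed(14)
  for (i in 1:10) {
    x <- round(rnorm(6), 2); y <- round(rnorm(6), 2)
    for (alt in c("greater", "less", "two_sided")) {
      r <- wilcoxon_signed_rank(x, y, alt)
      expect_equal(r$p_value, oracle_wilcoxon_p(x, y, alt))
      ralt <- sub("two_sided", "two.sided", alt)
      expect_equal(r$p_value,
                   wilcox.test(x, y, paired = TRUE, alternative = ralt,
                               exact = TRUE)$p.value)
    }
  }
  # enumeration handles ties through midranks (wilcox.test cannot go exact)
  x <- c(1, 2, 2, 5, 7, 9); y <- c(0, 4, 4, 1, 2, 3)
  expect_equal(wilcoxon_signed_rank(x, y, "two_sided")$p_value,
               oracle_wilcoxon_p(x, y, "two_sided"))
  # antisymmetry: swapping the pair reflects the statistic, negates the effect
  r1 <- wilcoxon_signed_rank(x, y, "greater")
  r2 <- wilcoxon_signed_rank(y, x, "greater")
  expect_equal(r1$effect_size_rrb, -r2$effect_size_rrb)
  expect_equal(r1$statistic + r2$statistic, 6 * 7 / 2)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "degenerate")
})

test_that("Mann-Whitney matches enumeration, wilcox.test, and its effect size bounds", {
  # complete separation
  r <- mann_whitney(1:5, 11:15)
  expect_equal(abs(r$effect_size_rrb), 1)
  expect_equal(mann_whitney(1:5, 1:5)$effect_size_rrb, 0)
  set.seed(21)
  for (i in 1:10) {
    a <- round(rnorm(5), 2); b <- round(rnorm(5), 2)
    for (alt in c("greater", "less", "two_sided")) {
      r <- mann_whitney(a, b, alt)
      expect_equal(r$p_value, oracle_mann_whitney_p(a, b, alt))
      ralt <- sub("two_sided", "two.sided", alt)
      expect_equal(r$p_value,
                   wilcox.test(a, b, alternative = ralt,
                               exact = TRUE)$p.value)
      expect_true(abs(r$effect_size_rrb) <= 1)
    }
  }
  # tied data stays exact via midrank enumeration
  a <- c(1, 2, 2, 3, 8); b <- c(2, 5, 5, 9, 9)
  expect_equal(mann_whitney(a, b, "two_sided")$p_value,
               oracle_mann_whitney_p(a, b, "two_sided"))
  # group swap flips the effect size sign
  expect_equal(mann_whitney(a, b)$effect_size_rrb,
               -mann_whitney(b, a)$effect_size_rrb)
})

test_that("Holm correction steps down correctly", {
  expect_equal(holm_adjust(0.03)$adjusted, 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04))$adjusted, c(0.02, 0.04))
  expect_equal(holm_adjust(rep(0.02, 5))$adjusted, rep(0.1, 5))
  set.seed(3)
  p <- runif(12)
  h <- holm_adjust(p)
  expect_true(all(h$adjusted >= p))
  ord <- order(p)
  expect_true(all(diff(h$adjusted[ord]) >= -1e-15))
  expect_equal(h$reject, h$adjusted <= 0.05)
})

test_that("phi coefficient matches the Pearson correlation of binary vectors", {
  expect_equal(phi_coefficient(matrix(c(10, 0, 0, 10), 2)), 1)
  # independent table: cell = product of margins / n
  expect_equal(phi_coefficient(matrix(c(8, 2, 32, 8), 2, byrow = TRUE)), 0)
  tab <- matrix(c(30, 8, 8, 56), 2, byrow = TRUE)
  x <- rep(c(1, 1, 0, 0), times = c(30, 8, 8, 56))
  y <- rep(c(1, 0, 1, 0), times = c(30, 8, 8, 56))
  expect_equal(phi_coefficient(tab), cor(x, y))
  # invariance under double swap, negation under single swap
  expect_equal(phi_coefficient(tab[2:1, 2:1]), phi_coefficient(tab))
  expect_equal(phi_coefficient(tab[2:1, ]), -phi_coefficient(tab))
  expect_warning(v <- phi_coefficient(matrix(c(5, 5, 0, 0), 2, byrow = TRUE)),
                 "undefined")
  expect_true(is.na(v))
})

test_that("median binarization screens positions as specified", {
  # cohort where neglect subjects fail position 1 and controls do not
  mk <- function(p1) make_sheet_with_omissions(list("1" = p1))
  # pooled lower median (7 subjects -> 4th smallest = 7) sits between groups
  sheets <- lapply(c(7L, 8L, 9L, 9L, 0L, 1L, 0L), mk)
  labels <- c(rep("neglect", 4), rep("no_neglect", 3))
  suppressWarnings(pd <- position_diagnostics(sheets, labels))
  expect_equal(pd$sensitivity[1], 1)
  expect_equal(pd$specificity[1], 1)
  # an all-zero position codes every subject 1: sensitivity 1, specificity 0
  w <- capture_warnings(pd <- position_diagnostics(sheets, labels))
  expect_match(w, "constant", all = FALSE)
  expect_equal(pd$sensitivity[14], 1)
  expect_equal(pd$specificity[14], 0)
})

test_that("the cohort vertical test runs the directional down > up hypothesis", {
  set.seed(8)
  sheets <- lapply(1:10, function(i)
    make_sheet_with_omissions(list("3" = sample(3:9, 1), "6" = sample(3:9, 1),
                                   "1" = sample(0:2, 1), "4" = sample(0:2, 1))))
  r <- vertical_neglect_test(sheets)
  expect_equal(r$alternative, "greater")
  expect_lt(r$p_value, 0.05)
  expect_gt(r$effect_size_rrb, 0)
  expect_equal(attr(r, "side_filter"), "all")
})
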