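#' Vertical (upper vs lower field) omission counts
#'
#' Sums a subject's omissions over the positions above the horizontal
#' midline (ids 1, 4, 8, 11) and below it (ids 3, 6, 10, 13). An optional
#' side filter restricts the sets to the left (ids <= 7) or right (ids >= 8)
#' hemifield; the default uses both sides. Output labels carry the filter so
#' the two conventions are never confused.
#'
#' @param sheet a `keen_scoresheet`
#' @param side_filter "all", "left_only" or "right_only"
#' @return list with `up`, `down` and `side_filter`
#' @export
vertical_counts <- function(sheet,
                            side_filter = c("all", "left_only", "right_only")) {
  side_filter <- match.arg(side_filter)
  up_ids <- c(1, 4, 8, 11)
  down_ids <- c(3, 6, 10, 13)
  keep <- switch(side_filter,
                 all = 1:14, left_only = 1:7, right_only = 8:14)
  om <- sheet$position_omissions
  list(up = sum(om[as.character(intersect(up_ids, keep))]),
       down = sum(om[as.character(intersect(down_ids, keep))]),
       side_filter = side_filter)
}

new_test_result <- function(statistic, p, r_rb, alternative, n, method) {
  structure(list(statistic = statistic, p_value = p,
                 effect_size_rrb = r_rb, alternative = alternative,
                 n = n, method = method),
            class = "keen_test")
}

#' @export
print.keen_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %g, p = %.4g (%s), r_rb = %.3f\n",
              x$method, x$statistic, x$p_value, x$alternative,
              x$effect_size_rrb))
  invisible(x)
}

#' Wilcoxon signed-rank test with exact enumeration and rank-biserial effect
#'
#' Tests paired samples on the differences `x - y` (zero differences
#' dropped, midranks for tied magnitudes). For n <= 12 retained pairs the
#' p-value is computed by exhaustive enumeration over all 2^n sign
#' assignments of the (mid)ranks — exact even under ties; for larger n the
#' normal approximation with tie-corrected variance is used (no continuity
#' correction). `alternative = "greater"` means `x` tends to exceed `y`. The
#' effect size is the matched-pairs rank-biserial correlation
#' `(W+ - W-) / (W+ + W-)`.
#'
#' @param x,y equal-length numeric vectors of paired observations
#' @param alternative "two_sided", "greater" or "less"
#' @return a `keen_test` with `statistic` (W = sum of positive-difference
#'   ranks), `p_value`, `effect_size_rrb`, `n` (retained pairs)
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; test is degenerate")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  S <- n * (n + 1) / 2
  r_rb <- (W - (S - W)) / S
  eps <- 1e-9
  if (n <= 12) {
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)  # all 2^n subset sums
    p <- switch(alternative,
                greater = mean(sums >= W - eps),
                less = mean(sums <= W + eps),
                two_sided = mean(abs(sums - S / 2) >= abs(W - S / 2) - eps))
    method <- "wilcoxon_signed_rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two_sided = 2 * stats::pnorm(-abs(z)))
    method <- "wilcoxon_signed_rank (normal approx.)"
  }
  new_test_result(W, min(p, 1), r_rb, alternative, n, method)
}

#' Mann-Whitney U test with exact enumeration and rank-biserial effect
#'
#' Two-sample rank test with midrank tie handling. U is the statistic for
#' the first group (`U = R1 - n1(n1+1)/2`). When `choose(n1+n2, n1)` is at
#' most 20000 the p-value is computed exactly by enumerating every group
#' assignment; otherwise the tie-corrected normal approximation is used (no
#' continuity correction). `alternative = "greater"` means group `a` tends
#' larger. The effect size is the rank-biserial correlation
#' `r_rb = 1 - 2U/(n1 n2)` (+1 when every `a` is below every `b`).
#'
#' @param a,b numeric vectors (both non-empty)
#' @param alternative "two_sided", "greater" or "less"
#' @return a `keen_test` with `statistic` (U), `p_value`,
#'   `effect_size_rrb`, `n` = c(n1, n2)
#' @export
mann_whitney <- function(a, b,
                         alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 > 0, n2 > 0)
  all_r <- rank(c(a, b))
  U <- sum(all_r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  r_rb <- 1 - 2 * U / (n1 * n2)
  eps <- 1e-9
  mu <- n1 * n2 / 2
  if (choose(n1 + n2, n1) <= 20000) {
    combos <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(all_r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
                greater = mean(Us >= U - eps),
                less = mean(Us <= U + eps),
                two_sided = mean(abs(Us - mu) >= abs(U - mu) - eps))
    method <- "mann_whitney (exact)"
  } else {
    n <- n1 + n2
    ties <- table(all_r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two_sided = 2 * stats::pnorm(-abs(z)))
    method <- "mann_whitney (normal approx.)"
  }
  new_test_result(U, min(p, 1), r_rb, alternative, c(n1, n2), method)
}

#' Holm step-down multiple-testing correction
#'
#' Wraps the standard step-down Holm procedure (with enforced monotonicity)
#' and reports the familywise decisions at `alpha`.
#'
#' @param p_values numeric vector in \[0, 1\]
#' @param alpha familywise error rate (default 0.05)
#' @return list with `adjusted` (numeric) and `reject` (logical)
#' @export
holm_adjust <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "holm")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Guilford phi coefficient of a 2x2 table
#'
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` — the Pearson correlation of two
#' binary variables. A zero margin makes the coefficient undefined; `NA` is
#' returned with a warning.
#'
#' @param tab 2x2 numeric matrix/table (rows: variable 1, cols: variable 2)
#' @return real in \[-1, 1\], or `NA`
#' @export
phi_coefficient <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    warning("phi is undefined: zero margin in the 2x2 table", call. = FALSE)
    return(NA_real_)
  }
  (a * d - b * c_) / sqrt(prod(margins))
}

lower_median <- function(v) sort(v)[floor((length(v) + 1) / 2)]

#' Per-position diagnostic screening by median binarization
#'
#' For each of the 14 positions, the cohort's pooled omission counts are
#' binarized at their pooled lower median (a sample value): counts greater
#' than or equal to the median code 1, below code 0. Sensitivity is the
#' proportion of neglect subjects coded 1; specificity the proportion of
#' non-neglect subjects coded 0. A position where every subject scores 0
#' (median = min = max) codes everyone 1 and therefore has sensitivity 1 but
#' specificity 0; a warning flags such degenerate positions.
#'
#' @param cohort_sheets list of `keen_scoresheet`
#' @param labels "neglect"/"no_neglect" vector, one per sheet
#' @return data.frame with `position`, `median`, `sensitivity`, `specificity`
#' @export
position_diagnostics <- function(cohort_sheets, labels) {
  labels <- as.character(labels)
  stopifnot(length(cohort_sheets) == length(labels),
            all(labels %in% CLASS_LEVELS))
  if (min(table(factor(labels, levels = CLASS_LEVELS))) < 2)
    stop("need at least 2 subjects per class")
  neg <- labels == "neglect"
  out <- data.frame(position = 1:14, median = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_)
  for (i in 1:14) {
    v <- vapply(cohort_sheets, function(s)
      as.numeric(s$position_omissions[[as.character(i)]]), numeric(1))
    med <- lower_median(v)
    code <- as.integer(v >= med)
    if (all(code == 1L))
      warning("position ", i,
              " is constant at the median; all subjects coded 1 (specificity 0)",
              call. = FALSE)
    out$median[i] <- med
    out$sensitivity[i] <- mean(code[neg] == 1L)
    out$specificity[i] <- mean(code[!neg] == 0L)
  }
  out
}

#' Directional vertical-neglect test over a cohort
#'
#' Computes per-subject upper- and lower-field omission counts via
#' [vertical_counts()] and compares them with the Wilcoxon signed-rank test.
#' The default directional hypothesis is that lower-field omissions exceed
#' upper-field omissions (the lower-left field is the typically neglected
#' region), i.e. `alternative = "greater"` on (down, up).
#'
#' @param cohort_sheets list of `keen_scoresheet`
#' @param side_filter passed to [vertical_counts()]
#' @param alternative passed to [wilcoxon_signed_rank()]; default "greater"
#'   tests down > up
#' @return a `keen_test` (plus `up`/`down` vectors as attributes)
#' @export
vertical_neglect_test <- function(cohort_sheets, side_filter = "all",
                                  alternative = "greater") {
  vc <- lapply(cohort_sheets, vertical_counts, side_filter = side_filter)
  up <- vapply(vc, `[[`, numeric(1), "up")
  down <- vapply(vc, `[[`, numeric(1), "down")
  res <- wilcoxon_signed_rank(down, up, alternative = alternative)
  attr(res, "up") <- up
  attr(res, "down") <- down
  attr(res, "side_filter") <- side_filter
  res
}
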