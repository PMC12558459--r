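#' Score a session into error counts and coefficients
#'
#' Implements the full scoring scheme. Sides are scored per trial and per
#' side, independently: a presented side absent from the report is a miss
#' (incrementing `LSU`/`RSU` on unilateral and `LSB`/`RSB` on bilateral
#' trials, plus the presented position's omission counter); a reported side
#' with no circle there is a spatial mislocalization "hallucination"
#' (`RH`/`LH`) — these opportunities exist only on unilateral trials of the
#' opposite side. A digit report that differs from the shown digit, or an
#' indefinite report (`NA`), is a digit error: `NIR`/`NIL` by the presented
#' side on unilateral trials, `NIB` on bilateral trials.
#'
#' The protocol constants BP (bilateral presentations) and LP (per-side
#' lateralized presentations) are recomputed from the session's schedule, so
#' truncated or non-standard schedules score correctly; the canonical main
#' series gives BP = 33 and LP = 54. The seven coefficients are computed from
#' the counts by [ka_bilateral()], [kpr()], [ka_all()] and [kef_all()];
#' zero-denominator cases yield a tagged `NA` with a warning, never a crash.
#'
#' @param record a validated `keen_session`
#' @return a `keen_scoresheet`: list with `position_omissions` and
#'   `position_max` (named integer vectors over ids 1--14), counts `RSU`,
#'   `LSU`, `RSB`, `LSB`, `RH`, `LH`, `NIR`, `NIL`, `NIB`, the seven
#'   coefficients `KA_bilateral`, `KPrR_bilateral`, `KPrL_bilateral`,
#'   `KA_all`, `KEf_all`, `KPrR_all`, `KPrL_all`, and `constants`
#'   (`BP`, `LP`).
#' @examples
#' sch <- generate_main_schedule(1)
#' ses <- simulate_session(profile_preset("control"), sch, seed = 2)
#' score_session(ses)
#' @export
score_session <- function(record) {
  stopifnot(inherits(record, "keen_session"))
  v <- validate_session(record)
  if (length(v)) stop("invalid session: ", paste(v, collapse = "; "))

  pos <- build_positions()
  tr <- record$schedule$trials
  resp <- record$responses[match(tr$trial_index, record$responses$trial_index), ]
  cnt <- schedule_counts(record$schedule)

  omis <- integer(14); names(omis) <- as.character(1:14)
  RSU <- LSU <- RSB <- LSB <- RH <- LH <- NIR <- NIL <- NIB <- 0L

  for (i in seq_len(nrow(tr))) {
    ids <- config_positions(tr$config_id[i])
    shown_sides <- pos$side[match(ids, pos$id)]
    rep_sides <- sides_reported(resp$reported_side[i])
    bilateral <- length(ids) == 2L
    for (k in seq_along(ids)) {
      if (!(shown_sides[k] %in% rep_sides)) {
        omis[as.character(ids[k])] <- omis[as.character(ids[k])] + 1L
        if (bilateral) {
          if (shown_sides[k] == "left") LSB <- LSB + 1L else RSB <- RSB + 1L
        } else {
          if (shown_sides[k] == "left") LSU <- LSU + 1L else RSU <- RSU + 1L
        }
      }
    }
    for (s in setdiff(rep_sides, shown_sides)) {
      if (s == "right") RH <- RH + 1L else LH <- LH + 1L
    }
    digit_err <- is.na(resp$reported_digit[i]) ||
      resp$reported_digit[i] != tr$digit[i]
    if (digit_err) {
      if (bilateral) NIB <- NIB + 1L
      else if (shown_sides[1] == "left") NIL <- NIL + 1L
      else NIR <- NIR + 1L
    }
  }

  BP <- cnt$n_bilateral
  LP <- cnt$lp_left  # equals lp_right for the standard protocol
  sheet <- structure(list(
    position_omissions = omis,
    position_max = cnt$position_presentations,
    RSU = RSU, LSU = LSU, RSB = RSB, LSB = LSB,
    RH = RH, LH = LH, NIR = NIR, NIL = NIL, NIB = NIB,
    KA_bilateral = ka_bilateral(LSB, RSB, BP),
    KPrR_bilateral = NA_real_, KPrL_bilateral = NA_real_,
    KA_all = ka_all(LSU, LSB, RSU, RSB, LP),
    KEf_all = kef_all(LSU, LSB, RSU, RSB, RH, LH, LP),
    KPrR_all = NA_real_, KPrL_all = NA_real_,
    constants = list(BP = BP, LP = LP)
  ), class = "keen_scoresheet")
  sheet$KPrR_bilateral <- kpr("right", "bilateral", sheet)
  sheet$KPrL_bilateral <- kpr("left", "bilateral", sheet)
  sheet$KPrR_all <- kpr("right", "all", sheet)
  sheet$KPrL_all <- kpr("left", "all", sheet)
  sheet
}

#' @export
print.keen_scoresheet <- function(x, ...) {
  cat("<keen_scoresheet>\n")
  cat(sprintf("  misses  L: uni %2d  bi %2d   R: uni %2d  bi %2d\n",
              x$LSU, x$LSB, x$RSU, x$RSB))
  cat(sprintf("  halluc  L: %d  R: %d   digit errs L/R/B: %d/%d/%d\n",
              x$LH, x$RH, x$NIL, x$NIR, x$NIB))
  cat(sprintf("  KA_bilateral %.3f  KA_all %.3f  KEf_all %.3f\n",
              x$KA_bilateral, x$KA_all, x$KEf_all))
  cat(sprintf("  KPr bilateral L/R %.3f/%.3f  all L/R %.3f/%.3f\n",
              x$KPrL_bilateral, x$KPrR_bilateral, x$KPrL_all, x$KPrR_all))
  invisible(x)
}

undefined_coef <- function(name) {
  warning(name, " is undefined (zero denominator); returning NA", call. = FALSE)
  NA_real_
}

#' Asymmetry coefficient for bilateral presentations
#'
#' `(LSB - RSB) / (2 * BP - RSB - LSB)`: the signed imbalance of left vs
#' right misses among bilateral trials, normalized by the number of circles
#' actually detected. Ranges over \[-1, 1\]; 0 means no lateral bias, +1
#' complete left extinction. `NA` (with a warning) when every circle of both
#' sides was missed, so the denominator is zero.
#'
#' @param LSB,RSB missed left/right circles on bilateral trials
#' @param BP number of bilateral presentations (33 in the standard protocol)
#' @return real in \[-1, 1\], or `NA` if undefined
#' @export
ka_bilateral <- function(LSB, RSB, BP) {
  check_count(LSB, 0, BP, "LSB"); check_count(RSB, 0, BP, "RSB")
  den <- 2 * BP - RSB - LSB
  if (den == 0) return(undefined_coef("KA_bilateral"))
  (LSB - RSB) / den
}

#' Overall asymmetry coefficient
#'
#' `(LSB + LSU - RSB - RSU) / (2 * LP - RSB - RSU - LSB - LSU)`: the broadest
#' index of lateral bias over both unilateral and bilateral presentations.
#' Ranges over \[-1, 1\]; +1 is total left neglect. `NA` with a warning when
#' no circle on either side was detected.
#'
#' @param LSU,LSB,RSU,RSB per-side miss counts
#' @param LP lateralized presentations per side (54 in the standard protocol)
#' @return real in \[-1, 1\], or `NA` if undefined
#' @export
ka_all <- function(LSU, LSB, RSU, RSB, LP) {
  check_count(LSU + LSB, 0, LP, "LSU + LSB")
  check_count(RSU + RSB, 0, LP, "RSU + RSB")
  den <- 2 * LP - RSB - RSU - LSB - LSU
  if (den == 0) return(undefined_coef("KA_all"))
  (LSB + LSU - RSB - RSU) / den
}

#' Productivity coefficient (proportion of detected circles on one side)
#'
#' Bilateral scope: `(BP - miss_side_bilateral) / BP`. All-presentations
#' scope: `(LP - miss_side_bilateral - miss_side_unilateral) / LP`. Ranges
#' over \[0, 1\]; 1 means every circle on that side was detected.
#'
#' @param side "left" or "right"
#' @param scope "bilateral" or "all"
#' @param sheet a `keen_scoresheet` (or any list carrying the counts and
#'   `constants`)
#' @return real in \[0, 1\]
#' @export
kpr <- function(side = c("left", "right"), scope = c("bilateral", "all"),
                sheet) {
  side <- match.arg(side); scope <- match.arg(scope)
  miss_b <- if (side == "left") sheet$LSB else sheet$RSB
  miss_u <- if (side == "left") sheet$LSU else sheet$RSU
  if (scope == "bilateral") {
    BP <- sheet$constants$BP
    (BP - miss_b) / BP
  } else {
    LP <- sheet$constants$LP
    (LP - miss_b - miss_u) / LP
  }
}

#' Overall efficiency coefficient
#'
#' `(D - H) / (D + H)` with `D = 2 * LP - RSB - RSU - LSB - LSU` (circles
#' detected) and `H = RH + LH` (spatial mislocalization reports). Penalizes
#' allochiria-style errors: 1 when there are none. The formula's range is
#' (-1, 1\] (negative when mislocalizations outnumber detections); `NA` with
#' a warning when `D + H = 0`.
#'
#' @param LSU,LSB,RSU,RSB miss counts
#' @param RH,LH hallucination counts
#' @param LP lateralized presentations per side
#' @return real in (-1, 1\], or `NA` if undefined
#' @export
kef_all <- function(LSU, LSB, RSU, RSB, RH, LH, LP) {
  check_count(LSU + LSB, 0, LP, "LSU + LSB")
  check_count(RSU + RSB, 0, LP, "RSU + RSB")
  check_count(RH, 0, Inf, "RH"); check_count(LH, 0, Inf, "LH")
  D <- 2 * LP - RSB - RSU - LSB - LSU
  H <- RH + LH
  if (D + H == 0) return(undefined_coef("KEf_all"))
  (D - H) / (D + H)
}

check_count <- function(x, lo, hi, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(name, " out of range [", lo, ", ", hi, "]")
  invisible(x)
}

#' Per-position omission percentages
#'
#' Normalizes each position's omission count by its presentation count
#' (6 for positions 2, 5, 7, 9, 12, 14; 9 for the rest, in the standard main
#' series), enabling comparison across positions with different presentation
#' frequencies.
#'
#' @param sheet a `keen_scoresheet`
#' @return named numeric vector of percentages over ids 1--14
#' @export
omission_percentages <- function(sheet) {
  stopifnot(inherits(sheet, "keen_scoresheet"))
  100 * sheet$position_omissions / sheet$position_max
}

#' Flatten a score sheet to a one-row data.frame
#'
#' Column vocabulary matches the raw-database layout: per-position omission
#' counts `pos1..pos14`, the nine error counts and the seven coefficients.
#'
#' @param sheet a `keen_scoresheet`
#' @param subject_id optional id column value
#' @return one-row data.frame
#' @export
scoresheet_row <- function(sheet, subject_id = NA_character_) {
  stopifnot(inherits(sheet, "keen_scoresheet"))
  row <- data.frame(subject_id = subject_id, stringsAsFactors = FALSE)
  for (i in 1:14) row[[paste0("pos", i)]] <- sheet$position_omissions[[as.character(i)]]
  for (nm in c("RSU", "LSU", "RSB", "LSB", "RH", "LH", "NIR", "NIL", "NIB",
               "KA_bilateral", "KPrR_bilateral", "KPrL_bilateral",
               "KA_all", "KEf_all", "KPrR_all", "KPrL_all"))
    row[[nm]] <- sheet[[nm]]
  row
}

#' Write score sheets to a cohort CSV
#' @param sheets list of `keen_scoresheet`
#' @param path output path
#' @param subject_ids optional character vector
#' @param labels optional character vector (e.g. neglect / no_neglect)
#' @export
write_scores_csv <- function(sheets, path, subject_ids = NULL, labels = NULL) {
  rows <- do.call(rbind, lapply(seq_along(sheets), function(i)
    scoresheet_row(sheets[[i]],
                   if (is.null(subject_ids)) sprintf("S%03d", i)
                   else subject_ids[i])))
  if (!is.null(labels)) rows$label <- labels
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
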