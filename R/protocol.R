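#' Target positions of the stimulus display
#'
#' The display uses 14 possible circle positions, 7 per hemifield, arranged
#' symmetrically about the vertical midline of the screen. Offsets are in
#' centimetres from screen centre; negative x is left of centre, positive y is
#' above centre. Positions on the horizontal midline (y = 0) form the middle
#' band; the remainder fall in the upper or lower band and support the
#' vertical-neglect analyses.
#'
#' @return A data.frame with one row per position and columns `id` (1--14),
#'   `x_cm`, `y_cm`, `side` ("left"/"right") and `band`
#'   ("upper"/"middle"/"lower").
#' @examples
#' pos <- build_positions()
#' subset(pos, band == "lower")
#' @export
build_positions <- function() {
  x <- c(-13.5, -13.5, -13.5, -7.5, -7.5, -7.5, -1.5,
         13.5, 13.5, 13.5, 7.5, 7.5, 7.5, 1.5)
  y <- c(8, 0, -8, 4, 0, -4, 0,
         8, 0, -8, 4, 0, -4, 0)
  data.frame(
    id = 1:14,
    x_cm = x,
    y_cm = y,
    side = ifelse(x < 0, "left", "right"),
    band = ifelse(y > 0, "upper", ifelse(y < 0, "lower", "middle")),
    stringsAsFactors = FALSE
  )
}

#' Stimulus configurations of the main series
#'
#' Each trial presents one of 25 configurations: 14 unilateral (a single
#' circle at one of the positions), 7 bilateral pairs symmetric about the
#' vertical axis (1+8, ..., 7+14), and 4 bilateral pairs symmetric about a
#' diagonal axis (1+10, 3+8, 4+13, 6+11). Every bilateral configuration pairs
#' exactly one left with one right position.
#'
#' @return A data.frame with columns `config_id` (1--25), `pos1`, `pos2`
#'   (`NA` for unilateral) and `kind` ("unilateral",
#'   "bilateral_vertical_symmetric", "bilateral_diagonal").
#' @export
build_configurations <- function() {
  uni <- data.frame(config_id = 1:14, pos1 = 1:14, pos2 = NA_integer_,
                    kind = "unilateral", stringsAsFactors = FALSE)
  vert <- data.frame(config_id = 15:21, pos1 = 1:7, pos2 = 8:14,
                     kind = "bilateral_vertical_symmetric",
                     stringsAsFactors = FALSE)
  diag <- data.frame(config_id = 22:25,
                     pos1 = c(1L, 3L, 4L, 6L), pos2 = c(10L, 8L, 13L, 11L),
                     kind = "bilateral_diagonal", stringsAsFactors = FALSE)
  rbind(uni, vert, diag)
}

#' Position ids shown by a configuration
#' @param config_id integer configuration id (1--25)
#' @return integer vector of 1 or 2 position ids
#' @export
config_positions <- function(config_id) {
  cfg <- build_configurations()
  row <- cfg[cfg$config_id == config_id, ]
  if (nrow(row) != 1L) stop("unknown config_id: ", config_id)
  ids <- c(row$pos1, row$pos2)
  ids[!is.na(ids)]
}

# Run expr with a temporary, seeded RNG state; the caller's RNG is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

new_schedule <- function(trials, seed, kind) {
  structure(list(trials = trials, seed = seed, kind = kind),
            class = "keen_schedule")
}

#' Generate the 75-trial main series
#'
#' Builds the standard main series: each of the 25 configurations repeated 3
#' times, presented in a seeded uniform random order. The central digit shown
#' on each trial is drawn i.i.d. uniformly from 1--4. Timing per trial is
#' fixed: 1000 ms fixation cross, 100 ms stimulus (8 mm circle(s) plus
#' central digit), 2000 ms mask.
#'
#' The resulting design constants follow by counting: 42 unilateral and 33
#' bilateral trials; 54 circle presentations per side; positions 2, 5, 7, 9,
#' 12, 14 shown 6 times each and all other positions 9 times.
#'
#' @param seed non-negative integer; identical seeds give identical schedules.
#' @return A `keen_schedule`: list with `trials` (data.frame: `trial_index`,
#'   `config_id`, `digit`, `fixation_ms`, `stimulus_ms`, `mask_ms`,
#'   `circle_diameter_mm`), `seed`, and `kind = "main"`.
#' @examples
#' sch <- generate_main_schedule(seed = 1)
#' table(schedule_counts(sch)$position_presentations)
#' @export
generate_main_schedule <- function(seed) {
  stopifnot(length(seed) == 1L, is.numeric(seed), seed >= 0, seed == floor(seed))
  cfg_ids <- rep(build_configurations()$config_id, each = 3L)
  with_seed(seed, {
    ord <- sample.int(length(cfg_ids))
    digits <- sample(1:4, length(cfg_ids), replace = TRUE)
    trials <- data.frame(
      trial_index = seq_along(cfg_ids),
      config_id = cfg_ids[ord],
      digit = digits,
      fixation_ms = 1000L,
      stimulus_ms = 100L,
      mask_ms = 2000L,
      circle_diameter_mm = 8,
      stringsAsFactors = FALSE
    )
    new_schedule(trials, as.integer(seed), "main")
  })
}

#' Generate the 7-trial training series
#'
#' Training familiarizes the participant with the task: 7 trials whose
#' stimulus duration descends linearly from 1000 ms to 100 ms
#' (1000, 850, ..., 100) while the number of circles, their side and their
#' eccentricity vary across trials. The configuration set is fixed (far/near
#' unilateral left and right, vertical-symmetric and diagonal bilateral
#' pairs); the digits are drawn from the seeded RNG.
#'
#' @param seed non-negative integer
#' @return A `keen_schedule` with 7 trials and `kind = "training"`.
#' @export
generate_training_schedule <- function(seed) {
  stopifnot(length(seed) == 1L, is.numeric(seed), seed >= 0, seed == floor(seed))
  # fixed spread over count x side x eccentricity: uni far-L, uni near-R,
  # bilateral mid, uni near-L, uni far-R, diagonal bilateral, bilateral mid
  cfg_ids <- c(1L, 14L, 16L, 7L, 9L, 22L, 19L)
  durations <- as.integer(seq(1000L, 100L, length.out = 7L))
  with_seed(seed, {
    trials <- data.frame(
      trial_index = 1:7,
      config_id = cfg_ids,
      digit = sample(1:4, 7L, replace = TRUE),
      fixation_ms = 1000L,
      stimulus_ms = durations,
      mask_ms = 2000L,
      circle_diameter_mm = 8,
      stringsAsFactors = FALSE
    )
    new_schedule(trials, as.integer(seed), "training")
  })
}

#' Design counts of a schedule
#'
#' Counts, from the schedule itself, the constants the scoring formulas rely
#' on: the number of bilateral presentations (BP), the per-side number of
#' lateralized circle presentations (LP, equal left and right for the
#' standard protocol), unilateral trial counts per side, and per-position
#' presentation counts. These are always derived by counting so truncated or
#' non-standard schedules score correctly; the standard main series yields
#' BP = 33 and LP = 54.
#'
#' @param schedule a `keen_schedule`
#' @return list with `n_trials`, `n_unilateral`, `n_bilateral` (= BP),
#'   `n_unilateral_left`, `n_unilateral_right`, `lp_left`, `lp_right`,
#'   `position_presentations` (named integer vector over ids 1--14).
#' @export
schedule_counts <- function(schedule) {
  stopifnot(inherits(schedule, "keen_schedule"))
  cfg <- build_configurations()
  pos <- build_positions()
  tr <- schedule$trials
  kind <- cfg$kind[match(tr$config_id, cfg$config_id)]
  bilateral <- kind != "unilateral"
  pp <- integer(14)
  names(pp) <- as.character(1:14)
  uni_left <- 0L; uni_right <- 0L
  for (cid in tr$config_id) {
    ids <- config_positions(cid)
    pp[as.character(ids)] <- pp[as.character(ids)] + 1L
    if (length(ids) == 1L) {
      if (pos$side[pos$id == ids] == "left") uni_left <- uni_left + 1L
      else uni_right <- uni_right + 1L
    }
  }
  side_of <- pos$side[match(1:14, pos$id)]
  list(
    n_trials = nrow(tr),
    n_unilateral = sum(!bilateral),
    n_bilateral = sum(bilateral),
    n_unilateral_left = uni_left,
    n_unilateral_right = uni_right,
    lp_left = sum(pp[side_of == "left"]),
    lp_right = sum(pp[side_of == "right"]),
    position_presentations = pp
  )
}

#' Convert a centimetre offset to degrees of visual angle
#'
#' Uses the centre-referenced arctangent convention:
#' `atan(offset / distance)` in degrees. The default viewing distance is the
#' protocol's 60 cm.
#'
#' @param offset_cm signed offset from screen centre (cm)
#' @param distance_cm viewing distance (cm), must be positive
#' @return degrees of visual angle (signed like `offset_cm`)
#' @examples
#' cm_to_visual_angle(1.5, 60)   # ~1.43 degrees, the nearest positions
#' cm_to_visual_angle(13.5, 60)  # the most eccentric positions
#' @export
cm_to_visual_angle <- function(offset_cm, distance_cm = 60) {
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0))
    stop("distance_cm must be positive")
  atan(offset_cm / distance_cm) * 180 / pi
}

#' @export
print.keen_schedule <- function(x, ...) {
  cat(sprintf("<keen_schedule: %s series, %d trials, seed %d>\n",
              x$kind, nrow(x$trials), x$seed))
  invisible(x)
}

#' Write a schedule to JSON (full fidelity, including the seed)
#' @param schedule a `keen_schedule`
#' @param path output file path
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "keen_schedule"))
  jsonlite::write_json(
    list(kind = schedule$kind, seed = schedule$seed, trials = schedule$trials),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a schedule from JSON written by [write_schedule_json()]
#' @param path input file path
#' @return a `keen_schedule`
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- as.data.frame(obj$trials, stringsAsFactors = FALSE)
  tr$trial_index <- as.integer(tr$trial_index)
  tr$config_id <- as.integer(tr$config_id)
  tr$digit <- as.integer(tr$digit)
  tr$fixation_ms <- as.integer(tr$fixation_ms)
  tr$stimulus_ms <- as.integer(tr$stimulus_ms)
  tr$mask_ms <- as.integer(tr$mask_ms)
  new_schedule(tr, as.integer(obj$seed), obj$kind)
}

#' Export a schedule as CSV (one row per trial)
#' @param schedule a `keen_schedule`
#' @param path output file path
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "keen_schedule"))
  tr <- schedule$trials
  tr$position_ids <- vapply(tr$config_id, function(cid)
    paste(config_positions(cid), collapse = "+"), character(1))
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
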