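#' Construct a session record
#'
#' A session record binds a stimulus schedule to the participant's per-trial
#' verbal reports. Each response carries the reported side(s) — `"left"`,
#' `"right"`, `"both"` or `"none"` (the last covering indefinite reports such
#' as "something flashed" with no side) — and the reported central digit,
#' `NA` meaning an indefinite digit report ("I didn't see").
#'
#' @param subject_id character subject identifier
#' @param schedule a `keen_schedule`
#' @param responses data.frame with columns `trial_index`, `reported_side`
#'   (one of left/right/both/none, case-insensitive) and `reported_digit`
#'   (integer 1--4 or `NA`)
#' @param metadata optional named list (group label, external test outcomes
#'   such as paper-and-pencil neglect screens)
#' @return a `keen_session` object
#' @export
keen_session <- function(subject_id, schedule, responses, metadata = list()) {
  stopifnot(inherits(schedule, "keen_schedule"), is.data.frame(responses))
  responses$reported_side <- normalize_side(responses$reported_side)
  responses$trial_index <- as.integer(responses$trial_index)
  responses$reported_digit <- suppressWarnings(as.integer(responses$reported_digit))
  rec <- structure(list(subject_id = as.character(subject_id),
                        schedule = schedule,
                        responses = responses,
                        metadata = metadata),
                   class = "keen_session")
  v <- validate_session(rec)
  if (length(v)) stop("invalid session: ", paste(v, collapse = "; "))
  rec
}

normalize_side <- function(x) {
  x <- tolower(trimws(as.character(x)))
  ok <- x %in% c("left", "right", "both", "none")
  if (any(!ok))
    stop("unknown side token(s) at row(s) ",
         paste(which(!ok), collapse = ", "), ": ",
         paste(unique(x[!ok]), collapse = ", "))
  x
}

#' Sides contained in a side token
#' @param token "left", "right", "both" or "none"
#' @return character vector of 0, 1 or 2 sides
#' @export
sides_reported <- function(token) {
  switch(token,
         left = "left", right = "right",
         both = c("left", "right"),
         none = character(0),
         stop("unknown side token: ", token))
}

#' Validate a session record
#'
#' Checks the structural invariants: response rows align one-to-one with the
#' schedule's trials, digits are in 1--4 or `NA`, side tokens are legal, and
#' the schedule is a legal protocol (each configuration id known; for a main
#' schedule, every configuration appearing with equal multiplicity).
#' Violations are returned, not raised.
#'
#' @param record a `keen_session`
#' @return character vector of violations; empty if the record is valid
#' @export
validate_session <- function(record) {
  out <- character(0)
  r <- record$responses
  tr <- record$schedule$trials
  if (nrow(r) != nrow(tr))
    out <- c(out, sprintf("response count %d does not match trial count %d",
                          nrow(r), nrow(tr)))
  dangling <- setdiff(r$trial_index, tr$trial_index)
  if (length(dangling))
    out <- c(out, paste("dangling trial index:",
                        paste(dangling, collapse = ", ")))
  bad_digit <- !is.na(r$reported_digit) & !(r$reported_digit %in% 1:4)
  if (any(bad_digit))
    out <- c(out, paste("reported digit outside 1-4 at row(s)",
                        paste(which(bad_digit), collapse = ", ")))
  bad_side <- !(r$reported_side %in% c("left", "right", "both", "none"))
  if (any(bad_side))
    out <- c(out, paste("unknown side token at row(s)",
                        paste(which(bad_side), collapse = ", ")))
  known <- build_configurations()$config_id
  if (!all(tr$config_id %in% known))
    out <- c(out, "schedule contains unknown configuration ids")
  if (identical(record$schedule$kind, "main")) {
    mult <- table(factor(tr$config_id, levels = known))
    if (length(unique(as.integer(mult))) != 1L)
      out <- c(out, "configuration multiplicity is not uniform over the 25 configurations")
  }
  out
}

#' @export
print.keen_session <- function(x, ...) {
  cat(sprintf("<keen_session: subject %s, %d trials (%s series)>\n",
              x$subject_id, nrow(x$responses), x$schedule$kind))
  invisible(x)
}

session_csv_table <- function(record) {
  tr <- record$schedule$trials
  r <- record$responses[match(tr$trial_index, record$responses$trial_index), ]
  data.frame(
    subject_id = record$subject_id,
    trial_index = tr$trial_index,
    config_id = tr$config_id,
    shown_digit = tr$digit,
    reported_side = r$reported_side,
    reported_digit = ifelse(is.na(r$reported_digit), "NA",
                            as.character(r$reported_digit)),
    stringsAsFactors = FALSE
  )
}

#' Write a session to disk
#'
#' Two dialects: `"json"` bundles schedule (with seed), responses and
#' metadata losslessly; `"csv"` writes one row per trial
#' (`subject_id, trial_index, config_id, shown_digit, reported_side,
#' reported_digit`) with the indefinite digit serialized as `NA`. The CSV
#' dialect is UTF-8, comma-separated, dot-decimal. CSV roundtrips require the
#' schedule seed, which is embedded as a `# schedule_seed:` comment header.
#'
#' @param record a `keen_session`
#' @param path output file path
#' @param format "json" or "csv"
#' @export
write_session <- function(record, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "keen_session"))
  if (format == "json") {
    obj <- list(
      subject_id = record$subject_id,
      schedule = list(kind = record$schedule$kind,
                      seed = record$schedule$seed,
                      trials = record$schedule$trials),
      responses = data.frame(
        trial_index = record$responses$trial_index,
        reported_side = record$responses$reported_side,
        reported_digit = record$responses$reported_digit),
      metadata = record$metadata)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("# schedule_seed: %d kind: %s",
                       record$schedule$seed, record$schedule$kind), con)
    utils::write.csv(session_csv_table(record), con,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' Side tokens are normalized case-insensitively; misaligned trial counts,
#' unknown tokens and out-of-range digits raise a format error naming the
#' offending rows.
#'
#' @param path input file path
#' @param format "json" or "csv"; defaults from the file extension
#' @return a validated `keen_session`
#' @export
read_session <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    sch <- new_schedule(as.data.frame(obj$schedule$trials),
                        as.integer(obj$schedule$seed), obj$schedule$kind)
    resp <- as.data.frame(obj$responses, stringsAsFactors = FALSE)
    meta <- if (is.null(obj$metadata)) list() else as.list(obj$metadata)
    keen_session(obj$subject_id, sch, resp, meta)
  } else {
    head1 <- readLines(path, n = 1L)
    m <- regmatches(head1,
                    regexec("# schedule_seed: (\\d+) kind: (\\w+)", head1))[[1]]
    if (length(m) != 3L)
      stop("session CSV is missing the '# schedule_seed:' header line")
    seed <- as.integer(m[2]); kind <- m[3]
    sch <- if (kind == "main") generate_main_schedule(seed)
           else generate_training_schedule(seed)
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = "NA")
    need <- c("subject_id", "trial_index", "reported_side", "reported_digit")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("session CSV missing column(s): ", paste(miss, collapse = ", "))
    keen_session(tab$subject_id[1], sch,
                 tab[, c("trial_index", "reported_side", "reported_digit")])
  }
}
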