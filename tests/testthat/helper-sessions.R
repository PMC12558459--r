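# Deterministic response builders used across test files.

# A session whose participant reports a fixed side token on every trial.
fixed_side_session <- function(schedule, token, digits_correct = TRUE) {
  tr <- schedule$trials
  keen_session("fixed", schedule, data.frame(
    trial_index = tr$trial_index,
    reported_side = token,
    reported_digit = if (digits_correct) tr$digit
                     else ((tr$digit %% 4) + 1L)))
}

# A flawless participant: reports exactly the presented side(s) and the digit.
perfect_session <- function(schedule) {
  tr <- schedule$trials
  pos <- build_positions()
  tok <- vapply(tr$config_id, function(cid) {
    sides <- unique(pos$side[match(config_positions(cid), pos$id)])
    if (length(sides) == 2) "both" else sides
  }, character(1))
  keen_session("perfect", schedule, data.frame(
    trial_index = tr$trial_index,
    reported_side = tok,
    reported_digit = tr$digit))
}
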