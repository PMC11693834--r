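# Behavioural coding: stay/leave labels, exploratory choice events, and the
# inclusion rule. A trial is a "leave" when the next trial is played with a
# different character; the label sits on the trial *preceding* the switch
# (the decision point), so predictors computed up to that trial are the
# information available when the decision was made. The session's final
# trial is censored (no subsequent observation), not coerced to "stay".

#' Label each trial of a session as stay or leave
#'
#' @param session data.frame of one participant's trials, sorted by `trial`,
#'   with a `character_id` column.
#' @return Character vector (`"stay"`/`"leave"`, `NA` for the censored final
#'   trial), one element per row.
#' @export
label_leave_stay <- function(session) {
  n <- nrow(session)
  if (n < 1L) stop("session must contain at least one trial", call. = FALSE)
  ch <- as.character(session$character_id)
  labs <- rep(NA_character_, n)
  if (n > 1L) labs[1:(n - 1L)] <- ifelse(ch[-1L] != ch[-n], "leave", "stay")
  labs
}

#' Extract exploratory choice events from a session
#'
#' One event per leave: the character switched away from, the character
#' chosen, and the unique third character that was the unchosen alternative.
#' Switches to a character never visited before are flagged
#' (`is_first_visit_to_chosen`); expectations are undefined there, so
#' modeling excludes them.
#'
#' @param session data.frame of one participant's trials, sorted by `trial`.
#' @param characters All character ids in the task (must have length 3 to
#'   resolve the alternative). Defaults to the ids observed in the session
#'   if exactly three occur.
#' @return data.frame with columns `participant_id`, `at_trial` (the trial
#'   carrying the leave label), `from_character`, `chosen_character`,
#'   `alternative_character`, `is_first_visit_to_chosen`. Zero rows when
#'   there are no switches.
#' @export
extract_choice_events <- function(session, characters = NULL) {
  chars <- as.character(characters %||% sort(unique(session$character_id)))
  labs <- label_leave_stay(session)
  idx <- which(labs == "leave")
  empty <- data.frame(participant_id = character(0), at_trial = integer(0),
                      from_character = character(0), chosen_character = character(0),
                      alternative_character = character(0),
                      is_first_visit_to_chosen = logical(0))
  if (!length(idx)) return(empty)
  if (length(chars) != 3L) {
    stop("resolving the unchosen alternative requires exactly 3 character ids",
         call. = FALSE)
  }
  ch <- as.character(session$character_id)
  ev <- lapply(idx, function(t) {
    from <- ch[t]
    chosen <- ch[t + 1L]
    alt <- setdiff(chars, c(from, chosen))
    data.frame(participant_id = session$participant_id[t],
               at_trial = session$trial[t], from_character = from,
               chosen_character = chosen, alternative_character = alt,
               is_first_visit_to_chosen = !chosen %in% ch[seq_len(t)])
  })
  do.call(rbind, ev)
}

#' Inclusion rule: at least `min_trials` trials with every character
#'
#' @param session data.frame of one participant's trials.
#' @param characters All character ids in the task (default: observed ids).
#'   A character never played counts 0 trials and fails the rule.
#' @param min_trials Minimum trials per character (default 10).
#' @return Logical flag.
#' @export
apply_inclusion <- function(session, characters = NULL, min_trials = 10) {
  chars <- as.character(characters %||% sort(unique(session$character_id)))
  counts <- vapply(chars, function(k) sum(session$character_id == k), integer(1))
  all(counts >= min_trials)
}

#' Code stay/leave and within-character trial numbers for a whole dataset
#'
#' Applies [label_leave_stay()] per participant and derives
#' `within_character_trial` (resets to 1 at session start and after every
#' switch).
#'
#' @param data Trial-log data.frame for one or more participants.
#' @return The input with columns `stay_leave` and `within_character_trial`
#'   appended.
#' @export
code_behavior <- function(data) {
  parts <- split(seq_len(nrow(data)), data$participant_id)
  data$stay_leave <- NA_character_
  data$within_character_trial <- NA_integer_
  for (rows in parts) {
    s <- data[rows, ]
    if (is.unsorted(s$trial, strictly = TRUE)) {
      stop("trial indices must be strictly increasing within participant",
           call. = FALSE)
    }
    data$stay_leave[rows] <- label_leave_stay(s)
    ch <- as.character(s$character_id)
    wct <- integer(length(ch))
    for (i in seq_along(ch)) {
      wct[i] <- if (i == 1L || ch[i] != ch[i - 1L]) 1L else wct[i - 1L] + 1L
    }
    data$within_character_trial[rows] <- wct
  }
  data
}
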