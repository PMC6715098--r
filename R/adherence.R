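# Rule-based adherence monitoring: red/orange flags, orange->red escalation,
# the trainer ticket lifecycle, notification throttling, and CheerSquad
# milestone events. "Emails" are modeled as events in an outbox log, never
# actually sent.

.RED_CAUSES <- c("more_incorrect_than_correct", "zero_correct",
                 "below_predefined_level", "decrease_in_performance",
                 "adherence_escalation")
.ORANGE_CAUSES <- c("session_overlong", "absence")

#' Adherence-monitoring configuration
#'
#' All thresholds of the flag system, with defaults equal to the delivery
#' rules' stated values: a decrease flag at a >= 10% decline across
#' consecutive attempts, an overlong-session flag beyond 90 minutes, an
#' absence flag at a 72-hour gap between sessions, escalation at the 3rd
#' orange flag, and automatic participant emails capped at 1 every 72 hours.
#'
#' @param decrease_threshold fractional decline triggering the
#'   decrease-in-performance flag (default 0.10).
#' @param session_duration_limit minutes; sessions strictly longer are
#'   flagged (default 90).
#' @param absence_limit hours; gaps of at least this are flagged
#'   (default 72).
#' @param orange_escalation_count orange flags per red escalation
#'   (default 3).
#' @param email_window hours defining the automatic-email cap window
#'   (default 72).
#' @param email_cap_per_window automatic emails allowed per window
#'   (default 1).
#' @param default_predefined_level minimum acceptable raw score for
#'   exercises without an entry in `predefined_levels`; the default is 10%
#'   of the 0-100 native scale.
#' @param predefined_levels optional named numeric vector of per-exercise
#'   minimum scores.
#' @return an `adherence_config` list.
#' @export
adherence_config <- function(decrease_threshold = 0.10,
                             session_duration_limit = 90,
                             absence_limit = 72,
                             orange_escalation_count = 3L,
                             email_window = 72,
                             email_cap_per_window = 1L,
                             default_predefined_level = 10,
                             predefined_levels = NULL) {
  vals <- c(decrease_threshold, session_duration_limit, absence_limit,
            orange_escalation_count, email_window, email_cap_per_window,
            default_predefined_level)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop("all adherence thresholds must be positive", call. = FALSE)
  }
  structure(list(decrease_threshold = decrease_threshold,
                 session_duration_limit = session_duration_limit,
                 absence_limit = absence_limit,
                 orange_escalation_count = as.integer(orange_escalation_count),
                 email_window = email_window,
                 email_cap_per_window = as.integer(email_cap_per_window),
                 default_predefined_level = default_predefined_level,
                 predefined_levels = predefined_levels),
            class = "adherence_config")
}

# minimum acceptable raw score for an exercise
predefined_level <- function(config, exercise_id) {
  lv <- config$predefined_levels
  if (!is.null(lv) && exercise_id %in% names(lv)) lv[[exercise_id]]
  else config$default_predefined_level
}

# flag records are plain data frames; this builds one row
new_flag <- function(participant_id, severity, cause, time,
                     exercise_id = NA_character_,
                     session_index = NA_integer_) {
  stopifnot(severity %in% c("red", "orange"),
            cause %in% c(.RED_CAUSES, .ORANGE_CAUSES))
  data.frame(time = as.POSIXct(time), participant_id = participant_id,
             severity = severity, cause = cause,
             exercise_id = exercise_id,
             session_index = as.integer(session_index),
             stringsAsFactors = FALSE)
}

#' An empty flag table
#'
#' @return zero-row data frame with the flag columns.
#' @export
empty_flags <- function() {
  data.frame(time = as.POSIXct(character(0), tz = "UTC"),
             participant_id = character(0), severity = character(0),
             cause = character(0), exercise_id = character(0),
             session_index = integer(0), stringsAsFactors = FALSE)
}

#' Performance (red) flags for one exercise result
#'
#' Evaluates the four poor-performance rules on a single attempt:
#' more incorrect than correct responses; zero correct answers; a raw score
#' below the exercise's predefined minimum level; and, given the previous
#' attempt of the same exercise in an earlier session, a decline of at least
#' `decrease_threshold` (10%) relative to that attempt. All resulting flags
#' are red. Evaluation is pure: the same inputs always yield the same flags.
#'
#' @param result a list or one-row data frame with fields `participant_id`,
#'   `exercise_id`, `session_index`, `time`, `n_correct`, `n_incorrect`,
#'   `raw_score`.
#' @param previous_attempt the previous attempt of the same exercise
#'   (same fields), or `NULL` if this is the first attempt.
#' @param config an [adherence_config()].
#' @return data frame of flags (possibly zero rows).
#' @export
evaluate_exercise_flags <- function(result, previous_attempt = NULL,
                                    config = adherence_config()) {
  r <- as.list(result)
  stopifnot(r$n_correct >= 0, r$n_incorrect >= 0)
  flags <- empty_flags()
  add <- function(cause) {
    rbind(flags, new_flag(r$participant_id, "red", cause, r$time,
                          exercise_id = r$exercise_id,
                          session_index = r$session_index))
  }
  if (r$n_incorrect > r$n_correct) flags <- add("more_incorrect_than_correct")
  if (r$n_correct == 0) flags <- add("zero_correct")
  if (r$raw_score < predefined_level(config, r$exercise_id)) {
    flags <- add("below_predefined_level")
  }
  if (!is.null(previous_attempt)) {
    prev <- as.list(previous_attempt)
    if (!identical(prev$exercise_id, r$exercise_id)) {
      stop("previous_attempt must be the same exercise (got ",
           sQuote(prev$exercise_id), " vs ", sQuote(r$exercise_id), ")",
           call. = FALSE)
    }
    if (r$raw_score <= (1 - config$decrease_threshold) * prev$raw_score) {
      flags <- add("decrease_in_performance")
    }
  }
  flags
}

#' Adherence (orange) flags for one session record
#'
#' A session strictly longer than the duration limit (90 minutes) yields a
#' `session_overlong` flag; a gap of at least the absence limit (72 hours)
#' since the previous session's end yields an `absence` flag. Both are
#' orange. The first session ever (no previous end) cannot produce an
#' absence flag.
#'
#' @param record list or one-row data frame with `participant_id`,
#'   `session_index`, `start`, `end` (`POSIXct`).
#' @param previous_session_end `POSIXct` end of the previous session, or
#'   `NULL`.
#' @param config an [adherence_config()].
#' @return data frame of flags (possibly zero rows).
#' @export
evaluate_session_flags <- function(record, previous_session_end = NULL,
                                   config = adherence_config()) {
  r <- as.list(record)
  if (as.numeric(r$end) < as.numeric(r$start)) {
    stop("malformed session record: end precedes start", call. = FALSE)
  }
  flags <- empty_flags()
  if (minutes_between(r$end, r$start) > config$session_duration_limit) {
    flags <- rbind(flags, new_flag(r$participant_id, "orange",
                                   "session_overlong", r$end,
                                   session_index = r$session_index))
  }
  if (!is.null(previous_session_end) &&
      hours_between(r$start, previous_session_end) >= config$absence_limit) {
    flags <- rbind(flags, new_flag(r$participant_id, "orange", "absence",
                                   r$start,
                                   session_index = r$session_index))
  }
  flags
}

#' Escalate accumulated orange flags to a red adherence flag
#'
#' When the count of orange flags since the last escalation reaches the
#' escalation threshold (3), one `adherence_escalation` red flag is due; the
#' counter then resets. This checks whether the history as given ends in a
#' state where an escalation is due.
#'
#' @param flag_history data frame of flags ordered by time (may already
#'   contain earlier `adherence_escalation` rows).
#' @param config an [adherence_config()].
#' @return a one-row flag data frame if an escalation is due, else `NULL`.
#' @export
escalate <- function(flag_history, config = adherence_config()) {
  esc <- which(flag_history$cause == "adherence_escalation")
  after <- if (length(esc)) flag_history[-seq_len(max(esc)), , drop = FALSE]
           else flag_history
  oranges <- after[after$severity == "orange", , drop = FALSE]
  if (nrow(oranges) >= config$orange_escalation_count) {
    last <- oranges[nrow(oranges), ]
    new_flag(last$participant_id, "red", "adherence_escalation", last$time)
  } else NULL
}

#' Interleave escalation flags into an orange-flag history
#'
#' Scans a time-ordered flag history and inserts an `adherence_escalation`
#' red flag each time the running orange count reaches the threshold,
#' resetting the counter after each escalation (so 6 oranges produce exactly
#' 2 escalations).
#'
#' @param flags data frame of flags ordered by time, without escalation rows.
#' @param config an [adherence_config()].
#' @return the flag history with escalation rows interleaved.
#' @export
apply_escalations <- function(flags, config = adherence_config()) {
  if (nrow(flags) == 0) return(flags)
  out <- empty_flags()
  count <- 0L
  for (i in seq_len(nrow(flags))) {
    row <- flags[i, , drop = FALSE]
    out <- rbind(out, row)
    if (row$severity == "orange") {
      count <- count + 1L
      if (count >= config$orange_escalation_count) {
        out <- rbind(out, new_flag(row$participant_id, "red",
                                   "adherence_escalation", row$time))
        count <- 0L
      }
    }
  }
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------- tickets

#' Open a trainer ticket
#'
#' Red flags always open a ticket; orange flags only notify (they open no
#' ticket until escalated to red). Participants can also open a ticket
#' themselves through the help button. Opening a ticket records a
#' trainer-alert event in the ticket's event log.
#'
#' @param participant_id participant the ticket concerns.
#' @param origin `"system_flag"` or `"user_help_request"`.
#' @param time opening time (`POSIXct`).
#' @param id ticket identifier.
#' @return a `ticket` with `status = "open"`, no owner, and its transition
#'   history/event log.
#' @export
open_ticket <- function(participant_id, origin = c("system_flag",
                                                   "user_help_request"),
                        time = Sys.time(), id = "ticket-1") {
  origin <- match.arg(origin)
  structure(list(id = id, participant_id = participant_id, origin = origin,
                 status = "open", owner = NA_character_,
                 history = data.frame(time = as.POSIXct(time),
                                      action = "open",
                                      trainer = NA_character_,
                                      status = "open",
                                      stringsAsFactors = FALSE),
                 events = data.frame(time = as.POSIXct(time),
                                     participant_id = participant_id,
                                     type = "trainer_alert",
                                     payload = paste0("ticket ", id,
                                                      " opened (", origin, ")"),
                                     stringsAsFactors = FALSE)),
            class = "ticket")
}

#' Tickets for a batch of flags
#'
#' @param flags data frame of flags; one ticket per red flag, none for
#'   orange flags.
#' @param time_prefix prefix for generated ticket ids.
#' @return list of `ticket`s.
#' @export
tickets_for_flags <- function(flags, time_prefix = "t") {
  reds <- flags[flags$severity == "red", , drop = FALSE]
  lapply(seq_len(nrow(reds)), function(i) {
    open_ticket(reds$participant_id[i], "system_flag", time = reds$time[i],
                id = paste0(time_prefix, "-", i))
  })
}

#' Advance a ticket through its lifecycle
#'
#' Valid transitions: open --assign--> assigned; assigned --assign/transfer-->
#' assigned (reassignment or shift handover; assigning the current owner is
#' an idempotent no-op); assigned --resolve--> resolved. Everything else —
#' resolving an unassigned ticket, any action on a resolved ticket,
#' transferring an open ticket — is an invalid transition. The full history
#' is retained on the ticket.
#'
#' @param ticket a `ticket`.
#' @param action `"assign"`, `"transfer"`, or `"resolve"`.
#' @param trainer trainer id (required for assign/transfer).
#' @param time transition time (`POSIXct`).
#' @return the updated `ticket`.
#' @export
transition_ticket <- function(ticket, action = c("assign", "transfer",
                                                 "resolve"),
                              trainer = NULL, time = Sys.time()) {
  stopifnot(inherits(ticket, "ticket"))
  action <- match.arg(action)
  invalid <- function() {
    stop("invalid ticket transition: ", action, " on a ", ticket$status,
         " ticket", call. = FALSE)
  }
  if (ticket$status == "resolved") invalid()
  if (action %in% c("assign", "transfer") && is.null(trainer)) {
    stop("'trainer' is required for ", action, call. = FALSE)
  }
  new_status <- switch(action,
    assign = {
      if (!ticket$status %in% c("open", "assigned")) invalid()
      "assigned"
    },
    transfer = {
      if (ticket$status != "assigned") invalid()
      "assigned"
    },
    resolve = {
      if (ticket$status != "assigned") invalid()
      "resolved"
    })
  if (action == "assign" && identical(ticket$owner, trainer)) {
    return(ticket) # idempotent re-assign to the current owner
  }
  ticket$status <- new_status
  if (action != "resolve") ticket$owner <- trainer
  ticket$history <- rbind(ticket$history,
                          data.frame(time = as.POSIXct(time), action = action,
                                     trainer = trainer %||% NA_character_,
                                     status = new_status,
                                     stringsAsFactors = FALSE))
  ticket
}

#' @export
print.ticket <- function(x, ...) {
  cat("ticket", x$id, "for", x$participant_id, "[", x$origin, "] status:",
      x$status, if (!is.na(x$owner)) paste0("(owner ", x$owner, ")"), "\n")
  invisible(x)
}

# ------------------------------------------------------------- throttling

#' Throttle automatic participant emails
#'
#' Automatic emails to a participant are capped at 1 per `email_window`
#' hours: a pending email is emitted only if no email was emitted to that
#' participant within the preceding window (an email exactly
#' `email_window` hours after the last one is allowed). Suppressed events
#' are retained and marked.
#'
#' @param events data frame of candidate automatic emails, time-ordered,
#'   with columns `time` (`POSIXct`) and `participant_id` (plus anything
#'   else, carried through).
#' @param config an [adherence_config()].
#' @return `events` with a logical `emitted` column.
#' @export
throttle_participant_emails <- function(events,
                                        config = adherence_config()) {
  if (nrow(events) == 0) {
    events$emitted <- logical(0)
    return(events)
  }
  if (is.unsorted(as.numeric(events$time))) {
    stop("'events' must be ordered by time", call. = FALSE)
  }
  events$emitted <- FALSE
  for (p in unique(events$participant_id)) {
    idx <- which(events$participant_id == p)
    last_emit <- -Inf
    for (i in idx) {
      t <- as.numeric(events$time[i])
      if ((t - last_emit) / 3600 >= config$email_window) {
        events$emitted[i] <- TRUE
        last_emit <- t
      }
    }
  }
  events
}

#' Maximum emails in any sliding window
#'
#' Counts, over all window placements, the maximum number of event times
#' falling in a half-open window `[t, t + window_hours)`.
#'
#' @param times `POSIXct` (or numeric seconds) event times.
#' @param window_hours window length in hours (default 72).
#' @return integer maximum count; 0 for no events.
#' @export
max_emails_in_window <- function(times, window_hours = 72) {
  t <- sort(as.numeric(times))
  if (length(t) == 0) return(0L)
  w <- window_hours * 3600
  max(vapply(t, function(s) sum(t >= s & t < s + w), integer(1)))
}

# ------------------------------------------------------------- CheerSquad

#' Create a participant's CheerSquad
#'
#' Up to five friends or family members who receive an invitation at
#' registration and automatic notifications at training milestones.
#'
#' @param participant_id participant identifier.
#' @param members character vector of member contacts (max 5).
#' @param time registration time (`POSIXct`).
#' @return a `cheersquad` with the invitation events attached.
#' @export
cheersquad <- function(participant_id, members = character(),
                       time = Sys.time()) {
  members <- as.character(members)
  if (length(members) > 5) {
    stop("a CheerSquad holds at most 5 members; got ", length(members),
         call. = FALSE)
  }
  invites <- if (length(members)) {
    data.frame(time = as.POSIXct(time), participant_id = participant_id,
               type = "cheersquad_invitation", member = members,
               stringsAsFactors = FALSE)
  } else {
    data.frame(time = as.POSIXct(character(0), tz = "UTC"),
               participant_id = character(0), type = character(0),
               member = character(0), stringsAsFactors = FALSE)
  }
  structure(list(participant_id = participant_id, members = members,
                 invitations = invites),
            class = "cheersquad")
}

#' Add a member to a CheerSquad
#'
#' @param squad a `cheersquad`.
#' @param member contact to add.
#' @param time invitation time.
#' @return the updated `cheersquad`; adding a 6th member is an error.
#' @export
add_member <- function(squad, member, time = Sys.time()) {
  stopifnot(inherits(squad, "cheersquad"))
  if (length(squad$members) >= 5) {
    stop("a CheerSquad holds at most 5 members", call. = FALSE)
  }
  squad$members <- c(squad$members, member)
  squad$invitations <- rbind(squad$invitations,
                             data.frame(time = as.POSIXct(time),
                                        participant_id = squad$participant_id,
                                        type = "cheersquad_invitation",
                                        member = member,
                                        stringsAsFactors = FALSE))
  squad
}

#' CheerSquad milestone notification events
#'
#' Emits one notification event per squad member for each milestone session
#' the participant has completed.
#'
#' @param state a `module_state` with completion timestamps.
#' @param squad a `cheersquad`.
#' @param milestones session indices counting as milestones
#'   (default 1, 10, 20, 30).
#' @return data frame of notification events (`time`, `participant_id`,
#'   `type`, `member`, `milestone`).
#' @export
milestone_events <- function(state, squad, milestones = c(1L, 10L, 20L, 30L)) {
  stopifnot(inherits(state, "module_state"), inherits(squad, "cheersquad"))
  done <- as.integer(names(state$completions))
  crossed <- sort(intersect(milestones, done))
  rows <- list()
  for (m in crossed) {
    for (mem in squad$members) {
      rows[[length(rows) + 1L]] <- data.frame(
        time = as.POSIXct(state$completions[[as.character(m)]],
                          origin = "1970-01-01", tz = "UTC"),
        participant_id = state$participant_id,
        type = "cheersquad_milestone", member = mem, milestone = m,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(time = as.POSIXct(character(0), tz = "UTC"),
                      participant_id = character(0), type = character(0),
                      member = character(0), milestone = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
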