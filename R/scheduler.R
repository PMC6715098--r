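# "Sandwich" session scheduling: 17-slot session plans interleaving easy,
# medium and hard exercises, the 30-session module schedule with profile
# refreshes, the no-skipping rule, and monthly boosters.

.N_SESSIONS <- 30L
.SLOTS_PER_SESSION <- 17L
.MODULE_DAYS <- 70L # 10 weeks
# Fixed positional difficulty pattern. Easy exercises open the session,
# reappear in the middle (slots 9-10) and close it (16-17); counts are
# 6 easy / 4 medium / 7 hard.
.SESSION_PATTERN <- c("easy", "easy", "medium", "medium", "medium",
                      "hard", "hard", "hard", "easy", "easy", "medium",
                      "hard", "hard", "hard", "hard", "easy", "easy")
.TIER_FOR_DIFFICULTY <- c(easy = "strength", medium = "mid",
                          hard = "weakness")

#' The positional difficulty pattern of a training session
#'
#' @return character vector of length 17 with values `"easy"`, `"medium"`,
#'   `"hard"`; 6/4/7 of each, easy at slots 1, 2, 9, 10, 16, 17.
#' @export
session_pattern <- function() .SESSION_PATTERN

# domains currently in a given tier under a profile
tier_domains <- function(profile, tier) {
  names(profile$tiers)[profile$tiers == tier]
}

#' Compose one "sandwich" session plan
#'
#' Fills the 17-slot positional pattern: each slot draws an exercise
#' pseudorandomly, without within-session repetition, from the exercises of
#' the domains in the tier matching the slot's difficulty (easy from
#' strength domains, medium from mid, hard from weakness). Deterministic
#' given `(profile, catalog, session_index, seed)`.
#'
#' @param profile the `cognitive_profile` in force for this session.
#' @param catalog an `exercise_catalog`.
#' @param session_index integer in 1..30.
#' @param seed optional integer root seed; the actual draw uses the
#'   substream `derive_seed(seed, "session", session_index)` so the same
#'   root seed gives a different (but reproducible) draw each session.
#' @return a `session_plan`: data frame with columns `slot`, `difficulty`,
#'   `exercise_id`, `domain`; attributes `session_index`, `profile_epoch`,
#'   `participant_id`.
#' @export
make_session_plan <- function(profile, catalog, session_index, seed = NULL) {
  stopifnot(inherits(profile, "cognitive_profile"),
            inherits(catalog, "exercise_catalog"))
  session_index <- as.integer(session_index)
  if (is.na(session_index) || session_index < 1L ||
      session_index > .N_SESSIONS) {
    stop("session_index must be an integer in 1..", .N_SESSIONS,
         call. = FALSE)
  }
  draw_seed <- if (is.null(seed)) NULL else
    derive_seed(seed, "session", session_index)
  picks <- with_seed(draw_seed, {
    out <- list()
    for (diff in c("easy", "medium", "hard")) {
      need <- sum(.SESSION_PATTERN == diff)
      pool <- exercises_in_domains(catalog,
                                   tier_domains(profile,
                                                .TIER_FOR_DIFFICULTY[[diff]]))
      if (nrow(pool) < need) {
        stop("cannot fill ", need, " ", diff, " slots: only ", nrow(pool),
             " eligible exercises in the ",
             .TIER_FOR_DIFFICULTY[[diff]], " tier", call. = FALSE)
      }
      out[[diff]] <- pool$id[sample.int(nrow(pool), need)]
    }
    out
  })
  ids <- character(.SLOTS_PER_SESSION)
  used <- c(easy = 0L, medium = 0L, hard = 0L)
  for (s in seq_len(.SLOTS_PER_SESSION)) {
    diff <- .SESSION_PATTERN[s]
    used[diff] <- used[diff] + 1L
    ids[s] <- picks[[diff]][used[diff]]
  }
  plan <- data.frame(slot = seq_len(.SLOTS_PER_SESSION),
                     difficulty = .SESSION_PATTERN,
                     exercise_id = ids,
                     domain = exercise_domain(catalog, ids),
                     stringsAsFactors = FALSE)
  structure(plan, session_index = session_index,
            profile_epoch = profile$epoch,
            participant_id = profile$participant_id,
            class = c("session_plan", "data.frame"))
}

#' @export
print.session_plan <- function(x, ...) {
  cat("session_plan: session", attr(x, "session_index"),
      "for", attr(x, "participant_id"),
      "(profile epoch", paste0(attr(x, "profile_epoch"), ")\n"))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# profile epoch in force at a given session index
epoch_for_session <- function(session_index) {
  if (session_index <= 12L) "baseline"
  else if (session_index <= 18L) "refresh-13"
  else if (session_index <= 24L) "refresh-19"
  else "refresh-25"
}

#' Build the full 30-session module schedule
#'
#' Sessions 1-12 use the baseline profile; sessions 13-18, 19-24 and 25-30
#' use the profile refreshed at the start of their range. A full module
#' contains 30 x 17 = 510 exercise slots.
#'
#' @param profiles named list of `cognitive_profile`s by epoch
#'   (`"baseline"`, `"refresh-13"`, `"refresh-19"`, `"refresh-25"`). Only
#'   the epochs needed for `sessions` must be present.
#' @param catalog an `exercise_catalog`.
#' @param seed optional integer root seed (see [make_session_plan()]).
#' @param sessions which session indices to generate (default all 30).
#' @return a `module_schedule`: list of `session_plan`s named by index.
#' @export
build_module_schedule <- function(profiles, catalog, seed = NULL,
                                  sessions = seq_len(.N_SESSIONS)) {
  stopifnot(is.list(profiles))
  if (inherits(profiles, "cognitive_profile")) {
    profiles <- stats::setNames(list(profiles), profiles$epoch)
  }
  sessions <- as.integer(sessions)
  need <- unique(vapply(sessions, epoch_for_session, character(1)))
  missing <- setdiff(need, names(profiles))
  if (length(missing)) {
    stop("no profile supplied for epoch(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  plans <- lapply(sessions, function(i) {
    make_session_plan(profiles[[epoch_for_session(i)]], catalog, i,
                      seed = seed)
  })
  structure(stats::setNames(plans, sessions), class = "module_schedule")
}

#' Flatten a schedule to one row per exercise slot
#'
#' @param schedule a `module_schedule`.
#' @return data frame with columns `session_index`, `slot`, `difficulty`,
#'   `exercise_id`, `domain`, `profile_epoch`.
#' @export
schedule_to_df <- function(schedule) {
  stopifnot(inherits(schedule, "module_schedule"))
  do.call(rbind, lapply(schedule, function(p) {
    cbind(session_index = attr(p, "session_index"), as.data.frame(p),
          profile_epoch = attr(p, "profile_epoch"))
  })) -> out
  rownames(out) <- NULL
  out
}

#' Create the training state for a participant's module
#'
#' Tracks session completions for the no-skipping rule: sessions complete in
#' strictly increasing order and at most one session is open at a time.
#'
#' @param participant_id participant identifier.
#' @param start module start time (`POSIXct`).
#' @param seed integer root seed used for this participant's session draws.
#' @return a `module_state`.
#' @export
new_module_state <- function(participant_id, start, seed = NULL) {
  stopifnot(inherits(start, "POSIXct"))
  structure(list(participant_id = participant_id, start = start,
                 completions = stats::setNames(numeric(0), character(0)),
                 seed = seed),
            class = "module_state")
}

#' Record the completion of the currently open session
#'
#' @param state a `module_state`.
#' @param session_index must be the lowest uncompleted index (sessions
#'   cannot be skipped).
#' @param timestamp completion time (`POSIXct`), not before the previous
#'   completion.
#' @return the updated `module_state`.
#' @export
complete_session <- function(state, session_index, timestamp) {
  stopifnot(inherits(state, "module_state"), inherits(timestamp, "POSIXct"))
  expected <- length(state$completions) + 1L
  if (session_index != expected) {
    stop("sessions cannot be skipped: next completable session is ",
         expected, ", got ", session_index, call. = FALSE)
  }
  if (expected > .N_SESSIONS) stop("module already complete", call. = FALSE)
  if (length(state$completions) &&
      as.numeric(timestamp) < max(state$completions)) {
    stop("completion timestamps must be non-decreasing", call. = FALSE)
  }
  state$completions[as.character(session_index)] <- as.numeric(timestamp)
  state
}

#' Next available session under the no-skipping rule
#'
#' Returns the lowest-index uncompleted session's plan while the module
#' window (70 days from start) is open; an uncompleted session stays
#' allocated until completed or the window closes, whichever is sooner.
#'
#' @param state a `module_state`.
#' @param profiles named list of profiles by epoch (as in
#'   [build_module_schedule()]).
#' @param catalog an `exercise_catalog`.
#' @param now current time (`POSIXct`), at or after the module start.
#' @return a `session_plan`, or a `session_status` list with
#'   `status = "module_ended"` (window closed) or `"module_complete"`
#'   (all 30 sessions done).
#' @export
next_session <- function(state, profiles, catalog, now) {
  stopifnot(inherits(state, "module_state"), inherits(now, "POSIXct"))
  if (now < state$start) stop("'now' precedes the module start", call. = FALSE)
  if (hours_between(now, state$start) > .MODULE_DAYS * 24) {
    return(structure(list(status = "module_ended",
                          completed = length(state$completions)),
                     class = "session_status"))
  }
  idx <- length(state$completions) + 1L
  if (idx > .N_SESSIONS) {
    return(structure(list(status = "module_complete",
                          completed = .N_SESSIONS),
                     class = "session_status"))
  }
  make_session_plan(profiles[[epoch_for_session(idx)]], catalog, idx,
                    seed = state$seed)
}

#' Monthly booster session dates after the module
#'
#' One booster per calendar month from the end of the 10-week module out to
#' the follow-up horizon (at most 3 years).
#'
#' @param module_end `Date` or `POSIXct` end of the module.
#' @param horizon_months integer number of months, 0..36.
#' @return vector of `horizon_months` booster dates.
#' @export
schedule_boosters <- function(module_end, horizon_months) {
  horizon_months <- as.integer(horizon_months)
  if (is.na(horizon_months) || horizon_months < 0 || horizon_months > 36) {
    stop("horizon_months must be between 0 and 36 (3-year follow-up)",
         call. = FALSE)
  }
  if (horizon_months == 0) return(module_end[0])
  seq(module_end, by = "month", length.out = horizon_months + 1L)[-1L]
}
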