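# Engine configuration and versioned state persistence (JSON, ISO 8601 UTC
# timestamps).

.STATE_VERSION <- 1L

#' Engine configuration and its default constants
#'
#' Collects every structural constant of the delivery engine in one place:
#' 30 sessions of 17 exercises (510 slots), the 6/4/7 easy/medium/hard
#' split and its positional pattern, 2/2/3 strength/mid/weakness tiers,
#' profile refreshes at sessions 13/19/25, the 70-day (10-week) module
#' window, the adherence thresholds, the CheerSquad cap of 5, and the
#' default milestone set.
#'
#' @param adherence an [adherence_config()].
#' @param seed default root seed.
#' @return an `engine_config` list.
#' @export
engine_config <- function(adherence = adherence_config(), seed = 1L) {
  structure(list(n_sessions = .N_SESSIONS,
                 slots_per_session = .SLOTS_PER_SESSION,
                 difficulty_counts = c(easy = 6L, medium = 4L, hard = 7L),
                 session_pattern = .SESSION_PATTERN,
                 tier_sizes = c(strength = 2L, mid = 2L, weakness = 3L),
                 refresh_points = .REFRESH_POINTS,
                 module_days = .MODULE_DAYS,
                 adherence = adherence,
                 squad_max = 5L,
                 milestones = c(1L, 10L, 20L, 30L),
                 seed = as.integer(seed)),
            class = "engine_config")
}

iso_ts <- function(t) format(as.POSIXct(t, tz = "UTC"),
                             "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC")
parse_ts <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OSZ",
                                   tz = "UTC")

#' Save engine state to a versioned JSON file
#'
#' Serializes a participant's module state and profiles (plus the RNG root
#' seed, so subsequent session plans continue identically after a reload).
#' Timestamps are stored as ISO 8601 UTC.
#'
#' @param state list with a `module_state` element and optionally a
#'   `profiles` list by epoch (a bare `module_state` is also accepted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_state <- function(state, path) {
  if (inherits(state, "module_state")) state <- list(module_state = state)
  ms <- state$module_state
  stopifnot(inherits(ms, "module_state"))
  payload <- list(
    version = .STATE_VERSION,
    module_state = list(
      participant_id = ms$participant_id,
      start = iso_ts(ms$start),
      completions = as.list(stats::setNames(
        vapply(ms$completions, function(x)
          iso_ts(as.POSIXct(x, origin = "1970-01-01", tz = "UTC")),
          character(1)),
        names(ms$completions))),
      seed = ms$seed),
    profiles = lapply(state$profiles %||% list(), profile_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load engine state from a JSON file
#'
#' @param path file written by [save_state()].
#' @return list with `module_state` and `profiles`.
#' @export
load_state <- function(path) {
  if (!file.exists(path)) stop("state file not found: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) {
                        stop("cannot parse state file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
  if (is.null(payload$version) || payload$version != .STATE_VERSION) {
    stop("state file version ", payload$version %||% "<missing>",
         " does not match supported version ", .STATE_VERSION,
         "; migration required", call. = FALSE)
  }
  msl <- payload$module_state
  ms <- new_module_state(msl$participant_id, parse_ts(msl$start),
                         seed = if (!is.null(msl$seed)) as.integer(msl$seed))
  comp <- vapply(msl$completions, function(s) as.numeric(parse_ts(s)),
                 numeric(1))
  ms$completions <- stats::setNames(as.numeric(comp), names(msl$completions))
  list(module_state = ms,
       profiles = lapply(payload$profiles, profile_from_list))
}
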