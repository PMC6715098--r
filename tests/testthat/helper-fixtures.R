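# Shared fixtures: the packaged catalog, timestamp shorthand, and profile /
# result builders.

CATALOG <- load_catalog()
DOMAINS <- cognitive_domains()

# POSIXct h hours after a fixed UTC origin
ts_h <- function(h) as.POSIXct("2026-01-01 00:00:00", tz = "UTC") + h * 3600

# profile from a z vector given in canonical domain order
profile_from_z <- function(z, id = "p1", epoch = "baseline") {
  new_cognitive_profile(id, stats::setNames(z, DOMAINS), epoch = epoch)
}

# a single exercise result with overridable fields
mk_result <- function(exercise_id = "verbal_learning", n_correct = 10,
                      n_incorrect = 2, raw_score = 60, session_index = 1,
                      time = ts_h(0), participant_id = "p1",
                      duration = 120) {
  list(participant_id = participant_id, exercise_id = exercise_id,
       session_index = session_index, time = time, n_correct = n_correct,
       n_incorrect = n_incorrect, raw_score = raw_score,
       duration = duration)
}

# a session record
mk_record <- function(session_index = 1, start = ts_h(0),
                      end = start + 45 * 60, participant_id = "p1") {
  list(participant_id = participant_id, session_index = session_index,
       start = start, end = end)
}

# reduced catalog whose tier pools exactly match the 6/4/7 slot counts when
# the profile ranks domains canonically: strength 3+3, mid 2+2,
# weakness 3+2+2
toy_catalog <- function() {
  mk <- function(domain, k) {
    data.frame(id = paste0(tolower(domain), "_", seq_len(k)),
               name = paste(domain, seq_len(k)), domain = domain,
               stringsAsFactors = FALSE)
  }
  ex <- rbind(mk("VerbalMemory", 3), mk("VisualAttention", 3),
              mk("VisualMemory", 2), mk("VerbalExecutive", 2),
              mk("VisualExecutive", 3), mk("WorkingMemory", 2),
              mk("ProcessingSpeed", 2))
  assess <- data.frame(id = paste0("a_", seq_along(DOMAINS)),
                       domain = DOMAINS,
                       source_name = paste("test", DOMAINS),
                       stringsAsFactors = FALSE)
  new_exercise_catalog(ex, assess)
}
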