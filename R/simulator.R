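# Virtual-participant simulator: normative cohorts, noisy practice-driven
# attempt generation, and end-to-end simulated training modules driving the
# profiling, scheduling, scoring and adherence machinery.

# latent z-scale <-> bounded native score scale (0-100, centered at 50,
# 15 points per population SD)
.SCORE_CENTER <- 50
.SCORE_SCALE <- 15
.N_TRIALS <- 20L # responses per exercise attempt
# baseline log-odds of a correct response for a participant of average
# ability: exercises are tuned so the average trainee answers ~82% of
# trials correctly, and the correct fraction falls with latent performance
.CORRECT_LOGIT_OFFSET <- 1.5

native_score <- function(z) pmin(100, pmax(0, .SCORE_CENTER + .SCORE_SCALE * z))

#' Define a virtual participant
#'
#' A virtual participant couples latent per-domain ability (population
#' standardized units) with behavioral traits: practice-driven learning,
#' attempt-level noise, session cadence, and the propensities to run
#' overlong sessions or lapse for 72+ hours.
#'
#' @param id participant identifier.
#' @param latent_ability named numeric vector over the 7 domains, or a
#'   scalar recycled to all domains (population SD units).
#' @param learning_rate gain in latent performance per repeated attempt of
#'   an exercise (scalar or named per-domain vector; default 0.02 SD).
#' @param noise_sd attempt-level performance noise SD (> 0; default 0.5,
#'   consistent with test-retest reliability around 0.8).
#' @param cadence_mean,cadence_sd inter-session gap model, hours (defaults
#'   56 and 8: three sessions per week).
#' @param overlong_prob probability a session exceeds the 90-minute limit.
#' @param lapse_prob probability of a >= 72-hour gap before a session.
#' @param seed integer root seed for this participant's streams.
#' @return a `virtual_participant`.
#' @export
virtual_participant <- function(id, latent_ability = 0, learning_rate = 0.02,
                                noise_sd = 0.5, cadence_mean = 56,
                                cadence_sd = 8, overlong_prob = 0.02,
                                lapse_prob = 0.05, seed = 1L) {
  if (length(latent_ability) == 1 && is.null(names(latent_ability))) {
    latent_ability <- stats::setNames(rep(latent_ability, 7), .DOMAINS)
  }
  if (!all(.DOMAINS %in% names(latent_ability))) {
    stop("latent_ability must name all 7 domains", call. = FALSE)
  }
  if (length(learning_rate) == 1 && is.null(names(learning_rate))) {
    learning_rate <- stats::setNames(rep(learning_rate, 7), .DOMAINS)
  }
  stopifnot(noise_sd > 0,
            overlong_prob >= 0, overlong_prob <= 1,
            lapse_prob >= 0, lapse_prob <= 1)
  structure(list(id = id,
                 latent_ability = latent_ability[.DOMAINS],
                 learning_rate = learning_rate[.DOMAINS],
                 noise_sd = noise_sd, cadence_mean = cadence_mean,
                 cadence_sd = cadence_sd, overlong_prob = overlong_prob,
                 lapse_prob = lapse_prob, seed = as.integer(seed)),
            class = "virtual_participant")
}

#' Simulate a normative cohort
#'
#' Draws `n` reference participants with latent per-domain abilities
#' `N(0, ability_sd)`, simulates their baseline assessment scores and one
#' attempt per training exercise (latent ability plus noise, mapped to the
#' 0-100 native scale), and summarizes them as the normative reference for
#' intake standardization plus per-exercise cohort score distributions. The
#' default size mirrors a pilot cohort of 100.
#'
#' @param catalog an `exercise_catalog`.
#' @param n cohort size (>= 2; default 100).
#' @param seed integer seed; the result is a pure function of
#'   `(parameters, seed)`.
#' @param ability_sd between-subject SD of latent ability (default 1).
#' @param test_noise_sd assessment measurement noise SD (default 0.5).
#' @param attempt_noise_sd exercise attempt noise SD (default 0.5).
#' @return a `normative_cohort`: list with `norms` (a
#'   [normative_reference()]), `exercise_ref` (a [cohort_reference()]),
#'   `n`, and `seed`.
#' @export
generate_normative_cohort <- function(catalog, n = 100L, seed = 1L,
                                      ability_sd = 1, test_noise_sd = 0.5,
                                      attempt_noise_sd = 0.5) {
  stopifnot(inherits(catalog, "exercise_catalog"))
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("cohort size n must be at least 2",
                              call. = FALSE)
  with_seed(derive_seed(seed, "normative-cohort"), {
    ability <- matrix(stats::rnorm(n * 7, 0, ability_sd), nrow = n,
                      dimnames = list(NULL, .DOMAINS))
    a <- catalog$assessments
    test_scores <- sapply(seq_len(nrow(a)), function(j) {
      native_score(ability[, a$domain[j]] +
                     stats::rnorm(n, 0, test_noise_sd))
    })
    norms <- normative_reference(a$id,
                                 mean = apply(test_scores, 2, mean),
                                 sd = apply(test_scores, 2, stats::sd),
                                 provenance = sprintf(
                                   "pilot-simulated, seed %s, n=%d", seed, n))
    e <- catalog$exercises
    ex_scores <- sapply(seq_len(nrow(e)), function(j) {
      native_score(ability[, e$domain[j]] +
                     stats::rnorm(n, 0, attempt_noise_sd))
    })
    exercise_ref <- cohort_reference(e$id,
                                     mean = apply(ex_scores, 2, mean),
                                     sd = apply(ex_scores, 2, stats::sd))
    structure(list(norms = norms, exercise_ref = exercise_ref, n = n,
                   seed = seed),
              class = "normative_cohort")
  })
}

#' Simulate one exercise attempt
#'
#' Latent performance is `ability + learning_rate * (attempt_number - 1) +
#' noise`, mapped to the bounded 0-100 native scale. Correct/incorrect
#' counts are drawn consistently with latent performance (20 trials with
#' success probability `plogis(1.5 + latent)`, so an average participant
#' answers ~82% of trials correctly and the correct fraction rises with the
#' score), and duration comes from a simple per-exercise timing model
#' (mean 150 s).
#'
#' @param p a [virtual_participant()].
#' @param exercise exercise id.
#' @param attempt_number 1 for the first attempt of this exercise, etc.
#' @param catalog an `exercise_catalog`.
#' @param participant_id,session_index,time metadata stamped onto the
#'   result.
#' @return one-row data frame: an exercise result (`participant_id`,
#'   `exercise_id`, `session_index`, `time`, `n_correct`, `n_incorrect`,
#'   `raw_score`, `duration`).
#' @export
simulate_attempt <- function(p, exercise, attempt_number, catalog,
                             session_index = NA_integer_,
                             time = Sys.time()) {
  stopifnot(inherits(p, "virtual_participant"), attempt_number >= 1)
  dom <- exercise_domain(catalog, exercise)
  latent <- p$latent_ability[[dom]] +
    p$learning_rate[[dom]] * (attempt_number - 1) +
    stats::rnorm(1, 0, p$noise_sd)
  raw <- native_score(latent)
  n_correct <- stats::rbinom(1, .N_TRIALS,
                             stats::plogis(.CORRECT_LOGIT_OFFSET + latent))
  duration <- max(30, stats::rnorm(1, 150, 30))
  data.frame(participant_id = p$id, exercise_id = exercise,
             session_index = as.integer(session_index),
             time = as.POSIXct(time),
             n_correct = n_correct,
             n_incorrect = .N_TRIALS - n_correct,
             raw_score = raw, duration = duration,
             stringsAsFactors = FALSE)
}

#' Simulate a complete 30-session training module
#'
#' Runs the full pipeline for one virtual participant: simulated intake
#' tests feed the baseline profile; sessions are planned with the sandwich
#' scheduler and played out attempt by attempt with simulated gaps,
#' durations and lapses; the profile refreshes at sessions 13, 19, 25 from
#' the participant's own results against the cohort reference; every result
#' and session passes through the flag rules, escalation, ticketing and the
#' email throttle. Byte-identical logs result from identical
#' `(parameters, seed)`.
#'
#' @param p a [virtual_participant()].
#' @param catalog an `exercise_catalog`.
#' @param cohort a `normative_cohort` from [generate_normative_cohort()].
#' @param config an [adherence_config()].
#' @param start module start time (`POSIXct`).
#' @param n_sessions number of sessions to simulate (default 30).
#' @return a `simulation_log`: list with `participant_id`, `profiles` (by
#'   epoch), `results`, `records`, `flags`, `tickets`, `emails`, `state`,
#'   and `seed`.
#' @export
simulate_module <- function(p, catalog, cohort,
                            config = adherence_config(),
                            start = as.POSIXct("2026-01-05 09:00:00",
                                               tz = "UTC"),
                            n_sessions = 30L) {
  stopifnot(inherits(p, "virtual_participant"),
            inherits(cohort, "normative_cohort"))
  n_sessions <- as.integer(n_sessions)

  # intake: simulated baseline tests -> baseline profile
  a <- catalog$assessments
  test_scores <- with_seed(derive_seed(p$seed, "intake"), {
    stats::setNames(native_score(p$latent_ability[a$domain] +
                                   stats::rnorm(nrow(a), 0, p$noise_sd)),
                    a$id)
  })
  profile <- build_baseline_profile(test_scores, cohort$norms, catalog, p$id)
  profiles <- list(baseline = profile)

  state <- new_module_state(p$id, start, seed = p$seed)
  results <- list()
  records <- list()
  raw_flags <- empty_flags()
  attempt_count <- stats::setNames(integer(nrow(catalog$exercises)),
                                   catalog$exercises$id)
  last_attempt <- list() # exercise_id -> last result row
  prev_end <- NULL
  now <- start

  for (i in seq_len(n_sessions)) {
    sess <- with_seed(derive_seed(p$seed, "session-events", i), {
      gap <- if (i == 1) 0 else if (stats::runif(1) < p$lapse_prob) {
        config$absence_limit + stats::rexp(1, 1 / 24)
      } else {
        # compliant gaps stay below the absence limit
        min(config$absence_limit - 1,
            max(8, stats::rnorm(1, p$cadence_mean, p$cadence_sd)))
      }
      overlong <- stats::runif(1) < p$overlong_prob
      list(gap = gap, overlong = overlong)
    })
    now <- now + sess$gap * 3600

    if (i %in% .REFRESH_POINTS) {
      own <- do.call(rbind, results)
      profile <- refresh_profile(profile, own, cohort$exercise_ref, i,
                                 catalog)
      profiles[[profile$epoch]] <- profile
    }

    plan <- make_session_plan(profile, catalog, i, seed = p$seed)
    sess_results <- with_seed(derive_seed(p$seed, "attempts", i), {
      t <- now
      rows <- lapply(seq_len(nrow(plan)), function(s) {
        ex <- plan$exercise_id[s]
        attempt_count[ex] <<- attempt_count[ex] + 1L
        r <- simulate_attempt(p, ex, attempt_count[ex], catalog,
                              session_index = i, time = t)
        t <<- t + r$duration
        r
      })
      do.call(rbind, rows)
    })
    end <- if (sess$overlong) {
      now + (config$session_duration_limit + 1 +
               with_seed(derive_seed(p$seed, "overlong", i),
                         stats::rexp(1, 1 / 10))) * 60
    } else {
      now + sum(sess_results$duration)
    }
    record <- data.frame(participant_id = p$id, session_index = i,
                         start = now, end = end, stringsAsFactors = FALSE)

    # flag evaluation: per-exercise rules against the previous attempt of
    # the same exercise, then session-level adherence rules
    for (s in seq_len(nrow(sess_results))) {
      r <- sess_results[s, , drop = FALSE]
      prev <- last_attempt[[r$exercise_id]]
      raw_flags <- rbind(raw_flags,
                         evaluate_exercise_flags(r, prev, config))
      last_attempt[[r$exercise_id]] <- r
    }
    raw_flags <- rbind(raw_flags,
                       evaluate_session_flags(record, prev_end, config))

    results[[i]] <- sess_results
    records[[i]] <- record
    state <- complete_session(state, i, end)
    prev_end <- end
    now <- end
  }

  raw_flags <- raw_flags[order(as.numeric(raw_flags$time)), , drop = FALSE]
  rownames(raw_flags) <- NULL
  flags <- apply_escalations(raw_flags, config)
  tickets <- tickets_for_flags(flags, time_prefix = paste0(p$id, "-ticket"))
  reds <- flags[flags$severity == "red", , drop = FALSE]
  emails <- throttle_participant_emails(
    data.frame(time = reds$time, participant_id = reds$participant_id,
               reason = reds$cause, stringsAsFactors = FALSE),
    config)

  structure(list(participant_id = p$id, profiles = profiles,
                 results = do.call(rbind, results),
                 records = do.call(rbind, records),
                 flags = flags, tickets = tickets, emails = emails,
                 state = state, seed = p$seed),
            class = "simulation_log")
}

#' @export
print.simulation_log <- function(x, ...) {
  cat("simulation_log for", x$participant_id, "\n")
  cat("  sessions:", nrow(x$records), " attempts:", nrow(x$results), "\n")
  cat("  flags:", nrow(x$flags),
      sprintf("(%d red, %d orange)", sum(x$flags$severity == "red"),
              sum(x$flags$severity == "orange")), "\n")
  cat("  tickets:", length(x$tickets), " emails emitted:",
      sum(x$emails$emitted), "\n")
  invisible(x)
}

#' Simulate a cohort's domain scores and feedback-zone membership
#'
#' Draws `n` participants with latent abilities `N(0, ability_sd)`, one
#' noisy attempt per exercise each, standardizes against the same cohort's
#' per-exercise distributions, aggregates to domain scores, and computes the
#' top-25% target zone per domain. Used to verify that roughly a quarter of
#' the cohort lands in the zone.
#'
#' @param catalog an `exercise_catalog`.
#' @param n cohort size.
#' @param seed integer seed.
#' @param ability_sd,noise_sd generative parameters (defaults 1, 0.5).
#' @return list with `domain_scores` (n x 7 matrix), `zone_bounds` (named
#'   vector, 75th percentiles), and `in_zone_fraction` (named vector per
#'   domain).
#' @export
simulate_feedback_cohort <- function(catalog, n = 1000L, seed = 1L,
                                     ability_sd = 1, noise_sd = 0.5) {
  stopifnot(inherits(catalog, "exercise_catalog"))
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("cohort size n must be at least 2",
                              call. = FALSE)
  with_seed(derive_seed(seed, "feedback-cohort"), {
    ability <- matrix(stats::rnorm(n * 7, 0, ability_sd), nrow = n,
                      dimnames = list(NULL, .DOMAINS))
    e <- catalog$exercises
    scores <- sapply(seq_len(nrow(e)), function(j) {
      native_score(ability[, e$domain[j]] + stats::rnorm(n, 0, noise_sd))
    })
    z <- scale(scores) # per-exercise cohort standardization
    dscore <- sapply(.DOMAINS, function(d) {
      rowMeans(z[, e$domain == d, drop = FALSE])
    })
    bounds <- apply(dscore, 2, zone_bound)
    frac <- vapply(.DOMAINS, function(d) mean(dscore[, d] >= bounds[[d]]),
                   numeric(1))
    list(domain_scores = dscore, zone_bounds = bounds,
         in_zone_fraction = frac)
  })
}
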