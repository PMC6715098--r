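cfg <- adherence_config()

test_that("performance rules flag exactly the stated situations", {
  # more incorrect than correct responses
  f <- evaluate_exercise_flags(mk_result(n_correct = 3, n_incorrect = 5))
  expect_identical(f$cause, "more_incorrect_than_correct")
  expect_identical(f$severity, "red")
  # zero correct answers (also has more incorrect than correct here)
  f <- evaluate_exercise_flags(mk_result(n_correct = 0, n_incorrect = 8))
  expect_setequal(f$cause, c("more_incorrect_than_correct", "zero_correct"))
  # score below the predefined level (default 10 on the 0-100 scale)
  f <- evaluate_exercise_flags(mk_result(raw_score = 9))
  expect_true("below_predefined_level" %in% f$cause)
  expect_length(evaluate_exercise_flags(mk_result(raw_score = 10))$cause, 0)
  # per-exercise override of the level
  cfg2 <- adherence_config(predefined_levels = c(verbal_learning = 70))
  f <- evaluate_exercise_flags(mk_result(raw_score = 60), config = cfg2)
  expect_identical(f$cause, "below_predefined_level")
  # clean pass: no flags at all
  f <- evaluate_exercise_flags(mk_result(n_correct = 10, n_incorrect = 0,
                                         raw_score = 80))
  expect_identical(nrow(f), 0L)
})

test_that("the decrease flag triggers at exactly a 10% decline", {
  prev <- mk_result(raw_score = 100, session_index = 1)
  at <- function(score) evaluate_exercise_flags(
    mk_result(raw_score = score, n_correct = 10, n_incorrect = 0,
              session_index = 2), previous_attempt = prev)
  expect_identical(at(90)$cause, "decrease_in_performance") # exactly 10%
  expect_identical(nrow(at(91)), 0L)
  expect_identical(nrow(at(90.0001)), 0L)
  expect_identical(at(89)$cause, "decrease_in_performance")
  # bisection pins the boundary at 90% of the previous score
  lo <- 60; hi <- 100
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (nrow(at(mid)) > 0) lo <- mid else hi <- mid
  }
  expect_equal(lo, 90, tolerance = 1e-9)
  # comparing against a different exercise is a usage error
  expect_error(evaluate_exercise_flags(
    mk_result(exercise_id = "memo_pair"), previous_attempt = prev),
    "same exercise")
})

test_that("flag evaluation is pure with no duplicate causes", {
  r <- mk_result(n_correct = 0, n_incorrect = 9, raw_score = 2)
  f1 <- evaluate_exercise_flags(r)
  expect_identical(f1, evaluate_exercise_flags(r))
  expect_identical(anyDuplicated(f1$cause), 0L)
  expect_true(all(f1$severity == "red"))
})

test_that("adherence rules flag overlong sessions and 72-hour absences", {
  # strictly longer than 90 minutes
  f <- evaluate_session_flags(mk_record(end = ts_h(0) + 91 * 60))
  expect_identical(f$cause, "session_overlong")
  expect_identical(f$severity, "orange")
  expect_identical(nrow(evaluate_session_flags(
    mk_record(end = ts_h(0) + 90 * 60))), 0L)
  # absent for 72 hours or more between sessions (inclusive boundary)
  f <- evaluate_session_flags(mk_record(start = ts_h(72)),
                              previous_session_end = ts_h(0))
  expect_identical(f$cause, "absence")
  expect_identical(nrow(evaluate_session_flags(
    mk_record(start = ts_h(71)), previous_session_end = ts_h(0))), 0L)
  # the first session ever has no defined gap
  expect_identical(nrow(evaluate_session_flags(mk_record())), 0L)
  expect_error(evaluate_session_flags(
    mk_record(start = ts_h(2), end = ts_h(1))), "malformed")
})

orange_at <- function(h) evaluate_session_flags(
  mk_record(start = ts_h(h), session_index = NA),
  previous_session_end = ts_h(h - 100))

test_that("three orange flags escalate to one adherence red flag", {
  hist2 <- rbind(orange_at(100), orange_at(200))
  expect_null(escalate(hist2))
  hist3 <- rbind(hist2, orange_at(300))
  esc <- escalate(hist3)
  expect_identical(esc$cause, "adherence_escalation")
  expect_identical(esc$severity, "red")
  # after an escalation the counter resets
  expect_null(escalate(rbind(hist3, esc)))
  # counting oracle: k oranges yield floor(k/3) escalations
  for (k in 0:10) {
    hist <- do.call(rbind, c(list(empty_flags()),
                             lapply(seq_len(k) * 100, orange_at)))
    out <- apply_escalations(hist, cfg)
    expect_identical(sum(out$cause == "adherence_escalation"),
                     as.integer(floor(k / 3)),
                     label = sprintf("%d oranges", k))
  }
})

test_that("red flags open tickets; orange flags do not", {
  red <- evaluate_exercise_flags(mk_result(n_correct = 2, n_incorrect = 9))
  orange <- orange_at(50)
  tk <- tickets_for_flags(rbind(red, orange))
  expect_length(tk, 1L)
  expect_identical(tk[[1]]$origin, "system_flag")
  expect_identical(tk[[1]]$status, "open")
  expect_identical(tk[[1]]$events$type, "trainer_alert")
  help <- open_ticket("p1", "user_help_request", time = ts_h(1))
  expect_identical(help$origin, "user_help_request")
})

test_that("the ticket lifecycle permits only open -> assigned -> resolved", {
  t0 <- open_ticket("p1", "system_flag", time = ts_h(0), id = "T")
  t1 <- transition_ticket(t0, "assign", "trainer_a", ts_h(1))
  expect_identical(t1$status, "assigned")
  expect_identical(t1$owner, "trainer_a")
  # handover to the next scheduled trainer
  t2 <- transition_ticket(t1, "transfer", "trainer_b", ts_h(2))
  expect_identical(t2$owner, "trainer_b")
  t3 <- transition_ticket(t2, "resolve", time = ts_h(3))
  expect_identical(t3$status, "resolved")
  expect_identical(nrow(t3$history), 4L)
  # guarded transitions
  expect_error(transition_ticket(t0, "resolve"), "invalid ticket transition")
  expect_error(transition_ticket(t0, "transfer", "trainer_a"),
               "invalid ticket transition")
  expect_error(transition_ticket(t3, "assign", "trainer_a"),
               "invalid ticket transition")
  # re-assigning the current owner is an idempotent no-op
  expect_identical(transition_ticket(t1, "assign", "trainer_a"), t1)
})

test_that("no action sequence reaches an undefined ticket state", {
  actions <- list(c("assign", "t1"), c("assign", "t2"),
                  c("transfer", "t1"), c("transfer", "t2"),
                  c("resolve", NA))
  seqs <- list(integer(0))
  for (depth in 1:4) {
    seqs <- c(seqs, unlist(lapply(seqs[lengths(seqs) == depth - 1],
                                  function(s) lapply(1:5, function(a) c(s, a))),
                           recursive = FALSE))
  }
  for (s in seqs) {
    tk <- open_ticket("p1", "system_flag", time = ts_h(0))
    ok <- TRUE
    for (a in s) {
      act <- actions[[a]]
      tk <- tryCatch(
        transition_ticket(tk, act[1],
                          trainer = if (!is.na(act[2])) act[2],
                          time = ts_h(1)),
        error = function(e) {
          expect_match(conditionMessage(e), "invalid ticket transition")
          ok <<- FALSE
          tk
        })
      if (!ok) break
    }
    expect_true(tk$status %in% c("open", "assigned", "resolved"))
    expect_identical(tk$status == "open", is.na(tk$owner))
  }
})

test_that("automatic participant emails are capped at 1 per 72 hours", {
  ev <- function(hs) data.frame(time = ts_h(hs), participant_id = "p1",
                                reason = "red_flag")
  # sliding-window oracle: flags at 0 h, 10 h, 80 h -> emails at 0 and 80
  out <- throttle_participant_emails(ev(c(0, 10, 80)), cfg)
  expect_identical(out$emitted, c(TRUE, FALSE, TRUE))
  expect_identical(throttle_participant_emails(ev(5), cfg)$emitted, TRUE)
  # suppressed events stay in the log, marked
  expect_identical(nrow(out), 3L)
  # hourly flags for 10 days never exceed the cap in any sliding window
  storm <- throttle_participant_emails(ev(0:239), cfg)
  sent <- storm$time[storm$emitted]
  expect_identical(max_emails_in_window(sent, 72), 1L)
  expect_identical(sum(storm$emitted), 4L) # 0, 72, 144, 216 h
  # throttling is per participant
  two <- data.frame(time = ts_h(c(0, 1)),
                    participant_id = c("p1", "p2"), reason = "red_flag")
  expect_identical(throttle_participant_emails(two, cfg)$emitted,
                   c(TRUE, TRUE))
  expect_error(throttle_participant_emails(ev(c(5, 1)), cfg), "ordered")
})

test_that("a CheerSquad holds at most five members", {
  sq <- cheersquad("p1", paste0("friend", 1:5), time = ts_h(0))
  expect_length(sq$members, 5L)
  expect_identical(nrow(sq$invitations), 5L)
  expect_error(add_member(sq, "friend6"), "at most 5")
  expect_error(cheersquad("p1", paste0("friend", 1:6)), "at most 5")
  sq4 <- cheersquad("p1", paste0("friend", 1:4), time = ts_h(0))
  expect_length(add_member(sq4, "friend5")$members, 5L)
})

test_that("milestones notify every squad member once per crossing", {
  st <- new_module_state("p1", ts_h(0))
  for (i in 1:30) st <- complete_session(st, i, ts_h(i * 50))
  sq <- cheersquad("p1", paste0("friend", 1:5), time = ts_h(0))
  ev <- milestone_events(st, sq)
  expect_identical(nrow(ev), 20L) # 4 default milestones x 5 members
  expect_identical(sort(unique(ev$milestone)), c(1L, 10L, 20L, 30L))
  expect_identical(sum(ev$milestone == 30), 5L)
  # partial module: only the crossed milestones fire
  st12 <- new_module_state("p1", ts_h(0))
  for (i in 1:12) st12 <- complete_session(st12, i, ts_h(i * 50))
  expect_identical(sort(unique(milestone_events(st12, sq)$milestone)),
                   c(1L, 10L))
  # an empty squad produces no events
  expect_identical(nrow(milestone_events(st, cheersquad("p1"))), 0L)
})
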