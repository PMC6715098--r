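# Comparable scoring and performance feedback: cohort-standardized exercise
# scores, domain-level aggregation, and the top-25% target zone.

#' Cohort reference distribution per exercise
#'
#' Location and scale of the comparison cohort's raw scores on each exercise.
#' Standardizing against these makes scores comparable across exercises with
#' different native scales.
#'
#' @param exercise_id character vector of exercise ids.
#' @param mean,sd numeric vectors; `sd` strictly positive.
#' @return a `cohort_reference` data frame (`exercise_id`, `mean`, `sd`).
#' @export
cohort_reference <- function(exercise_id, mean, sd) {
  n <- length(exercise_id)
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  stopifnot(length(mean) == n, length(sd) == n)
  if (anyDuplicated(exercise_id)) {
    stop("duplicate exercise ids in cohort reference", call. = FALSE)
  }
  structure(data.frame(exercise_id = as.character(exercise_id),
                       mean = as.numeric(mean), sd = as.numeric(sd),
                       stringsAsFactors = FALSE),
            class = c("cohort_reference", "data.frame"))
}

#' Cohort-comparable score for exercise results
#'
#' Standardizes each result's raw score against the cohort's distribution for
#' that exercise: `(raw_score - cohort mean) / cohort sd`. Affine-invariant:
#' rescaling an exercise's native scale together with its cohort distribution
#' leaves the comparable score unchanged.
#'
#' @param results a data frame of exercise results with columns `exercise_id`
#'   and `raw_score` (a single result may be given as a list with those
#'   fields).
#' @param cohort_dists a [cohort_reference()].
#' @return numeric vector of comparable (z) scores, one per result.
#' @export
comparable_score <- function(results, cohort_dists) {
  stopifnot(inherits(cohort_dists, "cohort_reference"))
  if (!is.data.frame(results)) results <- as.data.frame(results[c("exercise_id", "raw_score")])
  i <- match(results$exercise_id, cohort_dists$exercise_id)
  if (anyNA(i)) {
    stop("no cohort distribution for exercise(s): ",
         paste(sQuote(unique(results$exercise_id[is.na(i)])), collapse = ", "),
         call. = FALSE)
  }
  s <- cohort_dists$sd[i]
  if (any(!is.finite(s) | s <= 0)) {
    stop("degenerate cohort distribution (sd <= 0) for exercise(s): ",
         paste(sQuote(unique(cohort_dists$exercise_id[i][s <= 0])),
               collapse = ", "), call. = FALSE)
  }
  (results$raw_score - cohort_dists$mean[i]) / s
}

#' Domain-level scores for one participant
#'
#' Averages the cohort-comparable scores of a participant's attempts within
#' each cognitive domain. Domains with no attempts are absent from the
#' output.
#'
#' @param results data frame of the participant's exercise results
#'   (`exercise_id`, `raw_score`).
#' @param catalog an `exercise_catalog`.
#' @param cohort_dists a [cohort_reference()].
#' @return data frame with columns `domain`, `score`, `n_attempts`.
#' @export
domain_scores <- function(results, catalog, cohort_dists) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("'results' must be a non-empty data frame of exercise results",
         call. = FALSE)
  }
  z <- comparable_score(results, cohort_dists)
  dom <- factor(exercise_domain(catalog, results$exercise_id),
                levels = .DOMAINS)
  agg <- tapply(z, dom, mean)
  n <- tapply(z, dom, length)
  keep <- !is.na(agg)
  data.frame(domain = .DOMAINS[keep], score = as.numeric(agg[keep]),
             n_attempts = as.integer(n[keep]), stringsAsFactors = FALSE)
}

# target-zone lower bound: 75th percentile, linear-interpolation quantile
zone_bound <- function(scores) {
  as.numeric(stats::quantile(scores, 0.75, type = 7, names = FALSE))
}

#' Performance feedback with the top-25% target zone
#'
#' For each cognitive domain, compares one participant's domain score with
#' the cohort's distribution of domain scores and reports the target-zone
#' lower bound (the cohort's 75th percentile, linear-interpolation quantile)
#' and whether the participant is in the zone (score >= bound). This is the
#' data behind the feedback bar graph shown to participants.
#'
#' @param participant_scores data frame from [domain_scores()] for one
#'   participant.
#' @param cohort_scores long data frame of the cohort's domain scores with
#'   columns `participant_id`, `domain`, `score`.
#' @param min_cohort minimum cohort size per domain (default 20); smaller
#'   cohorts raise an error rather than show unstable percentiles.
#' @return data frame with columns `domain`, `score`, `zone_bound`,
#'   `in_zone`.
#' @export
feedback_graph <- function(participant_scores, cohort_scores,
                           min_cohort = 20) {
  stopifnot(is.data.frame(participant_scores),
            all(c("domain", "score") %in% names(participant_scores)),
            is.data.frame(cohort_scores),
            all(c("domain", "score") %in% names(cohort_scores)))
  out <- participant_scores[, c("domain", "score"), drop = FALSE]
  out$zone_bound <- NA_real_
  for (k in seq_len(nrow(out))) {
    pool <- cohort_scores$score[cohort_scores$domain == out$domain[k]]
    if (length(pool) < min_cohort) {
      stop("cohort for domain ", sQuote(out$domain[k]), " has ",
           length(pool), " participants; at least ", min_cohort,
           " are required for percentile feedback", call. = FALSE)
    }
    out$zone_bound[k] <- zone_bound(pool)
  }
  out$in_zone <- out$score >= out$zone_bound
  rownames(out) <- NULL
  out
}
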