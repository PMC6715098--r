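# Cognitive profiles: standardized per-domain scores, strength/mid/weakness
# tiers, and within-training refreshes.

.EPOCHS <- c("baseline", "refresh-13", "refresh-19", "refresh-25")
.REFRESH_POINTS <- c(13L, 19L, 25L)
# session range whose performance feeds the refresh at each point
.REFRESH_RANGES <- list(`13` = 1:12, `19` = 13:18, `25` = 19:24)

#' Normative reference for baseline assessments
#'
#' Holds the reference population's location and scale per assessment, the
#' yardstick against which baseline test scores are standardized. In the
#' live system these came from a pilot cohort; [generate_normative_cohort()]
#' produces a simulated equivalent.
#'
#' @param assessment_id character vector of assessment ids.
#' @param mean,sd numeric vectors (sd strictly positive).
#' @param provenance free-text label describing where the norms came from.
#' @return a `normative_reference` data frame (`assessment_id`, `mean`, `sd`).
#' @export
normative_reference <- function(assessment_id, mean, sd,
                                provenance = "unspecified") {
  n <- length(assessment_id)
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  stopifnot(length(mean) == n, length(sd) == n)
  if (any(!is.finite(sd) | sd <= 0)) {
    stop("normative SDs must all be positive", call. = FALSE)
  }
  if (anyDuplicated(assessment_id)) {
    stop("duplicate assessment ids in normative reference", call. = FALSE)
  }
  structure(data.frame(assessment_id = as.character(assessment_id),
                       mean = as.numeric(mean), sd = as.numeric(sd),
                       stringsAsFactors = FALSE),
            provenance = provenance,
            class = c("normative_reference", "data.frame"))
}

#' Standardize a raw assessment score
#'
#' @param raw numeric raw score on the assessment's native scale.
#' @param assessment_id id present in `norms`.
#' @param norms a [normative_reference()].
#' @return the z-score `(raw - mean) / sd`.
#' @export
standardize_score <- function(raw, assessment_id, norms) {
  stopifnot(inherits(norms, "normative_reference"))
  i <- match(assessment_id, norms$assessment_id)
  if (anyNA(i)) {
    stop("assessment ", sQuote(assessment_id[is.na(i)][1]),
         " not present in the normative reference", call. = FALSE)
  }
  (raw - norms$mean[i]) / norms$sd[i]
}

# ranking (highest z first) with ties broken by canonical domain order;
# z must be a full named vector in canonical order
rank_domains <- function(domain_z) {
  stopifnot(identical(names(domain_z), .DOMAINS))
  .DOMAINS[order(-domain_z, seq_along(domain_z))]
}

# 2/2/3 tier partition from a ranking
tiers_from_ranking <- function(ranking) {
  tiers <- c(rep("strength", 2), rep("mid", 2), rep("weakness", 3))
  names(tiers) <- ranking
  tiers[.DOMAINS] # canonical order, named by domain
}

#' Construct a cognitive profile from per-domain z-scores
#'
#' Ranks the seven domains from strength (highest z) to weakness (lowest z),
#' breaking ties by canonical domain order, and partitions them into 2
#' strength / 2 mid / 3 weakness tiers (ranks 1-2 / 3-4 / 5-7).
#'
#' @param participant_id participant identifier.
#' @param domain_z named numeric vector of z-scores covering all 7 domains.
#' @param epoch one of `"baseline"`, `"refresh-13"`, `"refresh-19"`,
#'   `"refresh-25"`.
#' @return a `cognitive_profile` with fields `participant_id`, `epoch`,
#'   `domain_z`, `ranking`, `tiers`.
#' @export
new_cognitive_profile <- function(participant_id, domain_z,
                                  epoch = "baseline") {
  epoch <- match.arg(epoch, .EPOCHS)
  if (!all(.DOMAINS %in% names(domain_z))) {
    stop("domain_z must cover all 7 cognitive domains; missing: ",
         paste(setdiff(.DOMAINS, names(domain_z)), collapse = ", "),
         call. = FALSE)
  }
  z <- as.numeric(domain_z[.DOMAINS])
  names(z) <- .DOMAINS
  if (anyNA(z)) stop("domain_z contains missing values", call. = FALSE)
  ranking <- rank_domains(z)
  structure(list(participant_id = participant_id, epoch = epoch,
                 domain_z = z, ranking = ranking,
                 tiers = tiers_from_ranking(ranking)),
            class = "cognitive_profile")
}

#' @export
print.cognitive_profile <- function(x, ...) {
  cat("cognitive_profile for", x$participant_id, "at epoch", x$epoch, "\n")
  for (i in seq_along(x$ranking)) {
    d <- x$ranking[i]
    cat(sprintf("  %d. %-16s z = %+.2f  [%s]\n", i, d, x$domain_z[[d]],
                x$tiers[[d]]))
  }
  invisible(x)
}

#' Build the baseline cognitive profile
#'
#' Standardizes each baseline assessment score against the normative
#' reference, aggregates to the domain level (averaging when a domain has
#' more than one assessment), and assigns the ranking and 2/2/3 tiers.
#'
#' @param test_scores named numeric vector of raw scores, one per assessment
#'   id in the catalog.
#' @param norms a [normative_reference()] covering those assessments.
#' @param catalog an `exercise_catalog`.
#' @param participant_id participant identifier.
#' @return a `cognitive_profile` at epoch `"baseline"`.
#' @export
#' @examples
#' cat <- load_catalog()
#' norms <- normative_reference(cat$assessments$id, mean = 50, sd = 10)
#' scores <- stats::setNames(rep(50, nrow(cat$assessments)),
#'                           cat$assessments$id)
#' build_baseline_profile(scores, norms, cat, "p1")
build_baseline_profile <- function(test_scores, norms, catalog,
                                   participant_id = "participant") {
  stopifnot(inherits(catalog, "exercise_catalog"))
  a <- catalog$assessments
  missing <- setdiff(a$id, names(test_scores))
  if (length(missing)) {
    dom <- a$domain[a$id %in% missing]
    stop("incomplete intake: no score for assessment(s) ",
         paste(sQuote(missing), collapse = ", "),
         " (domain(s) ", paste(unique(dom), collapse = ", "), ")",
         call. = FALSE)
  }
  z <- standardize_score(as.numeric(test_scores[a$id]), a$id, norms)
  domain_z <- tapply(z, factor(a$domain, levels = .DOMAINS), mean)
  new_cognitive_profile(participant_id, domain_z, epoch = "baseline")
}

#' Difficulty tier of an exercise under a profile
#'
#' Exercises in a participant's strength domains are easy for them, mid
#' domains medium, and weakness domains hard.
#'
#' @param profile a `cognitive_profile`.
#' @param exercise an exercise id (or a one-row exercise data frame).
#' @param catalog an `exercise_catalog`.
#' @return `"easy"`, `"medium"` or `"hard"` (vectorized over ids).
#' @export
classify_exercise <- function(profile, exercise, catalog) {
  stopifnot(inherits(profile, "cognitive_profile"))
  id <- if (is.data.frame(exercise)) exercise$id else exercise
  dom <- exercise_domain(catalog, id)
  unname(c(strength = "easy", mid = "medium",
           weakness = "hard")[profile$tiers[dom]])
}

#' Refresh a cognitive profile from within-training performance
#'
#' At sessions 13, 19 and 25 the profile is rebuilt from the participant's
#' exercise results over the preceding session range (1-12, 13-18, 19-24):
#' each attempt's raw score is standardized against the cohort's per-exercise
#' distribution and the standardized scores are averaged per domain. Domains
#' with no attempts in the range carry their previous z forward.
#'
#' @param profile the current `cognitive_profile`.
#' @param own_records data frame of the participant's exercise results with
#'   columns `exercise_id`, `session_index`, `raw_score`.
#' @param cohort_dists a [cohort_reference()] of per-exercise means/SDs.
#' @param refresh_point one of 13, 19, 25.
#' @param catalog an `exercise_catalog`.
#' @return a new `cognitive_profile` at epoch `refresh-<point>`.
#' @export
refresh_profile <- function(profile, own_records, cohort_dists, refresh_point,
                            catalog) {
  stopifnot(inherits(profile, "cognitive_profile"))
  refresh_point <- as.integer(refresh_point)
  if (!refresh_point %in% .REFRESH_POINTS) {
    stop("refresh_point must be one of 13, 19, 25", call. = FALSE)
  }
  range <- .REFRESH_RANGES[[as.character(refresh_point)]]
  rec <- own_records[own_records$session_index %in% range, , drop = FALSE]
  if (nrow(rec) == 0) {
    stop("cannot refresh at session ", refresh_point,
         ": no exercise results in sessions ", min(range), "-", max(range),
         call. = FALSE)
  }
  z <- comparable_score(rec, cohort_dists)
  dom <- exercise_domain(catalog, rec$exercise_id)
  new_z <- tapply(z, factor(dom, levels = .DOMAINS), mean)
  carry <- is.na(new_z)
  new_z[carry] <- profile$domain_z[.DOMAINS][carry]
  new_cognitive_profile(profile$participant_id, new_z,
                        epoch = paste0("refresh-", refresh_point))
}

# profile <-> plain list, for JSON state files
profile_to_list <- function(p) {
  list(participant_id = p$participant_id, epoch = p$epoch,
       domain_z = as.list(p$domain_z), ranking = p$ranking,
       tiers = as.list(p$tiers))
}

profile_from_list <- function(x) {
  new_cognitive_profile(x$participant_id,
                        unlist(x$domain_z)[.DOMAINS],
                        epoch = x$epoch)
}
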