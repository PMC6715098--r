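# Exercise catalog: the seven cognitive domains, the training exercises that
# load on them, and the baseline assessments used to build the cognitive
# profile.

.DOMAINS <- c("VerbalMemory", "VisualAttention", "VisualMemory",
              "VerbalExecutive", "VisualExecutive", "WorkingMemory",
              "ProcessingSpeed")

#' The seven cognitive domains
#'
#' Returns the closed set of cognitive domain labels used throughout the
#' engine, in canonical order. The order is fixed because it serves as the
#' tie-break order wherever domains are ranked.
#'
#' @return character vector of 7 domain labels.
#' @export
#' @examples
#' cognitive_domains()
cognitive_domains <- function() .DOMAINS

#' Load an exercise catalog
#'
#' Reads a YAML catalog listing training exercises (id, display name, domain)
#' and baseline assessments (id, domain, instrument name), validates it, and
#' returns an `exercise_catalog`. The packaged default maps 35 exercises and
#' 7 assessment scores onto the seven cognitive domains.
#'
#' @param path path to a YAML catalog; defaults to the packaged catalog.
#' @return an `exercise_catalog`: list with data frames `exercises`
#'   (`id`, `name`, `domain`) and `assessments` (`id`, `domain`,
#'   `source_name`).
#' @export
#' @examples
#' cat <- load_catalog()
#' table(cat$exercises$domain)
load_catalog <- function(path = system.file("extdata", "exercise_catalog.yaml",
                                            package = "cogtrainr")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("catalog file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$exercises) || is.null(raw$assessments)) {
    stop("catalog must contain 'exercises' and 'assessments' sections",
         call. = FALSE)
  }
  exercises <- do.call(rbind, lapply(raw$exercises, function(e) {
    data.frame(id = as.character(e$id), name = as.character(e$name),
               domain = as.character(e$domain), stringsAsFactors = FALSE)
  }))
  assessments <- do.call(rbind, lapply(raw$assessments, function(a) {
    data.frame(id = as.character(a$id), domain = as.character(a$domain),
               source_name = as.character(a$source_name),
               stringsAsFactors = FALSE)
  }))
  new_exercise_catalog(exercises, assessments)
}

#' Construct an exercise catalog from data frames
#'
#' Lower-level constructor used by [load_catalog()] and by tests that build
#' reduced catalogs. Validates domain labels, id uniqueness, and assessment
#' coverage of all seven domains.
#'
#' @param exercises data frame with columns `id`, `name`, `domain`.
#' @param assessments data frame with columns `id`, `domain`, `source_name`.
#' @return an `exercise_catalog`.
#' @export
new_exercise_catalog <- function(exercises, assessments) {
  stopifnot(is.data.frame(exercises),
            all(c("id", "name", "domain") %in% names(exercises)),
            is.data.frame(assessments),
            all(c("id", "domain", "source_name") %in% names(assessments)))
  bad <- which(!exercises$domain %in% .DOMAINS)
  if (length(bad)) {
    stop("unknown cognitive domain ", sQuote(exercises$domain[bad[1]]),
         " in exercise row ", bad[1], " (id ",
         sQuote(exercises$id[bad[1]]), ")", call. = FALSE)
  }
  bad <- which(!assessments$domain %in% .DOMAINS)
  if (length(bad)) {
    stop("unknown cognitive domain ", sQuote(assessments$domain[bad[1]]),
         " in assessment row ", bad[1], call. = FALSE)
  }
  dup <- exercises$id[duplicated(exercises$id)]
  if (length(dup)) {
    stop("duplicate exercise id(s): ", paste(sQuote(unique(dup)),
                                             collapse = ", "), call. = FALSE)
  }
  dup <- assessments$id[duplicated(assessments$id)]
  if (length(dup)) {
    stop("duplicate assessment id(s): ", paste(sQuote(unique(dup)),
                                               collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(.DOMAINS, assessments$domain)
  if (length(missing)) {
    stop("assessments do not cover domain(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rownames(exercises) <- NULL
  rownames(assessments) <- NULL
  structure(list(exercises = exercises, assessments = assessments),
            class = "exercise_catalog")
}

#' @export
print.exercise_catalog <- function(x, ...) {
  counts <- table(factor(x$exercises$domain, levels = .DOMAINS))
  cat("exercise_catalog:", nrow(x$exercises), "exercises,",
      nrow(x$assessments), "assessments across",
      length(.DOMAINS), "cognitive domains\n")
  for (d in .DOMAINS) cat(sprintf("  %-16s %d exercises\n", d, counts[[d]]))
  invisible(x)
}

#' Exercises belonging to a set of domains
#'
#' @param catalog an `exercise_catalog`.
#' @param domains non-empty character vector of domain labels.
#' @return the rows of `catalog$exercises` whose domain is in `domains`, in
#'   catalog order.
#' @export
#' @examples
#' exercises_in_domains(load_catalog(), "WorkingMemory")
exercises_in_domains <- function(catalog, domains) {
  stopifnot(inherits(catalog, "exercise_catalog"))
  if (length(domains) == 0) {
    stop("'domains' must be a non-empty set of cognitive domains",
         call. = FALSE)
  }
  bad <- setdiff(domains, .DOMAINS)
  if (length(bad)) {
    stop("unknown cognitive domain(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  out <- catalog$exercises[catalog$exercises$domain %in% domains, ,
                           drop = FALSE]
  rownames(out) <- NULL
  out
}

# domain of one exercise id; errors on unknown ids
exercise_domain <- function(catalog, exercise_id) {
  i <- match(exercise_id, catalog$exercises$id)
  if (anyNA(i)) {
    stop("unknown exercise id(s): ",
         paste(sQuote(exercise_id[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  catalog$exercises$domain[i]
}
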