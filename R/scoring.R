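#' Validate and resolve one lesion observation to its numeric grade
#'
#' Accepts either a numeric grade or a grade label ("absent", "present" for
#' binary lesions; "absent", "focal", "patchy", "diffuse" for graded
#' lesions) and returns the integer grade after range validation.
#'
#' @param grade Numeric grade or character label.
#' @param lesion_id Lesion identifier present in `scheme`.
#' @param scheme A [scoring_scheme][load_scheme].
#' @return Integer grade in `[0, max_grade]` for the lesion's scale.
#' @examples
#' score_lesion("diffuse", "syncytial_knots", default_scheme())  # 3
#' score_lesion("present", "villous_agglutination", default_scheme())  # 1
#' @export
score_lesion <- function(grade, lesion_id, scheme) {
  lesion <- .lesion_row(lesion_id, scheme)
  labels <- .grade_labels[[lesion$scale]]
  if (is.character(grade) || is.factor(grade)) {
    g <- match(tolower(as.character(grade)), labels) - 1L
    if (is.na(g)) {
      stop("unknown grade label '", grade, "' for ", lesion$scale, " lesion '",
           lesion_id, "' (expected one of: ", paste(labels, collapse = ", "), ")",
           call. = FALSE)
    }
    return(g)
  }
  if (length(grade) != 1L || is.na(grade)) {
    stop("grade for lesion '", lesion_id, "' must be a single non-missing value",
         call. = FALSE)
  }
  g <- as.integer(grade)
  if (g != grade) stop("grade for lesion '", lesion_id, "' must be an integer",
                       call. = FALSE)
  if (g < 0L || g > lesion$max_grade) {
    stop("grade ", g, " out of range [0, ", lesion$max_grade,
         "] for lesion '", lesion_id, "'", call. = FALSE)
  }
  g
}

.check_observations <- function(observations) {
  need <- c("participant_id", "lesion_id", "grade")
  missing_cols <- setdiff(need, names(observations))
  if (length(missing_cols)) {
    stop("observations must have columns ", paste(need, collapse = ", "),
         "; missing: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(observations) && length(unique(observations$participant_id)) > 1L) {
    stop("observations span more than one participant; score each participant ",
         "separately or use score_cohort()", call. = FALSE)
  }
  invisible(observations)
}

#' Severity score of one etiological category for one participant
#'
#' Sums the validated grades of the category's member lesions and caps the
#' sum at the category's maximum score. Lesions without an observation (or
#' with a missing grade) contribute 0; observations for lesions outside the
#' category are ignored.
#'
#' @param observations data.frame with columns `participant_id`, `lesion_id`,
#'   `grade` (numeric or label), for a single participant.
#' @param category_id Category identifier present in `scheme`.
#' @inheritParams score_lesion
#' @return Integer severity score in `[0, max_score]`.
#' @export
category_severity <- function(observations, category_id, scheme) {
  .check_observations(observations)
  category <- .category_row(category_id, scheme)
  members <- scheme$lesions$lesion_id[scheme$lesions$category_id == category_id]
  obs <- observations[observations$lesion_id %in% members, , drop = FALSE]
  if (anyDuplicated(obs$lesion_id)) {
    stop("duplicate observation for lesion(s): ",
         paste(unique(obs$lesion_id[duplicated(obs$lesion_id)]), collapse = ", "),
         call. = FALSE)
  }
  keep <- !is.na(obs$grade)
  grades <- vapply(
    which(keep),
    function(i) score_lesion(obs$grade[i], obs$lesion_id[i], scheme),
    integer(1)
  )
  min(sum(grades), category$max_score)
}

#' Full severity profile for one participant
#'
#' Computes every category severity score, the cumulative severity score
#' (sum over categories), and the severe maternal vascular malperfusion
#' (MVM) flag: MVM category score at or above `mvm_threshold`.
#'
#' @inheritParams category_severity
#' @param mvm_threshold MVM category score at or above which the placenta is
#'   classified as having severe MVM lesions. Default 2.
#' @return A `severity_profile` object: list with `participant_id`,
#'   `category_scores` (named integer vector), `cumulative_score`,
#'   `mvm_severe`, and observation completeness counts.
#' @examples
#' obs <- data.frame(participant_id = "p1",
#'                   lesion_id = c("placental_infarction", "syncytial_knots"),
#'                   grade = c(1, 2))
#' severity_profile(obs, default_scheme())
#' @export
severity_profile <- function(observations, scheme, mvm_threshold = 2L) {
  .check_observations(observations)
  unknown <- setdiff(unique(observations$lesion_id), scheme$lesions$lesion_id)
  if (length(unknown)) {
    stop("observations reference unknown lesion(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pid <- if (nrow(observations)) as.character(observations$participant_id[1]) else NA_character_
  scores <- vapply(
    scheme$categories$category_id,
    function(cid) category_severity(observations, cid, scheme),
    numeric(1)
  )
  scores <- as.integer(scores)
  names(scores) <- scheme$categories$category_id
  structure(
    list(
      participant_id   = pid,
      category_scores  = scores,
      cumulative_score = sum(scores),
      mvm_severe       = unname(scores[scheme$mvm_category] >= mvm_threshold),
      n_observed       = sum(!is.na(observations$grade)),
      n_lesions        = nrow(scheme$lesions)
    ),
    class = "severity_profile"
  )
}

#' @export
print.severity_profile <- function(x, ...) {
  cat("Placental severity profile for participant", x$participant_id, "\n")
  for (cid in names(x$category_scores)) {
    cat(sprintf("  %-24s %d\n", cid, x$category_scores[cid]))
  }
  cat("  cumulative score:", x$cumulative_score,
      " severe MVM:", x$mvm_severe, "\n")
  invisible(x)
}

#' Score a whole cohort of lesion observations
#'
#' Computes the [severity_profile()] quantities for every participant of a
#' long-format observation table (vectorized over the whole cohort; the two
#' routes agree exactly) and returns one row per participant with per-category
#' scores, cumulative score, severe-MVM flag and a completeness report
#' (missing lesion assessments are scored 0 but counted).
#'
#' @param observations Long-format data.frame (`participant_id`, `lesion_id`,
#'   `grade`). Use [lesions_wide_to_long()] for wide tables.
#' @inheritParams severity_profile
#' @return data.frame with columns `participant_id`, one score column per
#'   category id, `cumulative_score`, `mvm_score`, `mvm_severe`,
#'   `n_lesions_observed`, `n_lesions_total`, `complete`.
#' @export
score_cohort <- function(observations, scheme, mvm_threshold = 2L) {
  need <- c("participant_id", "lesion_id", "grade")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lesions <- scheme$lesions
  lidx <- match(observations$lesion_id, lesions$lesion_id)
  if (anyNA(lidx)) {
    stop("observations reference unknown lesion(s): ",
         paste(unique(observations$lesion_id[is.na(lidx)]), collapse = ", "),
         call. = FALSE)
  }
  pid <- as.character(observations$participant_id)
  if (anyDuplicated(paste(pid, observations$lesion_id))) {
    dup <- paste(pid, observations$lesion_id)
    stop("duplicate observation for participant/lesion: ",
         paste(unique(dup[duplicated(dup)])[1:min(3, sum(duplicated(dup)))],
               collapse = "; "), call. = FALSE)
  }
  # vectorized grade resolution (labels or integers); NA = not assessed
  grade <- observations$grade
  if (is.character(grade) || is.factor(grade)) {
    lab <- tolower(as.character(grade))
    g <- ifelse(lesions$scale[lidx] == "binary",
                match(lab, .grade_labels$binary) - 1L,
                match(lab, .grade_labels$graded) - 1L)
    bad <- !is.na(lab) & is.na(g)
    if (any(bad)) {
      stop("unknown grade label(s): ",
           paste(unique(lab[bad]), collapse = ", "), call. = FALSE)
    }
    grade <- g
  } else {
    bad <- !is.na(grade) &
      (grade != round(grade) | grade < 0 | grade > lesions$max_grade[lidx])
    if (any(bad)) {
      i <- which(bad)[1]
      stop("grade ", grade[i], " out of range [0, ", lesions$max_grade[lidx][i],
           "] for lesion '", observations$lesion_id[i], "'", call. = FALSE)
    }
  }
  pids <- unique(pid)
  m <- matrix(NA_integer_, length(pids), nrow(lesions),
              dimnames = list(pids, lesions$lesion_id))
  m[cbind(match(pid, pids), lidx)] <- as.integer(grade)
  n_observed <- rowSums(!is.na(m))
  m[is.na(m)] <- 0L  # unobserved / missing lesions contribute 0
  # category scores: summed member grades, capped
  cat_ind <- outer(lesions$category_id, scheme$categories$category_id, "==") * 1L
  raw <- m %*% cat_ind
  caps <- matrix(scheme$categories$max_score, length(pids),
                 nrow(scheme$categories), byrow = TRUE)
  cat_scores <- pmin(raw, caps)
  colnames(cat_scores) <- scheme$categories$category_id
  res <- data.frame(participant_id = pids, stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(cat_scores))
  res$cumulative_score <- as.integer(rowSums(cat_scores))
  res$mvm_score <- as.integer(cat_scores[, scheme$mvm_category])
  res$mvm_severe <- res$mvm_score >= mvm_threshold
  res$n_lesions_observed <- as.integer(n_observed)
  res$n_lesions_total <- nrow(lesions)
  res$complete <- res$n_lesions_observed == res$n_lesions_total
  rownames(res) <- NULL
  for (cid in scheme$categories$category_id) res[[cid]] <- as.integer(res[[cid]])
  res
}

#' Convert wide lesion columns to the long observation format
#'
#' A wide cohort table has one column per `lesion_id`; cells hold grades or
#' grade labels, `NA` meaning not assessed. Columns that are not lesion ids
#' of the scheme are ignored.
#'
#' @param cohort data.frame with `participant_id` and lesion columns.
#' @inheritParams score_lesion
#' @return Long data.frame (`participant_id`, `lesion_id`, `grade`).
#' @export
lesions_wide_to_long <- function(cohort, scheme) {
  if (!"participant_id" %in% names(cohort)) {
    stop("cohort must have a participant_id column", call. = FALSE)
  }
  lesion_cols <- intersect(scheme$lesions$lesion_id, names(cohort))
  if (!length(lesion_cols)) {
    stop("no lesion columns of the scheme found in the cohort table", call. = FALSE)
  }
  long <- do.call(rbind, lapply(lesion_cols, function(lid) {
    data.frame(
      participant_id = as.character(cohort$participant_id),
      lesion_id      = lid,
      grade          = cohort[[lid]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(long) <- NULL
  long
}

#' Read lesion observations from a delimited text file
#'
#' `read_lesions_long()` expects columns `participant_id`, `lesion_id`,
#' `grade` (numeric grades or labels). `read_lesions_wide()` expects one
#' column per lesion id and converts to long format. The field separator
#' (comma or tab) is auto-detected.
#'
#' @param path File path.
#' @inheritParams score_lesion
#' @return Long-format observation data.frame.
#' @export
read_lesions_long <- function(path) {
  tab <- .read_delim_auto(path)
  need <- c("participant_id", "lesion_id", "grade")
  if (!all(need %in% names(tab))) {
    stop("'", path, "' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab[need]
}

#' @rdname read_lesions_long
#' @export
read_lesions_wide <- function(path, scheme) {
  lesions_wide_to_long(.read_delim_auto(path), scheme)
}
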