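#' Ordered grade labels for the two lesion scales
#'
#' Binary lesions are scored 0 (absent) / 1 (present); graded lesions are
#' scored on a linear scale 0 (absent), 1 (focal), 2 (patchy), 3 (diffuse).
#' @keywords internal
.grade_labels <- list(
  binary = c("absent", "present"),
  graded = c("absent", "focal", "patchy", "diffuse")
)

.scale_max_grade <- c(binary = 1L, graded = 3L)

#' Path to a file shipped with the package
#' @keywords internal
.extdata <- function(file) {
  path <- system.file("extdata", file, package = "plascreen")
  if (!nzchar(path)) stop("shipped file not found: ", file, call. = FALSE)
  path
}

#' Load a synoptic scoring scheme from a config file
#'
#' Reads a YAML (or JSON; YAML is a superset) scheme file with `categories:`
#' and `lesions:` blocks, validates it, and returns a `scoring_scheme`
#' object. The scheme defines, for each named lesion, its scale (binary or
#' graded) and the etiological category it belongs to; each category carries
#' a maximum severity score at which the summed lesion grades are capped.
#'
#' @param path Path to the scheme file. Defaults to the shipped scheme with
#'   seven categories capped at 14, 4, 11, 5, 6, 5 and 6.
#' @return A `scoring_scheme` object: a list with elements `categories`
#'   (data.frame: `category_id`, `display_name`, `max_score`), `lesions`
#'   (data.frame: `lesion_id`, `display_name`, `category_id`, `scale`,
#'   `max_grade`), `mvm_category` and `version`.
#' @examples
#' scheme <- default_scheme()
#' scheme$categories
#' @seealso [severity_profile()], [score_cohort()]
#' @export
load_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file does not exist: ", path, call. = FALSE)
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("failed to parse scheme file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  as_scoring_scheme(raw, source = path)
}

#' @rdname load_scheme
#' @export
default_scheme <- function() {
  load_scheme(.extdata("default_scheme.yaml"))
}

#' Build and validate a scoring scheme from a parsed list
#' @keywords internal
as_scoring_scheme <- function(raw, source = "<list>") {
  for (block in c("categories", "lesions")) {
    if (is.null(raw[[block]])) {
      stop("scheme '", source, "' is missing the '", block, "' block", call. = FALSE)
    }
  }
  need <- function(entry, field, where) {
    if (is.null(entry[[field]])) {
      stop("scheme '", source, "': ", where, " entry is missing field '",
           field, "'", call. = FALSE)
    }
    entry[[field]]
  }
  categories <- do.call(rbind, lapply(raw$categories, function(cc) {
    data.frame(
      category_id  = as.character(need(cc, "category_id", "category")),
      display_name = as.character(if (is.null(cc$display_name)) cc$category_id else cc$display_name),
      max_score    = as.integer(need(cc, "max_score", "category")),
      stringsAsFactors = FALSE
    )
  }))
  lesions <- do.call(rbind, lapply(raw$lesions, function(ll) {
    data.frame(
      lesion_id    = as.character(need(ll, "lesion_id", "lesion")),
      display_name = as.character(if (is.null(ll$display_name)) ll$lesion_id else ll$display_name),
      category_id  = as.character(need(ll, "category_id", "lesion")),
      scale        = as.character(need(ll, "scale", "lesion")),
      stringsAsFactors = FALSE
    )
  }))
  if (anyDuplicated(categories$category_id)) {
    stop("scheme '", source, "': duplicate category_id: ",
         paste(unique(categories$category_id[duplicated(categories$category_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(lesions$lesion_id)) {
    stop("scheme '", source, "': duplicate lesion_id: ",
         paste(unique(lesions$lesion_id[duplicated(lesions$lesion_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_scale <- setdiff(unique(lesions$scale), names(.scale_max_grade))
  if (length(bad_scale)) {
    stop("scheme '", source, "': unknown scale '", paste(bad_scale, collapse = ", "),
         "' (must be 'binary' or 'graded')", call. = FALSE)
  }
  dangling <- setdiff(lesions$category_id, categories$category_id)
  if (length(dangling)) {
    stop("scheme '", source, "': lesion references unknown category: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  if (any(categories$max_score <= 0L)) {
    stop("scheme '", source, "': category max_score must be positive", call. = FALSE)
  }
  lesions$max_grade <- .scale_max_grade[lesions$scale]
  mvm_cat <- if (is.null(raw$mvm_category)) "mvm" else as.character(raw$mvm_category)
  if (!mvm_cat %in% categories$category_id) {
    stop("scheme '", source, "': mvm_category '", mvm_cat,
         "' is not a defined category", call. = FALSE)
  }
  structure(
    list(
      categories   = categories,
      lesions      = lesions,
      mvm_category = mvm_cat,
      version      = if (is.null(raw$version)) "unversioned" else as.character(raw$version)
    ),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Synoptic placental scoring scheme (version ", x$version, ")\n", sep = "")
  cat(nrow(x$lesions), " lesions in ", nrow(x$categories), " categories:\n", sep = "")
  for (i in seq_len(nrow(x$categories))) {
    cid <- x$categories$category_id[i]
    n <- sum(x$lesions$category_id == cid)
    cat(sprintf("  %-24s max score %2d  (%d lesions)\n",
                cid, x$categories$max_score[i], n))
  }
  invisible(x)
}

.lesion_row <- function(lesion_id, scheme) {
  i <- match(lesion_id, scheme$lesions$lesion_id)
  if (is.na(i)) stop("unknown lesion: '", lesion_id, "'", call. = FALSE)
  scheme$lesions[i, ]
}

.category_row <- function(category_id, scheme) {
  i <- match(category_id, scheme$categories$category_id)
  if (is.na(i)) stop("unknown category: '", category_id, "'", call. = FALSE)
  scheme$categories[i, ]
}
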