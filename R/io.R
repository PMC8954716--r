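#' Read a delimited text table, auto-detecting comma or tab separation
#' @keywords internal
.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read and write cohort tables
#'
#' Cohort tables are plain delimited text (tab by default) with one row per
#' participant. `write_cohort()` optionally writes a JSON sidecar with the
#' generator's ground-truth parameters when given a
#' [synthetic_cohort][generate_cohort] object.
#'
#' @param x A data.frame or `synthetic_cohort`.
#' @param path Output file path; the sidecar (if any) is `path` with a
#'   `.params.json` suffix.
#' @param sep Field separator, default tab.
#' @return `read_cohort()`: a data.frame. `write_cohort()`: `path`, invisibly.
#' @export
write_cohort <- function(x, path, sep = "\t") {
  cohort <- if (inherits(x, "synthetic_cohort")) x$cohort else x
  utils::write.table(cohort, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (inherits(x, "synthetic_cohort") && !is.null(x$params)) {
    jsonlite::write_json(unclass(x$params), paste0(path, ".params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- .read_delim_auto(path)
  # logical columns round-trip as TRUE/FALSE strings
  for (nm in names(tab)) {
    v <- tab[[nm]]
    if (is.character(v) && all(v %in% c("TRUE", "FALSE", "NA", NA), na.rm = TRUE) &&
        any(v %in% c("TRUE", "FALSE"))) {
      tab[[nm]] <- as.logical(v)
    }
  }
  tab
}
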