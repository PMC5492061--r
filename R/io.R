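#' Read a validated training-data CSV
#'
#' Comma-separated, UTF-8, header required.  Conditions are numeric (hours
#' as decimals; no unit conversion is performed); category labels are opaque
#' strings.  Row-level problems are reported with their line numbers.
#'
#' Schemas:
#' \describe{
#'   \item{categorical}{\code{specimen_id, condition, category} — one row
#'     per specimen per observation time.}
#'   \item{continuous}{\code{specimen_id, condition} plus one or more
#'     numeric response columns.}
#'   \item{mixed}{\code{specimen_id, condition, stage} plus one or more
#'     numeric response columns.}
#' }
#'
#' @param path CSV file path.
#' @param schema one of \code{"categorical"}, \code{"continuous"},
#'   \code{"mixed"}.
#' @return validated data frame.
#' @export
read_training_csv <- function(path,
                              schema = c("categorical", "continuous", "mixed")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  fixed <- switch(schema,
                  categorical = c("specimen_id", "condition", "category"),
                  continuous = c("specimen_id", "condition"),
                  mixed = c("specimen_id", "condition", "stage"))
  missing_cols <- setdiff(fixed, names(dat))
  if (length(missing_cols))
    stop("missing column(s) for schema '", schema, "': ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  resp <- setdiff(names(dat), fixed)
  if (schema != "categorical" && !length(resp))
    stop("schema '", schema, "' needs at least one response column",
         call. = FALSE)
  problems <- character()
  line_of <- function(i) i + 1L  # header is line 1
  cond <- suppressWarnings(as.numeric(dat$condition))
  bad <- which(is.na(cond) | !nzchar(dat$condition))
  if (length(bad))
    problems <- c(problems, paste0("line ", line_of(bad),
                                   ": non-numeric condition '",
                                   dat$condition[bad], "'"))
  dat$condition <- cond
  if (schema != "categorical") {
    for (rc in resp) {
      v <- suppressWarnings(as.numeric(dat[[rc]]))
      bad <- which(is.na(v) | !nzchar(dat[[rc]]))
      if (length(bad))
        problems <- c(problems, paste0("line ", line_of(bad),
                                       ": non-numeric ", rc, " '",
                                       dat[[rc]][bad], "'"))
      dat[[rc]] <- v
    }
  }
  lbl <- if (schema == "categorical") "category" else if (schema == "mixed") "stage"
  if (!is.null(lbl)) {
    bad <- which(!nzchar(dat[[lbl]]) | is.na(dat[[lbl]]))
    if (length(bad))
      problems <- c(problems, paste0("line ", line_of(bad), ": empty ", lbl))
  }
  if (length(problems))
    stop("invalid rows in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  dat
}

#' Write a training-data CSV
#'
#' @param data data frame as returned by [read_training_csv()] or the
#'   simulators.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_training_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Serialize an analysis result as JSON or text
#'
#' JSON reports are schema-versioned and embed everything needed to
#' reproduce the run (level, scheme or model description, per-condition
#' results, members, hull).  Text reports render confidence sets as
#' asterisk/gap rows over the candidate grid; an empty set is marked
#' explicitly, never left blank.
#'
#' @param result a \code{"confidence_set"}, \code{"coverage_report"} or
#'   \code{"f_test_result"}.
#' @param format \code{"json"} or \code{"text"}.
#' @param path optional file to write to.
#' @return the serialized report (character), invisibly if \code{path} is
#'   given.
#' @export
render_report <- function(result, format = c("json", "text"), path = NULL) {
  format <- match.arg(format)
  out <- if (format == "json") report_json(result) else report_text(result)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

report_json <- function(result) {
  body <- if (inherits(result, "confidence_set")) {
    list(schema_version = REPORT_SCHEMA_VERSION, type = "confidence_set",
         kind = result$kind, alpha = result$alpha,
         members = result$members,
         hull = if (is.null(result$hull)) NULL else
           list(lower = result$hull[1], upper = result$hull[2]),
         empty = length(result$members) == 0L,
         per_condition = result$per_condition)
  } else if (inherits(result, "coverage_report")) {
    c(list(schema_version = REPORT_SCHEMA_VERSION, type = "coverage_report"),
      unclass(result))
  } else if (inherits(result, "f_test_result")) {
    c(list(schema_version = REPORT_SCHEMA_VERSION, type = "f_test_result"),
      unclass(result))
  } else stop("cannot serialize a ", class(result)[1], call. = FALSE)
  jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null",
                   dataframe = "rows", pretty = TRUE)
}

report_text <- function(result) {
  if (inherits(result, "confidence_set")) {
    hdr <- sprintf("%d%% %s confidence set (alpha = %g)",
                   round(100 * (1 - result$alpha)), result$kind, result$alpha)
    grid <- result$per_condition$condition
    rejected <- if ("rejected" %in% names(result$per_condition))
      result$per_condition$rejected else !grid %in% result$members
    marks <- ifelse(rejected, "*", "")
    head <- formatC(grid, format = "g")
    w <- pmax(nchar(head), 1L)
    body <- c(paste(mapply(formatC, head, width = w), collapse = " "),
              paste(mapply(formatC, marks, width = w), collapse = " "))
    tail <- if (!length(result$members)) "EMPTY SET (all conditions rejected)"
    else sprintf("members: %d values, hull [%g, %g]",
                 length(result$members), result$hull[1], result$hull[2])
    c(hdr, body, tail)
  } else if (inherits(result, "coverage_report")) {
    utils::capture.output(print(result))
  } else if (inherits(result, "f_test_result")) {
    utils::capture.output(print(result))
  } else stop("cannot render a ", class(result)[1], call. = FALSE)
}

#' Serialize a fitted growth model to JSON
#'
#' Stores the basis, coefficients, residual scatter, degrees of freedom and
#' design cross-product inverse, so inverse prediction can be run later or
#' elsewhere without the training data.
#'
#' @param model a [fit_growth_model()] fit.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @seealso [read_growth_model()]
#' @export
write_growth_model <- function(model, path) {
  stopifnot(inherits(model, "growth_model"))
  body <- list(schema_version = REPORT_SCHEMA_VERSION, type = "growth_model",
               basis = model$basis, degree = model$degree,
               levels = model$levels, range = model$range,
               q = model$q, N = model$N, df = model$df,
               responses = model$responses,
               coefficients = model$coefficients,
               scatter = model$scatter, xtx_inv = model$xtx_inv)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a serialized growth model
#'
#' @param path JSON path written by [write_growth_model()].
#' @return a \code{"growth_model"} equivalent to the fitted original.
#' @export
read_growth_model <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$type, "growth_model"))
    stop(path, " is not a serialized growth model", call. = FALSE)
  cf <- matrix(as.numeric(b$coefficients), ncol = b$q)
  colnames(cf) <- b$responses
  structure(list(coefficients = cf,
                 scatter = matrix(as.numeric(b$scatter), b$q, b$q),
                 df = as.integer(b$df),
                 xtx_inv = matrix(as.numeric(b$xtx_inv), nrow(cf), nrow(cf)),
                 basis = b$basis,
                 degree = if (is.null(b$degree) || is.na(b$degree)) NA
                 else as.integer(b$degree),
                 levels = as.numeric(b$levels), range = as.numeric(b$range),
                 q = as.integer(b$q), N = as.integer(b$N),
                 responses = b$responses),
            class = "growth_model")
}
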