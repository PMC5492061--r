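#' Declare a categorical response scheme
#'
#' The category scheme fixes the number of response categories \code{c} that
#' enters the conservative matching test.  \code{c} is a property of the
#' declared design, not of the categories actually observed: scoring
#' presence/absence of \code{s} species gives \code{c = 2^s} even if some
#' combinations were never seen in training.
#'
#' @param labels character vector of distinct, non-empty category labels.
#' @return an object of class \code{"category_scheme"} with elements
#'   \code{labels} and \code{c}.
#' @examples
#' category_scheme(c("present", "absent"))
#' category_scheme(apply(expand.grid(0:1, 0:1), 1, paste, collapse = ""))
#' @export
category_scheme <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("a category scheme needs at least 2 labels", call. = FALSE)
  if (anyDuplicated(labels) || any(!nzchar(labels)) || anyNA(labels))
    stop("category labels must be unique and non-empty", call. = FALSE)
  structure(list(labels = labels, c = length(labels)),
            class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("Category scheme with c =", x$c, "categories:\n ",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Per-condition category counts from categorical training data
#'
#' Builds the training table used by [categorical_confidence_set()]: for each
#' sampled condition value (time since placement in hours, or insect age),
#' the counts of training specimens over the declared category scheme.
#'
#' @param conditions numeric vector of condition values, strictly increasing.
#' @param counts integer matrix, one row per condition, one column per scheme
#'   label (column names must match the scheme, or be unnamed in scheme
#'   order).
#' @param scheme a [category_scheme()].
#' @return an object of class \code{"categorical_training_table"} with
#'   elements \code{scheme}, \code{conditions}, \code{counts} and per-
#'   condition totals \code{n_t}.
#' @export
categorical_training_table <- function(conditions, counts, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  conditions <- as.numeric(conditions)
  if (anyNA(conditions) || is.unsorted(conditions, strictly = TRUE))
    stop("'conditions' must be strictly increasing and free of NA", call. = FALSE)
  counts <- as.matrix(counts)
  if (nrow(counts) != length(conditions) || ncol(counts) != scheme$c)
    stop("'counts' must be length(conditions) x scheme$c", call. = FALSE)
  if (!is.null(colnames(counts))) {
    if (!setequal(colnames(counts), scheme$labels))
      stop("count columns do not match scheme labels", call. = FALSE)
    counts <- counts[, scheme$labels, drop = FALSE]
  } else colnames(counts) <- scheme$labels
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  n_t <- as.integer(rowSums(counts))
  if (any(n_t < 1))
    stop("every condition needs at least one training specimen", call. = FALSE)
  structure(list(scheme = scheme, conditions = conditions,
                 counts = counts, n_t = n_t),
            class = "categorical_training_table")
}

#' Build a categorical training table from long-form records
#'
#' Pivots one-row-per-specimen records (columns \code{specimen_id},
#' \code{condition}, \code{category}) into per-condition category counts.
#' Categories observed in the data must belong to the declared scheme; the
#' scheme may declare categories never observed.
#'
#' @param data data frame with columns \code{specimen_id}, \code{condition},
#'   \code{category}.
#' @param scheme a [category_scheme()]; if missing, one is built from the
#'   observed categories (with a message, since \code{c} should normally be
#'   fixed by design).
#' @return a [categorical_training_table()].
#' @export
pivot_categorical <- function(data, scheme = NULL) {
  need <- c("specimen_id", "condition", "category")
  if (!all(need %in% names(data)))
    stop("data needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  data$condition <- as.numeric(data$condition)
  if (anyNA(data$condition)) stop("non-numeric condition values", call. = FALSE)
  if (is.null(scheme)) {
    scheme <- category_scheme(sort(unique(as.character(data$category))))
    message("no scheme declared; using the ", scheme$c,
            " observed categories (c should normally be fixed by design)")
  }
  bad <- setdiff(unique(as.character(data$category)), scheme$labels)
  if (length(bad))
    stop("categories outside the declared scheme: ",
         paste(bad, collapse = ", "), call. = FALSE)
  conds <- sort(unique(data$condition))
  tab <- table(factor(data$condition, levels = conds),
               factor(as.character(data$category), levels = scheme$labels))
  categorical_training_table(conds, unclass(as.matrix(tab)), scheme)
}

#' Confidence set on condition from a categorical response
#'
#' For each sampled condition value, counts how many training specimens fall
#' in the mystery specimen's category and applies the conservative matching
#' test; the non-rejected conditions form a confidence set with coverage at
#' least \code{1 - alpha}.  Rejection uses \code{p <= alpha}, which is what
#' makes the printed minimum sample sizes attainable at their boundary
#' (e.g. n = 7, c = 2 rejects at 5% with p ~ 0.0491).
#'
#' A mystery-specimen category never observed in training is fine (the match
#' count is 0 at every condition); a category outside the declared scheme is
#' an error, because the number of scheme categories enters the p-value —
#' re-declare the scheme if the category is genuinely possible.
#'
#' @param table a [categorical_training_table()].
#' @param ms_label the mystery specimen's category label.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return an object of class \code{"confidence_set"}: \code{alpha},
#'   \code{members} (non-rejected condition values), \code{hull}
#'   (range of members, \code{NULL} if empty), and \code{per_condition},
#'   a data frame with one row per condition
#'   (\code{condition, n, m, p_value, rejected}).
#' @examples
#' sch <- category_scheme(c("present", "absent"))
#' tab <- categorical_training_table(
#'   c(24, 48, 72), rbind(c(0, 20), c(10, 10), c(20, 0)), sch)
#' categorical_confidence_set(tab, "present")
#' @export
categorical_confidence_set <- function(table, ms_label, alpha = 0.05) {
  stopifnot(inherits(table, "categorical_training_table"),
            length(alpha) == 1L, alpha > 0, alpha < 1)
  ms_label <- as.character(ms_label)
  if (!ms_label %in% table$scheme$labels)
    stop("mystery-specimen category '", ms_label, "' is outside the declared ",
         "scheme; extend the scheme (c enters the p-value) and rebuild the ",
         "training table", call. = FALSE)
  m <- table$counts[, ms_label]
  p <- conservative_p_value(table$n_t, table$scheme$c, m)
  per <- data.frame(condition = table$conditions, n = table$n_t,
                    m = as.integer(m), p_value = p, rejected = p <= alpha,
                    row.names = NULL)
  new_confidence_set(alpha, members = table$conditions[p > alpha],
                     per_condition = per, kind = "categorical")
}

new_confidence_set <- function(alpha, members, per_condition, kind,
                               extra = list()) {
  hull <- if (length(members)) range(members) else NULL
  structure(c(list(alpha = alpha, members = members, hull = hull,
                   per_condition = per_condition, kind = kind), extra),
            class = "confidence_set")
}

#' @export
print.confidence_set <- function(x, ...) {
  cat(sprintf("%d%% %s confidence set on condition\n",
              round(100 * (1 - x$alpha)), x$kind))
  if (!length(x$members)) {
    cat("  EMPTY SET: every candidate condition was rejected\n")
  } else {
    cat(sprintf("  %d of %d candidate values retained; hull [%g, %g]\n",
                length(x$members), nrow(x$per_condition),
                x$hull[1], x$hull[2]))
  }
  invisible(x)
}
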