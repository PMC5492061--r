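#' Specify a combination of responses for age prediction
#'
#' Age-prediction models can use continuous responses (body length L, body
#' width W), the categorical response (instar I), or combinations (L+W, W+I,
#' L+W+I, ...).  The categorical and continuous components are combined by a
#' Bonferroni union: a candidate age is rejected if either component rejects
#' at its share of the overall level, which guarantees the joint level
#' without any assumption linking stage and size.  Multiple continuous
#' responses enter jointly through the multivariate pivot, not by further
#' splitting.
#'
#' @param continuous character vector of continuous response names to use
#'   (possibly empty).
#' @param use_stage use the categorical stage response?
#' @param alpha_split optional c(alpha_cat, alpha_cont) overriding the
#'   default equal split of the overall level; must be non-negative and is
#'   rescaled to sum to the overall alpha at prediction time.
#' @return an object of class \code{"model_combo"}.
#' @examples
#' model_combo(c("width"), use_stage = TRUE)    # the W + I model
#' model_combo(character(), use_stage = TRUE)   # stage only
#' @export
model_combo <- function(continuous = character(), use_stage = FALSE,
                        alpha_split = NULL) {
  continuous <- as.character(continuous)
  if (!length(continuous) && !use_stage)
    stop("a model combo needs at least one active component", call. = FALSE)
  if (!is.null(alpha_split)) {
    stopifnot(length(alpha_split) == 2L, all(alpha_split >= 0),
              sum(alpha_split) > 0)
    if (!use_stage && alpha_split[1] > 0)
      stop("alpha_cat must be 0 when stage is unused", call. = FALSE)
    if (!length(continuous) && alpha_split[2] > 0)
      stop("alpha_cont must be 0 when no continuous response is used",
           call. = FALSE)
  }
  structure(list(continuous = continuous, use_stage = use_stage,
                 alpha_split = alpha_split),
            class = "model_combo")
}

combo_label <- function(combo) {
  parts <- c(combo$continuous, if (combo$use_stage) "stage")
  paste(parts, collapse = "+")
}

resolve_split <- function(combo, alpha) {
  if (!is.null(combo$alpha_split))
    return(combo$alpha_split * alpha / sum(combo$alpha_split))
  if (combo$use_stage && length(combo$continuous)) c(alpha / 2, alpha / 2)
  else if (combo$use_stage) c(alpha, 0)
  else c(0, alpha)
}

#' Confidence set on condition from mixed responses
#'
#' Combines the categorical stage test ([categorical_confidence_set()]) and
#' the continuous inverse-prediction test ([inverse_p_value()]) over a shared
#' grid of candidate conditions.  A condition is rejected if either active
#' component rejects at its share of \code{alpha} (Bonferroni union), so the
#' combined set is contained in each component's set and keeps overall
#' coverage at least \code{1 - alpha}.
#'
#' The stage component can only be tested at conditions with categorical
#' training data; grid conditions without it are testable by the continuous
#' component alone and are flagged in the output.
#'
#' @param cat_table a [categorical_training_table()], or NULL when the combo
#'   does not use stage.
#' @param growth_model a [fit_growth_model()] fit on the continuous
#'   responses, or NULL when the combo uses stage only.
#' @param ms the mystery specimen: a list with \code{y_star} (named numeric,
#'   matching the model's responses) and/or \code{stage} (category label).
#' @param combo a [model_combo()].
#' @param grid candidate conditions; default the growth model's grid, or the
#'   categorical table's conditions for a stage-only combo.
#' @param alpha overall significance level; default 0.05.
#' @return a \code{"confidence_set"} whose \code{per_condition} carries the
#'   component p-values and an \code{untestable_by_stage} flag.
#' @export
combined_confidence_set <- function(cat_table = NULL, growth_model = NULL,
                                    ms, combo, grid = NULL, alpha = 0.05) {
  stopifnot(inherits(combo, "model_combo"),
            length(alpha) == 1L, alpha > 0, alpha < 1)
  split <- resolve_split(combo, alpha)
  if (combo$use_stage) {
    stopifnot(inherits(cat_table, "categorical_training_table"))
    if (is.null(ms$stage)) stop("combo uses stage but ms$stage is missing",
                                call. = FALSE)
  }
  use_cont <- length(combo$continuous) > 0L
  if (use_cont) {
    stopifnot(inherits(growth_model, "growth_model"))
    if (!all(combo$continuous %in% growth_model$responses))
      stop("combo responses not in the fitted model: ",
           paste(setdiff(combo$continuous, growth_model$responses),
                 collapse = ", "), call. = FALSE)
    if (!setequal(combo$continuous, growth_model$responses))
      stop("refit the growth model on exactly the combo's responses (",
           paste(combo$continuous, collapse = ", "), ")", call. = FALSE)
    y_star <- unlist(ms$y_star)[growth_model$responses]
    if (anyNA(y_star)) stop("ms$y_star lacks responses: ",
                            paste(combo$continuous, collapse = ", "),
                            call. = FALSE)
  }
  if (is.null(grid))
    grid <- if (use_cont) condition_grid(growth_model) else cat_table$conditions
  grid <- as.numeric(grid)

  p_cont <- rep(NA_real_, length(grid))
  if (use_cont)
    p_cont <- inverse_p_value(growth_model, y_star, grid)
  p_cat <- rep(NA_real_, length(grid))
  untestable <- rep(FALSE, length(grid))
  if (combo$use_stage) {
    if (!ms$stage %in% cat_table$scheme$labels)
      stop("mystery-specimen stage '", ms$stage, "' is outside the declared ",
           "scheme", call. = FALSE)
    idx <- match(grid, cat_table$conditions)
    ok <- !is.na(idx)
    p_cat[ok] <- conservative_p_value(cat_table$n_t[idx[ok]],
                                      cat_table$scheme$c,
                                      cat_table$counts[idx[ok], ms$stage])
    untestable <- !ok
    if (any(untestable) && !use_cont)
      stop("grid conditions without categorical training data in a ",
           "stage-only combo: ", paste(grid[untestable], collapse = ", "),
           call. = FALSE)
    if (any(untestable))
      message(sum(untestable), " grid condition(s) untestable by stage; ",
              "continuous component only applies there")
  }
  rej_cat <- combo$use_stage & !is.na(p_cat) & split[1] > 0 & p_cat <= split[1]
  rej_cont <- use_cont & !is.na(p_cont) & split[2] > 0 & p_cont <= split[2]
  rejected <- rej_cat | rej_cont
  per <- data.frame(condition = grid, p_cat = p_cat, p_cont = p_cont,
                    untestable_by_stage = untestable, rejected = rejected)
  new_confidence_set(alpha, members = grid[!rejected], per_condition = per,
                     kind = paste0("combined (", combo_label(combo), ")"),
                     extra = list(alpha_split = split,
                                  combo = combo_label(combo)))
}

#' Summarize confidence-set widths across model combinations
#'
#' The practical quality of a prediction model is how narrow its confidence
#' sets are, at equal coverage: the narrower the interval, the better.  Given
#' sets computed on a common grid, reports per model the member count, the
#' hull width in condition units, and whether the set is empty, ordered from
#' narrowest to widest.
#'
#' @param sets named list of \code{"confidence_set"} objects on a common
#'   grid (names label the model combinations).
#' @return data frame with columns \code{model}, \code{n_members},
#'   \code{hull_width}, \code{empty}, ordered by increasing hull width.
#' @export
set_width_summary <- function(sets) {
  stopifnot(length(sets) > 0L,
            all(vapply(sets, inherits, logical(1), "confidence_set")))
  if (is.null(names(sets)))
    names(sets) <- vapply(sets, function(s) s$kind, character(1))
  g0 <- sets[[1]]$per_condition$condition
  for (s in sets)
    if (!identical(s$per_condition$condition, g0))
      stop("confidence sets are not on a common grid", call. = FALSE)
  out <- data.frame(
    model = names(sets),
    n_members = vapply(sets, function(s) length(s$members), integer(1)),
    hull_width = vapply(sets, function(s)
      if (length(s$members)) diff(range(s$members)) else 0, numeric(1)),
    empty = vapply(sets, function(s) length(s$members) == 0L, logical(1)),
    row.names = NULL)
  out[order(out$hull_width, out$n_members), , drop = FALSE]
}

#' Render confidence sets as asterisk/gap rows over the grid
#'
#' Text rendering for side-by-side comparison of model combinations: one row
#' per model, an asterisk where the candidate condition is rejected and a
#' gap where it is retained, so the prediction interval is read off as the
#' gap in each row.
#'
#' @inheritParams set_width_summary
#' @return character vector, one line per model plus a header, invisibly;
#'   printed to the console.
#' @export
render_asterisk_rows <- function(sets) {
  stopifnot(length(sets) > 0L)
  if (is.null(names(sets)))
    names(sets) <- vapply(sets, function(s) s$kind, character(1))
  grid <- sets[[1]]$per_condition$condition
  head <- formatC(grid, format = "g")
  w <- pmax(nchar(head), 1L)
  pad <- function(x) paste(mapply(formatC, x, width = w), collapse = " ")
  namew <- max(nchar(c("MODEL", names(sets))))
  lines <- paste(formatC("MODEL", width = namew, flag = "-"), pad(head))
  for (nm in names(sets)) {
    s <- sets[[nm]]
    mark <- ifelse(s$per_condition$rejected, "*", "")
    if (!length(s$members)) mark[] <- "*"
    lines <- c(lines, paste(formatC(nm, width = namew, flag = "-"), pad(mark)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
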