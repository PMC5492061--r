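#' Subsample a single-age cohort
#'
#' The two sampling schemes whose consequences for inverse prediction are
#' compared throughout this package: a genuinely random subsample, and the
#' size-biased scheme of deliberately taking the largest individuals from a
#' rearing container.  Under multiplicative growth-rate heterogeneity the
#' biased scheme selects intrinsically fast growers at every age, so a model
#' trained on it systematically misjudges the age of typical specimens.
#'
#' @param responses numeric vector: the response (e.g. larval length, mm)
#'   of every individual in the cohort.
#' @param scheme \code{"random"} or \code{"largest_k"}.
#' @param s subsample size, between 1 and the cohort size.
#' @param seed integer seed; required for \code{"random"} so the subsample
#'   is reproducible.
#' @return integer vector of selected indices (ties in \code{largest_k}
#'   broken by stable input order).
#' @export
subsample_cohort <- function(responses, scheme = c("random", "largest_k"),
                             s, seed = NULL) {
  scheme <- match.arg(scheme)
  n <- length(responses)
  if (s < 1 || s > n) stop("subsample size s must be in 1..", n, call. = FALSE)
  if (scheme == "random") {
    if (is.null(seed)) stop("random subsampling requires a seed", call. = FALSE)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    sample.int(n, s)
  } else {
    order(responses, decreasing = TRUE)[seq_len(s)]
  }
}

#' Coverage proportion of inverse-prediction confidence sets
#'
#' The package's criterion for training-experiment design and model quality:
#' build the predictor from a training table, compute a confidence set on
#' condition for each evaluation specimen of known condition, and report the
#' proportion of sets containing the truth.  A sound design at level
#' \code{alpha} achieves coverage of at least \code{1 - alpha}; a biased
#' design shows up as coverage below nominal, regardless of how precise the
#' fit looks.
#'
#' A grid-based set contains the true condition when the truth is within
#' half a grid step of some member (a continuous true age rarely equals a
#' grid point exactly).
#'
#' @param train data frame with column \code{condition} and the response
#'   column(s) named in \code{responses}.
#' @param eval_data data frame with the same columns: evaluation specimens
#'   of known condition, normally fresh draws disjoint from training.
#' @param responses character vector of response column names (q >= 1).
#' @param degree polynomial degree for [fit_growth_model()].
#' @param alpha nominal level; default 0.05.
#' @param grid candidate-condition grid; default [condition_grid()] of the
#'   fitted model.
#' @param scheme_label free-text description of the training design,
#'   carried into the report.
#' @return an object of class \code{"coverage_report"}: \code{n_eval},
#'   \code{n_covered}, \code{coverage}, \code{mean_hull_width},
#'   \code{alpha}, \code{scheme_label}.
#' @export
coverage_proportion <- function(train, eval_data, responses, degree = 2L,
                                alpha = 0.05, grid = NULL,
                                scheme_label = "") {
  for (d in list(train, eval_data))
    if (!all(c("condition", responses) %in% names(d)))
      stop("need columns 'condition' and ", paste(responses, collapse = ", "),
           call. = FALSE)
  model <- tryCatch(
    fit_growth_model(train$condition,
                     as.matrix(train[, responses, drop = FALSE]),
                     degree = degree),
    error = function(e) stop("predictor construction failed for design '",
                             scheme_label, "': ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(grid)) grid <- condition_grid(model)
  step <- if (length(grid) > 1L) stats::median(diff(grid)) else Inf
  Y <- as.matrix(eval_data[, responses, drop = FALSE])
  covered <- logical(nrow(Y))
  width <- numeric(nrow(Y))
  for (i in seq_len(nrow(Y))) {
    p <- suppressWarnings(inverse_p_value(model, Y[i, ], grid))
    members <- grid[!is.na(p) & p > alpha]
    covered[i] <- length(members) > 0 &&
      min(abs(members - eval_data$condition[i])) <= step / 2 + 1e-9
    width[i] <- if (length(members)) diff(range(members)) else 0
  }
  structure(list(n_eval = nrow(Y), n_covered = sum(covered),
                 coverage = mean(covered), mean_hull_width = mean(width),
                 alpha = alpha, scheme_label = scheme_label),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "Coverage report%s: %d/%d sets (%.1f%%) contain the true condition\n",
    if (nzchar(x$scheme_label)) paste0(" [", x$scheme_label, "]") else "",
    x$n_covered, x$n_eval, 100 * x$coverage))
  cat(sprintf("  nominal %.0f%%; mean hull width %.2f condition units\n",
              100 * (1 - x$alpha), x$mean_hull_width))
  invisible(x)
}

#' Coverage when transferring a model across populations
#'
#' Trains on population A and evaluates coverage on labeled specimens from
#' population B (e.g. larvae reared on a different food substrate).  This is
#' the practical test of whether a covariate matters for prediction: a
#' covariate can have a strongly significant effect on growth
#' ([group_effect_f_test()]) while the transferred model still covers at or
#' above nominal, because prediction intervals absorb a small mean shift
#' within their individual-variation width.
#'
#' @param train_a training data frame from population A.
#' @param eval_b evaluation data frame from population B.
#' @inheritParams coverage_proportion
#' @return a \code{"coverage_report"} labeled as a transfer.
#' @export
transfer_coverage <- function(train_a, eval_b, responses, degree = 2L,
                              alpha = 0.05, grid = NULL,
                              scheme_label = "transfer A -> B") {
  coverage_proportion(train_a, eval_b, responses, degree = degree,
                      alpha = alpha, grid = grid,
                      scheme_label = scheme_label)
}

#' F-test for a group effect on the response across sampled ages
#'
#' Least-squares test of whether two training populations (e.g. two rearing
#' substrates) differ in mean response, treating the sampled condition
#' values as a categorical cell factor.  The full model has one mean per
#' group-by-age cell; the null model has one mean per age.  The numerator
#' degrees of freedom are therefore the group main effect plus the
#' group-by-age interaction (with a sampled ages and 2 groups, a cells),
#' and the denominator is the within-cell residual.
#'
#' @param td_a,td_b data frames with columns \code{condition} and the
#'   response named in \code{response}; the two groups must share their
#'   sampled conditions, with at least 2 specimens per cell.
#' @param response name of the response column; default \code{"response"}.
#' @return an object of class \code{"f_test_result"}: \code{F},
#'   \code{df_num}, \code{df_den}, \code{p}.
#' @export
group_effect_f_test <- function(td_a, td_b, response = "response") {
  for (d in list(td_a, td_b))
    if (!all(c("condition", response) %in% names(d)))
      stop("need columns 'condition' and '", response, "'", call. = FALSE)
  conds <- sort(unique(c(td_a$condition, td_b$condition)))
  dat <- rbind(
    data.frame(condition = td_a$condition, y = td_a[[response]], group = "A"),
    data.frame(condition = td_b$condition, y = td_b[[response]], group = "B"))
  cell_n <- table(factor(dat$condition, levels = conds), dat$group)
  if (any(cell_n < 2)) {
    bad <- which(cell_n < 2, arr.ind = TRUE)
    stop("cells with fewer than 2 specimens: ",
         paste(sprintf("(condition %s, group %s)",
                       rownames(cell_n)[bad[, 1]],
                       colnames(cell_n)[bad[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  dat$cell <- factor(dat$condition)
  fit0 <- stats::lm(y ~ cell, data = dat)
  fit1 <- stats::lm(y ~ cell * group, data = dat)
  an <- stats::anova(fit0, fit1)
  structure(list(F = an$F[2], df_num = as.integer(an$Df[2]),
                 df_den = as.integer(an$Res.Df[2]), p = an$`Pr(>F)`[2]),
            class = "f_test_result")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf("Group effect: F = %.2f, df = %d/%d, p = %.3g\n",
              x$F, x$df_num, x$df_den, x$p))
  invisible(x)
}
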