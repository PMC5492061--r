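#' Fit a growth model for inverse prediction
#'
#' Ordinary least-squares regression of one or more continuous responses
#' (larval length, width, in mm) on a polynomial basis in the condition
#' (age in hours).  The fit keeps everything inverse prediction needs: the
#' coefficient matrix, the residual (co)variance with its degrees of freedom,
#' and the design cross-product for the leverage \eqn{h(t_0) =
#' x(t_0)^\top (X^\top X)^{-1} x(t_0)}.  The default degree 2 accommodates
#' the unimodal rise-then-fall shape of larval size against age
#' (post-feeding shrinkage); degree 1 suffices for a monotone window.
#'
#' A cell-means basis (\code{basis = "cell_means"}) is available for sparse
#' designs: the condition is treated as a factor, so prediction and inverse
#' prediction are only defined at the sampled condition values, with no
#' interpolation between them.
#'
#' @param conditions numeric vector of known condition values, length N.
#' @param responses numeric vector (q = 1) or N x q matrix of responses.
#' @param degree polynomial degree d (default 2); ignored for cell means.
#' @param basis \code{"polynomial"} or \code{"cell_means"}.
#' @return an object of class \code{"growth_model"}: \code{coefficients}
#'   ((d+1) x q), \code{scatter} (q x q residual covariance; the MSE when
#'   q = 1), \code{df} (residual degrees of freedom \eqn{\nu}),
#'   \code{xtx_inv}, \code{range} of sampled conditions, \code{q}, \code{N}.
#' @examples
#' age <- rep(c(24, 48, 72, 96), each = 6)
#' len <- 2 + 0.15 * age - 0.0006 * age^2 + rnorm(length(age), 0, 0.4)
#' fit_growth_model(age, len, degree = 2)
#' @export
fit_growth_model <- function(conditions, responses, degree = 2L,
                             basis = c("polynomial", "cell_means")) {
  basis <- match.arg(basis)
  t <- as.numeric(conditions)
  Y <- as.matrix(responses)
  if (anyNA(t) || anyNA(Y)) stop("NA in training data", call. = FALSE)
  if (nrow(Y) != length(t)) stop("conditions and responses disagree in length",
                                 call. = FALSE)
  if (is.null(colnames(Y)))
    colnames(Y) <- if (ncol(Y) == 1L) "response" else
      paste0("response_", seq_len(ncol(Y)))
  X <- design_matrix(t, degree, basis, levels = sort(unique(t)))
  p <- ncol(X)
  if (length(unique(t)) < p || nrow(X) < p + 1L)
    stop("need more than ", p, " observations over at least ", p,
         " distinct conditions for basis '", basis, "'", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("rank-deficient design for polynomial degree ", degree, call. = FALSE)
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  nu <- nrow(X) - p
  structure(list(coefficients = B,
                 scatter = crossprod(res) / nu,
                 df = nu,
                 xtx_inv = chol2inv(qr.R(qrX)),
                 basis = basis, degree = if (basis == "polynomial") degree else NA,
                 levels = sort(unique(t)),
                 range = range(t), q = ncol(Y), N = nrow(X),
                 responses = colnames(Y)),
            class = "growth_model")
}

design_matrix <- function(t, degree, basis, levels) {
  if (basis == "polynomial")
    outer(t, 0:degree, `^`)
  else {
    if (!all(t %in% levels))
      stop("cell-means model is only defined at the sampled conditions: ",
           paste(levels, collapse = ", "), call. = FALSE)
    1 * outer(t, levels, `==`)
  }
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("Growth model: %s basis%s, q = %d response(s), N = %d, df = %d\n",
              x$basis,
              if (x$basis == "polynomial") paste0(" (degree ", x$degree, ")") else "",
              x$q, x$N, x$df))
  cat(sprintf("  condition range [%g, %g] h\n", x$range[1], x$range[2]))
  invisible(x)
}

#' Fitted mean response and leverage at new condition values
#'
#' @param object a [fit_growth_model()] fit.
#' @param t0 condition values.
#' @param ... unused.
#' @return list with \code{mean} (length(t0) x q matrix) and \code{leverage}
#'   (vector h(t0)).
#' @export
predict.growth_model <- function(object, t0, ...) {
  X0 <- design_matrix(as.numeric(t0), object$degree, object$basis,
                      object$levels)
  list(mean = X0 %*% object$coefficients,
       leverage = rowSums((X0 %*% object$xtx_inv) * X0))
}

#' Inverse-prediction p-value for a candidate condition
#'
#' Tests whether the mystery specimen's responses are consistent with
#' candidate condition \code{t0}, by the prediction pivot of the fitted
#' model.  Univariate (q = 1):
#' \deqn{T = \frac{y^* - \hat y(t_0)}{\sqrt{MSE\,(1 + h(t_0))}} \sim t_\nu,}
#' two-sided.  Multivariate:
#' \deqn{T^2 = \frac{(y^* - \hat y(t_0))^\top S^{-1} (y^* - \hat y(t_0))}
#'   {1 + h(t_0)}, \qquad \frac{\nu - q + 1}{\nu q}\,T^2 \sim F_{q,\,\nu-q+1}.}
#' At q = 1 the two coincide.  Conditions outside the fitted range are not
#' evaluated by default, since a growth model has no warrant beyond the ages
#' the training experiment sampled: they return \code{NA} with a warning
#' unless \code{extrapolate = TRUE}.
#'
#' @param model a [fit_growth_model()] fit.
#' @param y_star numeric vector of length q: the mystery specimen's
#'   responses, in training units.
#' @param t0 candidate condition value(s); vectorized.
#' @param extrapolate evaluate t0 outside the fitted range? Default FALSE.
#' @return p-values in \code{[0, 1]}, one per t0.
#' @export
inverse_p_value <- function(model, y_star, t0, extrapolate = FALSE) {
  stopifnot(inherits(model, "growth_model"))
  y_star <- as.numeric(y_star)
  if (length(y_star) != model$q || anyNA(y_star) || any(!is.finite(y_star)))
    stop("'y_star' must be ", model$q, " finite value(s)", call. = FALSE)
  if (model$df < model$q)
    stop("residual df (", model$df, ") below q: multivariate test undefined",
         call. = FALSE)
  t0 <- as.numeric(t0)
  outside <- t0 < model$range[1] | t0 > model$range[2]
  p <- rep(NA_real_, length(t0))
  if (any(outside) && !extrapolate) {
    warning(sum(outside), " condition value(s) outside the fitted range [",
            model$range[1], ", ", model$range[2],
            "] not evaluated (set extrapolate = TRUE to override)")
    if (all(outside)) return(p)
  }
  use <- if (extrapolate) seq_along(t0) else which(!outside)
  pr <- predict(model, t0[use])
  dev <- sweep(pr$mean, 2L, y_star, `-`)
  nu <- model$df; q <- model$q
  if (q == 1L) {
    mse <- model$scatter[1L, 1L]
    if (mse == 0) { p[use] <- as.numeric(dev == 0); return(p) }
    tt <- -dev[, 1L] / sqrt(mse * (1 + pr$leverage))
    p[use] <- 2 * pt(-abs(tt), df = nu)
  } else {
    sinv <- tryCatch(solve(model$scatter), error = function(e)
      stop("residual scatter matrix is singular (degenerate or duplicated ",
           "responses); multivariate test refused", call. = FALSE))
    t2 <- rowSums((dev %*% sinv) * dev) / (1 + pr$leverage)
    p[use] <- pf(t2 * (nu - q + 1) / (nu * q), q, nu - q + 1,
                 lower.tail = FALSE)
  }
  p
}

#' Default evaluation grid over the fitted condition range
#'
#' @param model a [fit_growth_model()] fit.
#' @param n number of grid points (default 200), or use \code{step}.
#' @param step grid step in condition units; overrides \code{n}.
#' @return increasing numeric grid spanning the sampled range (the sampled
#'   conditions themselves for a cell-means fit).
#' @export
condition_grid <- function(model, n = 200L, step = NULL) {
  if (model$basis == "cell_means") return(model$levels)
  if (!is.null(step))
    seq(model$range[1], model$range[2], by = step)
  else
    seq(model$range[1], model$range[2], length.out = n)
}

#' Confidence set on condition from continuous responses
#'
#' Inverts the prediction pivot over a grid of candidate conditions: the
#' members are the grid values not rejected by [inverse_p_value()] at level
#' \code{alpha}.  For q = 1 this is exactly the set of conditions whose
#' prediction band contains the observed response (see [prediction_band()]).
#'
#' @inheritParams inverse_p_value
#' @param grid increasing numeric vector of candidate conditions; default
#'   [condition_grid()] with 200 points over the fitted range.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return a \code{"confidence_set"} (see [categorical_confidence_set()]).
#' @export
continuous_confidence_set <- function(model, y_star, grid = NULL,
                                      alpha = 0.05, extrapolate = FALSE) {
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1)
  if (is.null(grid)) grid <- condition_grid(model)
  grid <- as.numeric(grid)
  if (!length(grid) || is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be a non-empty increasing vector", call. = FALSE)
  p <- inverse_p_value(model, y_star, grid, extrapolate = extrapolate)
  per <- data.frame(condition = grid, p_value = p,
                    rejected = !is.na(p) & p <= alpha)
  new_confidence_set(alpha, members = grid[!is.na(p) & p > alpha],
                     per_condition = per, kind = "continuous")
}

#' Prediction band of a univariate growth model
#'
#' The two-sided \code{1 - alpha} prediction band
#' \eqn{\hat y(t) \pm t_{1-\alpha/2,\nu}\sqrt{MSE\,(1 + h(t))}} over a
#' condition grid.  A response value lies inside the band at \code{t}
#' exactly when \code{t} belongs to the inverse-prediction confidence set.
#'
#' @inheritParams continuous_confidence_set
#' @return data frame with columns \code{condition}, \code{fit},
#'   \code{lower}, \code{upper}.
#' @export
prediction_band <- function(model, grid = NULL, alpha = 0.05) {
  stopifnot(inherits(model, "growth_model"))
  if (model$q != 1L)
    stop("prediction bands are univariate; q = ", model$q, call. = FALSE)
  if (is.null(grid)) grid <- condition_grid(model)
  pr <- predict(model, grid)
  half <- qt(1 - alpha / 2, model$df) *
    sqrt(model$scatter[1L, 1L] * (1 + pr$leverage))
  data.frame(condition = as.numeric(grid), fit = pr$mean[, 1L],
             lower = pr$mean[, 1L] - half, upper = pr$mean[, 1L] + half)
}
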