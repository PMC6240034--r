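#' Ordinary least-squares fit on complete cases
#'
#' The linear-model workhorse of the pipeline: fits `y ~ 1 + X` by OLS
#' on the rows where `y` and every predictor are observed, and records
#' the quantities the downstream analyses need (coefficient table,
#' R-squared, adjusted R-squared, AIC and its small-sample correction
#' AICc, residuals aligned to the input rows).
#'
#' The AICc parameter count k includes the intercept and the residual
#' variance: `AICc = AIC + 2k(k+1)/(n-k-1)`.
#'
#' @param y numeric response vector (`NA` allowed).
#' @param X numeric predictor matrix (no intercept column); must be
#'   full rank on the complete cases.
#' @return object of class `es_lm`: list with `coefficients` (matrix
#'   with estimate, SE, t, p), `r2`, `adj_r2`, `aic`, `aicc`,
#'   `residuals` and `fitted` (full length, `NA` where unused), `n`,
#'   `k`, `predictors`, `rows` (logical complete-case index) and the
#'   underlying `lm` fit.
#' @export
fit_lm <- function(y, X) {
  X <- as.matrix(X)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)")
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  rows <- !is.na(y) & stats::complete.cases(X)
  n <- sum(rows)
  p <- ncol(X)
  if (n <= p + 1)
    stop("insufficient complete cases: n = ", n, " with ", p, " predictors")
  Xc <- X[rows, , drop = FALSE]
  qx <- qr(cbind(`(Intercept)` = 1, Xc))
  if (qx$rank < p + 1) {
    drop_cols <- colnames(cbind(`(Intercept)` = 1, Xc))[qx$pivot[-seq_len(qx$rank)]]
    stop("rank-deficient predictor matrix; offending column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  df <- data.frame(.y = y[rows], Xc, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)
  k <- p + 2L                     # coefficients + intercept + error variance
  aic <- stats::AIC(fit)
  res <- fitted <- rep(NA_real_, length(y))
  res[rows] <- stats::residuals(fit)
  fitted[rows] <- stats::fitted(fit)
  structure(list(coefficients = sm$coefficients, r2 = sm$r.squared,
                 adj_r2 = sm$adj.r.squared, aic = aic,
                 aicc = aicc(aic, k, n), residuals = res, fitted = fitted,
                 n = n, k = k, predictors = colnames(X), rows = rows,
                 lm = fit),
            class = "es_lm")
}

#' Small-sample corrected AIC
#'
#' @param aic AIC value.
#' @param k number of estimated parameters, counting the intercept and
#'   the error variance.
#' @param n sample size; must exceed `k + 1`.
#' @return `aic + 2k(k+1)/(n-k-1)`.
#' @export
aicc <- function(aic, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n <= k + 1")
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.es_lm <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, %d predictor(s); R2 = %.4f (adj %.4f), AICc = %.2f\n",
              x$n, length(x$predictors), x$r2, x$adj_r2, x$aicc))
  stats::printCoefmat(x$coefficients, ...)
  invisible(x)
}

#' @export
coef.es_lm <- function(object, ...) object$coefficients[, 1]

#' @export
residuals.es_lm <- function(object, ...) object$residuals

#' Replace columns by their OLS residuals
#'
#' Regresses every column of `Y` on `X` (with intercept) and returns the
#' residuals, column by column on that column's complete cases.  Rows
#' missing in a column stay missing.  This is the residualization
#' primitive of the cascade: it removes the linear effect of a predictor
#' block from each service.
#'
#' @param Y numeric matrix whose columns are to be residualized.
#' @param X numeric predictor matrix (complete).
#' @return matrix of residuals, same shape and dimnames as `Y`.
#' @export
residualize <- function(Y, X) {
  Y <- as.matrix(Y)
  out <- Y
  for (j in seq_len(ncol(Y)))
    out[, j] <- fit_lm(Y[, j], X)$residuals
  out
}

#' Compare a fitted model against the intercept-only null model
#'
#' Refits the intercept-only model on exactly the rows the model used
#' and reports both AICc values and their difference.
#'
#' @param fit an [fit_lm()] object.
#' @param y the response vector the model was fitted to (full length).
#' @return list with `aicc_model`, `aicc_null` and
#'   `delta_aicc = aicc_model - aicc_null` (negative favours the model).
#' @export
null_comparison <- function(fit, y) {
  stopifnot(inherits(fit, "es_lm"))
  yc <- y[fit$rows]
  null <- stats::lm(yc ~ 1)
  a0 <- aicc(stats::AIC(null), 2L, length(yc))
  list(aicc_model = fit$aicc, aicc_null = a0,
       delta_aicc = fit$aicc - a0)
}
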